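Package: aggkin
Title: Aggregation-Kinetics Prediction for Antibody Fragments from
    Molecular Dynamics Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for predicting the aggregation kinetics of an
    antibody Fab fragment across formulation conditions (temperature, pH,
    ionic strength) from molecular-dynamics trajectory descriptors.
    Reads multi-model PDB and XYZ trajectories; computes seventeen
    molecular descriptors (Shrake-Rupley solvent-accessible surface
    areas, per-region delta-SASA over aggregation-prone regions, RMSD,
    per-residue RMSF, radius of gyration, hydrogen-bond counts,
    salt-bridge occurrence, native-contact fraction and
    Henderson-Hasselbalch net charge); performs Pearson/Spearman
    correlation analysis, redundancy-based feature selection,
    single-feature risk banding and residue-level regression mapping;
    fits multiple linear regression and NIPALS partial least squares
    with k-fold and leave-one-out cross-validation, fold-number
    sensitivity analysis and stability-aware model selection; and ranks
    features by model-agnostic Shapley attribution (exact enumeration or
    permutation sampling). Includes generators for synthetic
    trajectories and low-rank feature tables used to validate every
    stage, plus a 49-condition formulation table shipped as a fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
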