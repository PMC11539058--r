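# aggkin

Predicting antibody-fragment aggregation kinetics across formulation
conditions from molecular-dynamics descriptors.

## The problem

Therapeutic antibody fragments aggregate at rates that depend strongly on
the formulation: temperature, pH and ionic strength together set the
experimental aggregation rate ln(*v*) (*v* in % monomer lost per day) over
a range of more than fifteen log units for the same protein. `aggkin`
implements, as a tested and reusable R pipeline, a workflow that connects
all-atom MD trajectories of a Fab fragment (442 residues: light chain
1–214, heavy chain 215–442) to those measured kinetics:

1. **Descriptor extraction** — seventeen molecular features per
   formulation condition, averaged over replicate trajectories and over
   the trailing half of each run: total and nonpolar (carbon-only)
   solvent-accessible surface area by the Shrake–Rupley rolling-probe
   construction; ΔSASA of seven aggregation-prone regions (APRs
   31–36, 47–51, 114–118, 129–139, 261–265, 325–329, 387–402) relative
   to an early-trajectory baseline, and their sum; the fraction of native
   Cα contacts *Q* (8 Å cutoff); last-window mean RMSF, RMSD and radius
   of gyration; hydrogen-bond counts (3.5 Å / 30° criterion); salt-bridge
   occurrence (acidic-O to basic-N within 3.2 Å); and the
   Henderson–Hasselbalch net charge
   *Z* = Σ_base 1/(1+10^(pH−pKa)) − Σ_acid 1/(1+10^(pKa−pH))
   from externally supplied per-site pKa values.
2. **Statistical screening** — Pearson/Spearman correlation matrices,
   redundancy-based feature selection (|r| > 0.8 drops the member with
   the weaker response correlation), a three-band single-feature risk
   classifier (high: ln *v* > 4; low: ln *v* < 0), and residue-level
   regression R² maps written into PDB B-factor columns.
3. **Model building** — multiple linear regression and NIPALS partial
   least squares written from first principles, k-fold/LOOCV machinery
   with fold-number sensitivity analysis, stability-aware model
   selection, and parity metrics.
4. **Attribution** — model-agnostic Shapley values (exact subset
   enumeration up to 15 features, seeded permutation sampling beyond)
   and mean-|φ| global importance ranking.
5. **Synthetic data** — generators for condition-dependent toy
   trajectories and low-rank feature tables with planted coefficients,
   used throughout the test suite, plus the 49-condition formulation
   table shipped as a CSV fixture.

## Worked example

```r
library(aggkin)

ct <- table1_fixture()   # the 49 formulation conditions
cm <- correlation_matrix(ct[, c("temperature", "ionic_strength",
                                "pH", "tm", "ln_v")])
round(cm$r, 2)
#>                temperature ionic_strength    pH    tm  ln_v
#> temperature           1.00           0.18  0.21 -0.08  0.84
#> ionic_strength        0.18           1.00  0.29 -0.07  0.15
#> pH                    0.21           0.29  1.00  0.65 -0.13
#> tm                   -0.08          -0.07  0.65  1.00 -0.44
#> ln_v                  0.84           0.15 -0.13 -0.44  1.00
```

Temperature dominates the aggregation kinetics (r = 0.84 with ln *v*),
while the melting temperature tracks pH (r = 0.65) rather than any
dynamics feature. Banding the same table:

```r
banded_classifier(rep(0, 49), ct$ln_v, feature_threshold = 1)
#> <banded_classification> n=49 | low 24 / medium 15 / high 10
```

10 of the 49 conditions sit in the high-aggregation band (ln *v* > 4).
Cross-validated PLS on a synthetic feature table with planted low-rank
structure at the study's size (49 × 9, 10 % response noise):

```r
st <- synth_feature_table(feature_table_spec(
  n_rows = 49, features = paste0("f", 1:9), latent_rank = 3,
  noise_sd = 0.3, response_noise_frac = 0.1, seed = 2))
cross_validate(model_spec("pls", n_components = "auto"),
               st$X, st$y, k = 10, seed = 2)
#> <cv_report> PLS, k=10 | mean MSE 0.3403, max 0.6379, sd 0.1761 | eval R2 0.986
```

The full orchestration — descriptors → selection → banding →
k-sensitivity → CV → final model → Shapley ranking → residue map — runs
through `run_pipeline(pipeline_config(...))`, which also offers a
statistics-only mode driven by a precomputed feature table.

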