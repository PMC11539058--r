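---
title: "Methods: from MD descriptors to aggregation-kinetics models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MD descriptors to aggregation-kinetics models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkin)
```

## The modelling problem

A Fab antibody fragment in solution aggregates at a rate ln(*v*) that
varies with temperature, pH and ionic strength. The working hypothesis
of this workflow is that the aggregation rate of a natively folded
protein is governed by native-ensemble dynamics — transient local
unfolding that exposes aggregation-prone regions (APRs) — rather than by
global unfolding. Accordingly the pipeline measures *descriptors of
native-state dynamics and surface exposure* from MD trajectories run
under each formulation condition, and regresses the measured kinetics on
them.

The package assumes MD has already been run elsewhere: its inputs are
multi-model PDB or XYZ trajectories, a condition table, and per-site pKa
predictions as plain files. The 49-condition table studied in the
source data set ships as a fixture (`table1_fixture()`); the original
trajectories are not public, so all trajectory-dependent stages are
validated on constructed and synthetic inputs instead.

## Conventions

* Coordinates in Å, times in ns, default frame spacing 0.1 ns.
* Residues are numbered continuously across chains (light 1–214, heavy
  215–442), because the heavy-chain APR windows (261–265, 325–329,
  387–402) are defined on that continuous index; `read_structure()`
  accepts per-chain offsets for data numbered per chain.
* User-facing residue ranges are 1-based and inclusive.
* "Last-window" descriptors average over the trailing
  `last_window_fraction` (default 0.5) of frames, so a 1001-frame,
  100 ns run contributes its last 500 frames (50 ns). Expressing the
  window as a fraction lets the same code handle trajectories of any
  length.
* The condition table's melting temperatures are stored exactly as
  printed in the source table. Their magnitudes (59.5–83.2) are on the
  Celsius scale even though the source header says kelvin; no
  conversion is applied anywhere, and nothing downstream depends on the
  unit — `tm` is only ever correlated against other columns.

## Descriptors and their parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water probe, universal convention |
| `sphere_points` | 960 | – | golden-spiral mesh; <1 % change on doubling |
| `hbond_da_cutoff` | 3.5 | Å | common geometric H-bond criterion |
| `hbond_angle_cutoff` | 30 | ° | H–donor–acceptor angle, same convention |
| `saltbridge_cutoff` | 3.2 | Å | acidic-O to basic-N contact distance |
| `native_cutoff` | 8.0 | Å | Cα–Cα native-contact radius |
| `last_window_fraction` | 0.5 | – | trailing 50 ns of a 100 ns run |
| `baseline_frames` | 20 | frames | early-trajectory ΔSASA baseline |

**SASA.** The Shrake–Rupley construction meshes each atom's expanded
sphere (vdW + probe) with a golden-spiral point set and counts points
outside every neighbour's expanded sphere. Hydrogens are excluded both
as surface atoms and as occluders. Nonpolar SASA restricts the surface
atoms to carbons — the hydrophobic-exposure reading of "nonpolar" —
while all heavy atoms still occlude. Built-in vdW radii: C 1.70, N 1.55,
O 1.52, S 1.80, H 1.20, P 1.80 Å (overridable via the topology).

**ΔSASA of APRs.** Two baseline conventions circulate for "change in
exposure over a run": subtracting the average of the first 20 frames,
or subtracting frame 20 alone. The 20-frame average is the default
(less noisy); the single-frame variant is available via
`delta_sasa_baseline = "single"`. The seven-region sum `sum_aprsasa`
is, by construction, the row sum of the per-region columns, and the
feature-table assembler asserts it.

**RMSF.** Fluctuations are measured about the time-average structure
after a two-pass superposition (fit to the first window frame, average,
re-fit to the average). This is the common convention; the reference is
not stated by most MD tools' documentation but the time-average choice
makes RMSF independent of which frame happens to start the window.
Superposition can be disabled for controlled tests.

**Hydrogen bonds.** When the model carries no hydrogens (as the
synthetic toys may), the detector falls back to distance-only counting
of N/O pairs with a logged warning. Donor detection binds each H to its
nearest N/O within 1.25 Å per frame.

**Net charge.** Henderson–Hasselbalch from per-site pKa values consumed
as input; the package never predicts pKas itself, and ionic strength
enters the models only as a condition covariate, not as a charge
correction.

## Statistical stages

**Redundancy-based selection.** Feature pairs with |r| above the
threshold (default 0.8) are processed in descending |r| — the source
procedure does not state an order, and processing the strongest
redundancies first makes the outcome deterministic. At each pair the
member with the weaker |r| against the response is dropped; exact ties
drop the later column and are logged. A keep-list exempts features
retained on domain grounds (e.g. weakly correlated but mechanistically
interesting descriptors such as net charge or native contacts), since a
purely rule-based pass cannot reproduce retention-by-judgment.

**Risk banding.** Band edges (0 and 4 on ln *v*) use strict
inequalities; a condition exactly at an edge falls in the middle band.
Precision is reported as 100·TP/(TP+FP) and flagged undefined when
nothing is flagged.

**PCA overview.** Columns are z-scored; loading signs are fixed so each
component's largest-magnitude loading is positive (SVD signs are
otherwise arbitrary, which would break byte-identical reruns).

## Regression

**OLS** uses a QR decomposition of the standardized design and refuses
rank-deficient inputs, naming the collinear columns.

**PLS** is NIPALS: per component the weight vector is proportional to
X'y, scores/loadings follow, and X and y are deflated. Features are
z-scored and the response centered inside the fit — the scale of the
seventeen descriptors spans Å² to elementary charges, so unscaled PLS
would be dominated by SASA columns. Standardization parameters are
always learned on the training split only. The component count defaults
to `"auto"`: inner 5-fold CV minimising MSE, chosen per training split,
because no fixed count is defensible across the fold sizes the
machinery must handle. At full components PLS reproduces OLS, which the
tests assert at 1e-8.

**Cross-validation.** Folds come from a seeded shuffle with sizes
differing by at most one; k = n is LOOCV. The evaluation R² pools
out-of-fold predictions over all folds rather than averaging per-fold
R² values, which is unstable for fold sizes of 4–5. The fold-number
sensitivity scan (default k = 2…31) reports every k against the LOOCV
baseline and recommends the k with the closest mean MSE (ties to
smaller k); k = 10 remains the conventional choice and nothing in the
package forces the recommendation.

**Model selection.** "Unstable" is formalized as: MSE standard
deviation above the median across candidates. Among the stable
candidates the lowest mean MSE wins, ties resolved by input order and
logged. This is one formalization of a qualitative stability judgment
and the rule is pluggable.

## Shapley attribution

The value function is interventional: v(S) averages the model over
background rows with the features in S replaced by the explained row's
values. Exact enumeration covers p ≤ 15; beyond that a seeded
permutation estimator averages marginal contributions over random
feature orderings, with standard errors from the between-permutation
variance. Efficiency, null-player and symmetry hold exactly for the
enumerated method and within Monte-Carlo error for the estimator. The
ranking of a tree-ensemble explainer on the original data is *not* a
reproduction target: it depends on unstated hyperparameters of the
fitted booster, whereas the attribution here explains whatever model
the pipeline actually selected.

## Synthetic data: what it does and does not show

`synth_trajectory()` plants per-residue Gaussian fluctuation amplitudes
(σ per residue, times a temperature scale) on a fixed helix or random
coil, with optional charged side-chain pseudo-atoms (ASP/GLU carboxylate
oxygens, LYS/ARG nitrogens) and backbone N/O so the interaction
detectors have real targets. `synth_feature_table()` plants low-rank
linear structure X = FL' + E, y = Xβ + ε, with response noise expressed
as a fraction of the signal's standard deviation, and returns the
planted truth for recovery tests. Both are pure functions of their spec
(seed included), which the suite asserts by identical reruns.

Defaults mirror the study's shape where one exists: 49 rows, the 17
canonical feature codes, four temperature levels in the synthetic
condition grids, and the recovery benchmark at n = 49, p = 9 with 10 %
response noise. The generators emulate *statistical* structure only —
condition-dependent fluctuation amplitudes and a linear
feature→response map. They do not emulate force-field energetics,
correlated backbone motion, solvent, or the nonlinearities of real
unfolding. Passing tests therefore demonstrate that the machinery is
correct (descriptors measure what they claim on constructed geometry;
the regression recovers planted structure at realistic size and noise),
not that the descriptors predict real kinetics — that claim rests on
the original study's data, which is not redistributable.

## Numerical choices and degenerate inputs

* Kabsch superposition excludes reflections by the determinant
  correction; all-zero weights are an error.
* Zero-variance columns yield *missing* correlation coefficients, never
  0, and are refused by PCA and the regression fits with the column
  named.
* An empty salt-bridge universe or an empty pKa site list returns 0
  with a warning rather than an error, since both are legitimate for
  small synthetic systems.
* B-factor output clips to [0, 99.99] (the PDB field width) with a
  warning; XYZ is the lossless round-trip format (1e-6 Å), PDB carries
  1e-3 Å.
* All RNG funnels through a seed-scoped helper that restores the
  caller's RNG state, so library calls never perturb user scripts.

## Problem sizes in the shipped suite

The test suite exercises: SASA meshes up to 1e5 points on two-atom
systems; a 200-residue, 5000-frame jitter trajectory for the RMSF
expectation check; 20 generator seeds for the PLS recovery benchmark;
and an eight-condition end-to-end pipeline run with 24-frame
trajectories at 240 mesh points. These sizes were chosen to make the
Monte-Carlo checks statistically decisive while keeping the default
suite quick on a single core.

## Known limitations

* The cli surface is the R API (`run_pipeline()` plus the module
  functions); there is no shell subcommand wrapper.
* GROMACS binary formats (XTC/TRR) are out of scope; convert to
  multi-model PDB or XYZ first.
* H-bond donor detection is geometric and per-frame; no topology-based
  bond table is consumed.
* The salt-bridge pair scan is quadratic in charged residues and
  intended for analysis windows, not millisecond trajectories.
* Comparison learners (random forest, SVR) attach through the custom
  model-spec adapter and carry no from-scratch guarantee.
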