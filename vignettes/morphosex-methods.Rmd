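---
title: "Methods and design notes: sacral sex estimation with morphosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes: sacral sex estimation with morphosex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosex)
```

`morphosex` analyses sexual dimorphism of the human sacrum from two kinds
of data — 3D landmark configurations and classic linear osteometrics — and
evaluates how reliably sex can be classified from each. This vignette
documents the statistical models, the tunable parameters, the numerical
choices, and what the synthetic data generator does and does not emulate.

## Superimposition model

A specimen is a $k \times 3$ landmark configuration in mm. Size is
measured by centroid size, $CS = \sqrt{\sum_j \lVert x_j - \bar x
\rVert^2}$, and shape by the Procrustes coordinates after generalized
Procrustes analysis (GPA): configurations are centred, scaled to unit
centroid size, and iteratively rotated (proper rotations only) to the
least-squares consensus until the consensus root-mean-square change falls
below $10^{-10}$ (cap: 200 iterations). Form space augments the flattened
shape coordinates with one unweighted column of $\ln CS$; centring happens
inside the PCA, not during augmentation.

Numerical choices worth knowing:

* **Consensus initialization.** The consensus starts from the mean of the
  centred, scaled configurations; if raw orientations cancel so far that
  the mean shape nearly vanishes (centroid size below 10% of the
  specimens'), the first configuration is used instead. Mean
  initialization makes re-alignment of already-aligned data an exact
  fixed point (one iteration, no movement beyond tolerance), which
  first-specimen initialization does not.
* **Reflections** are excluded by default (determinant $+1$ fits), the
  standard convention; `allow_reflection = TRUE` gives the full
  orthogonal fit used by some oracles.
* **Procrustes distance** between specimens is the Euclidean distance of
  their coordinates in the common GPA frame — this is the statistic the
  permutation test uses. A fresh two-configuration fit
  (`procrustes_distance(..., fit = TRUE)`) exists for oracle comparisons.

## Thin-plate-spline machinery and semilandmark sliding

Curve semilandmarks carry no point-to-point homology along their curve, so
each is allowed to slide along the curve tangent during superimposition.
The sliding criterion is minimal TPS bending energy relative to the
current reference.

The TPS kernel follows the standard fundamental solutions, $U(r) = r^2 \ln
r^2$ in 2D and $U(r) = r$ in 3D. The bending-energy matrix $B_k$ is the
upper-left $k \times k$ block of the inverse bordered system
$[[K, P], [P^T, 0]]$; two implementation details matter:

* In 3D the biharmonic fundamental solution carries a negative constant,
  so the block is negated to give a positive-semidefinite energy form
  (eigenvalues checked $\ge -10^{-9}$ in the tests). The form annihilates
  affine displacement fields exactly.
* The polynomial block $P = [1, X]$ is pruned to its column rank, so
  coplanar or collinear references (a flat calibration grid, a straight
  curve) remain solvable; affine annihilation then applies to the affine
  span the reference actually has.

Sliding solves, per specimen and pass, one joint equality-constrained
quadratic program: all semilandmarks move simultaneously along their
tangent lines to minimize the bending energy of the deformation from the
reference (the sample consensus) to the specimen. Fixed landmarks never
move during sliding. After each pass the sample is re-superimposed and the
reference re-estimated; three outer passes are the default, and the
per-pass energies are recorded in `energy_path`. The non-increase
guarantee (energy after $\le$ energy before) is structural *within* a
pass — between passes the reference changes, so the trace is reported
per pass.

**Tangent estimation.** Tangents are central differences of the adjacent
curve points, one-sided at free curve ends (declared fixed anchors serve
as end neighbours). By default they are computed from the *reference*
(consensus) geometry: this makes the constrained optimum an exact fixed
point of the pass and is robust when semilandmarks are closely spaced
relative to digitizing noise — with specimen-based tangents the
constraint directions wobble with the noise and the pass-to-pass
contraction can stall. `tangents = "specimen"` restores the
specimen-based variant. Semilandmarks slide along straight tangent lines
without re-projection onto a surface; with no meshes available this
approximation is explicit and is the main reason slid configurations
should not be over-interpreted at high curvature.

## Shape statistics

PCA is a centred (unscaled) eigendecomposition; $\min(n-1, 3k)$
components are retained. Variance-explained regressions fit all shape
columns on one predictor block by least squares and report $100 \cdot
SS_{model}/SS_{total}$; for orthogonal predictors these percentages are
additive. The allometry-corrected sex effect regresses shape on $\ln CS$,
keeps the residuals, regresses those on binary sex, and reports the
stage-2 percentage both of the residual and of the original total
variance.

The permutation test of the group mean difference uses the Euclidean
distance between group mean vectors in the GPA frame, label permutation
(default $B = 10000$), and the add-one estimator $p = (\#\{d^* \ge d\} +
1)/(B + 1)$, which keeps $p \in (0, 1]$ and is exact at level
$\alpha$ when $\alpha(B+1)$ is an integer. `exact = TRUE` enumerates all
assignments (the test suite checks $n = 3+3$ against a full manual
enumeration).

Procrustes ANOVA uses sequential (type-I) sums of squares in the declared
term order and residual randomization (RRPP): for each term the reduced
model's residuals are permuted, added back to the reduced fit, and the
term's $F$ ratio recomputed. Rank-deficient designs abort with the aliased
term named. Type-I error is verified by simulation (1000 null replicates,
$B = 199$, nominal 0.05 within three binomial SEs) — $B$ is reduced from
the analysis default because the calibration multiplies it by a thousand
replicates.

## Osteometrics and effect sizes

CBI $= 100\,CW/SW$ and CAI $= 100\sqrt{CW \cdot CD}/SW$ are
scale-invariant; the corpus area $CW \cdot CD$ scales with size squared.
The square-root CAI form is used because it is the only rendering
dimensionally consistent with an index in the mid-30s for CW, CD and SW
around 49, 30 and 113 mm — the linear form $100\,CW \cdot CD/SW$ would be
in the hundreds. Landmark-derived measurements are chord distances between
registered endpoint pairs on the raw (unscaled) configurations; the
registry lives in the template so the anatomical mapping is configuration,
not code.

Cohen's D is reported in two conventions because published tables rarely
state their formula: `pooled` (mean difference over the pooled
within-group SD, $n-1$ weights) and `total` (mean difference over the
total-sample SD reconstructed from the group summaries with group-size
weights for both the within and the between component). The `total`
convention is the one that reproduces published sacral effect-size tables
to the printed precision on the rows where the inputs are printed too;
with rounded inputs a third decimal can move (one published row gives 0.88
here against a printed 0.89).

## Classification

The two-group LDA is the Gaussian equal-covariance discriminant computed
explicitly from the group means and pooled covariance: $w =
S^{-1}(m_F - m_M)$, score $w^T(x - \tfrac{m_F + m_M}{2}) + \log
\pi_F/\pi_M$, positive scores = female (females are the positive class
throughout, and prevalence is always an explicit argument, so the
prevalence-weighted accuracy $\mathrm{sens} \cdot \mathrm{prev} +
\mathrm{spec} \cdot (1 - \mathrm{prev})$ is unambiguous under relabeling).
Priors default to equal; proportional and numeric priors are available. A
numerically singular pooled covariance triggers ridge regularization
($\lambda = 10^{-8} \cdot \mathrm{tr}(S)/p$) with a warning — selected-PC
features can be few but collinear in small samples. The explicit form is
cross-checked against `MASS::lda` (direction cosines and LOO predictions)
in the tests.

Leave-one-out cross-validation refits the discriminant $n$ times; PC
screening (per-PC two-sample t-test at $\alpha = 0.05$, rank-sum
available) is performed once on the full sample *before* the folds,
mirroring common practice in the field; this is optimistic, and the
reported cross-validated rates should be read accordingly.

ROC curves place thresholds at midpoints between consecutive distinct
scores plus $\pm\infty$; AUC is the two-sample rank statistic with ties
counted one half, and equals the trapezoidal staircase area to $10^{-12}$
by construction (asserted on random tied data). Box's M uses the standard
$\chi^2$ approximation with the usual small-sample correction factor.

## The synthetic generator

`make_template()` builds a deterministic, bilaterally symmetric,
sacrum-like 3D object — a tapering, sagittally curved body with lateral
alae flanges — carrying 44 fixed landmarks and 56 semilandmarks on 7
smooth curves, with SW/CW/CD endpoint registries (113, 49, 30 mm on the
reference) and regional subsets (`fixed_only`, `corpus`, `S1`, `S1S2`,
`auricular`). The geometry is synthetic: it mirrors the counts, roles,
symmetry and measurement magnitudes of a real sacrum digitization
protocol, not anatomy.

`simulate_dataset()` draws, per specimen,
$$\text{shape} = \text{reference} + s \cdot d\,F_{sex} + G_{group}
  + a\,(\ln CS - \overline{\ln CS})\,F_{allo} + \varepsilon,$$
with $s = \mp\tfrac12$ for F/M, unit-norm deterministic effect fields
built from the template geometry (alae broadening and corpus narrowing
with shortening for the female direction; stronger sagittal curvature
with larger size for allometry), iid Gaussian landmark noise, extra
tangential jitter on the semilandmarks (so sliding has real work to do),
lognormal centroid sizes, and a random rigid motion per specimen (so GPA
has real work to do). All effect fields are projected into the shape
tangent space at the reference (orthogonal to translation, rotation and
scaling directions), so superimposition preserves their variance and the
generator's variance shares are recoverable by the pipeline — the
acceptance suite verifies recovery within one percentage point at
$n = 500$ over 50 seeds.

Default magnitudes are chosen to emulate the variance structure reported
for geographically heterogeneous modern-human samples: a weak sex shape
effect and weak allometry (each a small percent of total shape variance),
small group offsets, nearly size-monomorphic sexes (M/F centroid-size
ratio $113.7/112.3$), digitizing noise of 0.5% of centroid size per
coordinate, and tangential jitter of 1%. The measurement generator uses
per-sex trivariate Gaussians with published-style means/SDs (SW nearly
non-dimorphic; CW and CD strongly dimorphic) and a within-sex CW–CD
correlation of 0.70 (SW–CW 0.42, SW–CD 0.45). Note that the *pooled*
CW–CD correlation exceeds the within-sex parameter (about 0.78) because
both measurements are larger in males; checks therefore measure the
sex-centred correlation.

**What passing tests do and do not show.** The generator's residual
variation is iid Gaussian noise, so its sex signal — though a small share
of total variance — lies along a clean direction and simulated
classification accuracies (often $> 90\%$ at the defaults) exceed what
real, biologically structured samples yield (low 70s for comparable
heterogeneous material). Real individual variation is concentrated in a
few correlated modes, observer error is anisotropic, and populations are
admixed; none of that is modelled. Passing calibration therefore
demonstrates the *machinery* (alignment, sliding, variance decomposition,
resampling, cross-validation) is correct, not that any particular
real-world accuracy is expected.

## Problem sizes and reproducibility

The test and acceptance computations use: resampling calibration with
1000 null replicates at $B = 199$; classifier calibration with five
replicates of $n = 400$ at Mahalanobis separation 2 (expected accuracy
$\Phi(1) \approx 84\%$) and a chance check at $n = 200$; parameter
recovery at $n = 500$ over 50 seeds; correlation recovery averaged over
five $n = 500$ draws. All stochastic entry points take explicit seeds;
`run_pipeline()` derives per-stage streams from its single seed and
records them in the JSON manifest, so a rerun from the manifest reproduces
every number byte for byte.

## Known limitations

* No missing-landmark estimation, no weighted/robust Procrustes.
* Sliding is tangent-linear without surface re-projection; no 2D-patch
  surface semilandmarks.
* Box's M relies on the $\chi^2$ approximation (fine at the group sizes
  used here); no permutation version.
* The template's anatomical fidelity is nominal; users with real
  digitization protocols should edit the measurement and subset
  registries on the template rather than rely on the synthetic geometry.
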