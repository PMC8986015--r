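# morphosex

Quantifying sexual dimorphism of the human sacrum — and how well sex can
actually be classified from it — from 3D landmark data and classic
osteometric measurements.

Skeletal sex estimation from the sacrum has a century-long literature with
reported accuracies anywhere from ~54% to ~98%, depending on method and
reference sample. `morphosex` implements, as reusable and tested R
functions, the complete analysis chain used to compare three approaches on
a common footing:

* **Geometric morphometrics** — generalized Procrustes analysis (GPA) of
  fixed landmarks plus curve semilandmarks slid by thin-plate-spline (TPS)
  bending-energy minimization; PCA in *shape space* (Procrustes
  coordinates) and *form space* (coordinates augmented by the log centroid
  size, lnCS); multivariate variance-explained regressions on size, sex
  and geographic origin; the allometry-corrected sex effect (regress shape
  on lnCS, then the residuals on sex); permutation tests of the Procrustes
  distance between group mean shapes; Procrustes ANOVA with residual
  randomization.
* **Linear osteometrics** — sacral width (SW), corpus width (CW) and
  corpus depth (CD), the corporo-basal index CBI = 100·CW/SW, the
  corpus-area index CAI = 100·√(CW·CD)/SW and the corpus area CW·CD, with
  pooled t-tests and Cohen's D in two conventions (pooled within-group SD,
  and total-sample SD reconstructed from group summaries).
* **Classification** — two-group linear discriminant analysis with
  leave-one-out cross-validation, per-PC significance screening, Box's M,
  prevalence-weighted accuracy
  (`sensitivity·prevalence + specificity·(1 − prevalence)`), ROC curves
  with the rank-sum (Mann–Whitney) AUC, and intra-/inter-observer
  agreement statistics for qualitative sex ratings.

Because real skeletal samples cannot be redistributed, the package ships a
**synthetic landmark-population generator**: a deterministic sacrum-like
template (44 fixed landmarks, 56 sliding semilandmarks on 7 curves,
bilaterally symmetric, with registered SW/CW/CD endpoints) and a simulator
with a sex-specific mean-shape offset, an allometric shape component,
geographic-group offsets, lognormal centroid sizes and digitizing noise —
all with exported ground truth, so every stage of the pipeline is
exercisable and testable end to end.

## Worked example

Reconstructing combined-sample statistics from per-group summaries (the
printed-table workflow — no raw data needed):

```r
library(morphosex)

# corpus depth, complete sample: F 28.3 +/- 2.9 mm (n = 68),
#                                M 31.8 +/- 2.8 mm (n = 77)
summary_from_groups(68, 28.3, 2.9, 77, 31.8, 2.8)
#>  group  n mean  sd min max
#>      F 68 28.3 2.9  NA  NA
#>      M 77 31.8 2.8  NA  NA
#>   average difference = 3.5; t = 7.387, p = 1.145e-11
#>   Cohen's D = 1.05 (total-sample SD), 1.23 (pooled SD)

# per-sex correct rates 80.6% (F) and 75.3% (M) at prevalence 68/145:
weighted_accuracy(0.806, 0.753, 68 / 145)
#> 0.778
```

The average difference of 3.5 mm and the effect size of about one total
SD say that male corpora are deeper by a forensically useful margin; the
0.778 says a corpus-depth discriminant classifies roughly 78% of a
mixed-prevalence sample correctly.

The landmark pipeline on simulated data:

```r
sim  <- simulate_dataset(population_spec(n_per_cell = 12, seed = 1))
slid <- slide_semilandmarks(sim$data)      # GPA + bending-energy sliding
#> sliding_result: 48 specimens, 3 passes
#>   mean bending energy: 1.131 (pass-1 start) -> 0.4621 (final)

pca <- shape_pca(slid)                     # shape-space PCA
sel <- select_significant_pcs(pca$scores, sim$meta$sex)
lda_loo_cv(cbind(pca$scores[, sel, drop = FALSE], lnCS = slid$gpa$lnCS),
           sim$meta$sex)
#> classification_report (positive class 'F')
#>   correct: F 95.8% | M 95.8%; weighted accuracy 95.8% (prevalence 0.500)
#>   confusion TP=23 FP=1 TN=23 FN=1; AUC = 0.986

permutation_mean_difference(slid$gpa, sim$meta$sex, n_perm = 999, seed = 2)
#> group_comparison: F (n=24) vs M (n=24)
#>   distance between means = 0.0360852, p = 0.001 (permutation, B = 999)
```

`run_pipeline(demo_config("out", seed = 1))` chains all stages (align →
slide → PCA/regressions → permutation test → univariate tables →
LDA/ROC) and writes CSV reports plus a JSON manifest that makes the run
reproducible from its seed.

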