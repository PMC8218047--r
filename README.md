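# zonespect

Quantitative multi-modal SPECT bone imaging with CT-derived tissue zones:
simulation, reconstruction and evaluation statistics in one R package.

## What problem this addresses, and for whom

Tc-99m diphosphonate bone SPECT shows tracer uptake at sites of bone
turnover, but conventional iterative reconstruction smears that uptake well
beyond the bone it belongs to. When a co-registered CT is available, its
140 keV attenuation map can be segmented into five tissue classes — lung/air,
adipose, soft tissue, spongy bone, cortical bone — and those "zone maps" can
constrain the emission reconstruction so tissue boundaries stay sharp and
small bone lesions keep their counts. `zonespect` is for imaging scientists
and methodologists who want a fully inspectable, desk-scale model of that
pipeline: digital phantoms, projection physics with an exact adjoint,
dual-energy-window scatter estimation, three reconstruction variants, and
absolute quantification to Bq/ml and body-weight SUV — plus the statistics
used to evaluate such reconstructions in reader studies and SUV-threshold
classification.

## The core models

**Reconstruction.** All variants maximize the Poisson log-likelihood of the
projection counts y under the mean model A x + s, where A is an attenuated,
distance-dependent-resolution system matrix and s the scatter projection
estimate from the adjacent lower energy window:

* `recon_osem()` — OSEM, the reference method:
  x ← x / (Aᵀ1) ⊙ Aᵀ( y / (A x + s) ), monotone in likelihood with one
  subset; 10 mm Gaussian post-smoothing.
* `recon_cg()` — conjugate-gradient MLEM (Polak–Ribière, EM-preconditioned
  gradient, monotone line search, nonnegativity by projection); one CG
  update is worth roughly four OSEM updates.
* `recon_zonal()` — zonal CG: the same objective plus zone-masked
  regularization and edge-preserving zonal post-smoothing, 5 mm inside
  bone-dominant voxels and 10 mm elsewhere, with a symmetric
  doubly-stochastic masked kernel so no intensity crosses the bone/non-bone
  boundary, in-set constants are reproduced, and per-set totals are
  conserved.

**Evaluation.** Reader confidence is summarized by the confidence
likelihood ratio between methods a and b,

    R_C = (H_a / L_a) / (H_b / L_b),

where H counts confident reads (rating ±2) and L equivocal ones (−1/0/+1),
with Pearson χ² on the 2×2 method-agreement tables, two-way random-effects
ICC(2,1)/ICC(2,k) for absolute agreement, and majority-vote surrogate
truth. SUV-based classification uses the empirical ROC (AUC = Mann–Whitney
pair statistic), the Youden index J = max(sens + spec − 1) with its
associated "SUV > c" criterion, Hanley–McNeil and DeLong standard errors,
DeLong paired AUC comparison, BCa bootstrap intervals and Clopper–Pearson
exact binomial intervals.

## Worked example

```r
library(zonespect)

# published reader-confidence table: R_C and chi-squared per stratum
fx <- confidence_analysis(reader_confidence_counts())
fx[, c("question", "ct", "h_xb", "l_xb", "h_f3d", "l_f3d", "r_c", "chi2")]
#>         question      ct h_xb l_xb h_f3d l_f3d   r_c  chi2
#> 1      detection without 1406  646  1244   808 1.414 594.5
#> 2      detection    with 1505  547  1425   627 1.211 704.3
#> 3 classification without  548 1042   235  1355 3.032 124.4
#> 4 classification    with  976  666   863   779 1.323 377.5

# simulate a small bone study end to end: phantom -> projections -> noise ->
# scatter -> zones -> three reconstructions -> calibration -> SUV -> lesions
rep <- run_pipeline(default_pipeline_config(seed = 1, n_updates = 16))
rep$lesions[, c("variant", "lesion_id", "volume_ml", "mean_value", "max_value")]
#>   variant lesion_id volume_ml mean_value max_value
#> 1     F3D         1      5.72       5.04      7.05
#> 2     F3D         2      3.04       3.94      4.51
#> 3    CGAS         1      5.72       5.23      7.37
#> 4    CGAS         2      3.04       4.09      4.73
#> 5   CGZAS         1      5.72       5.38      7.94
#> 6   CGZAS         2      3.04       4.15      4.87

# SUV-threshold ROC on a synthetic lesion population
les <- make_lesion_population(lesion_population_spec(400, seed = 8))
ts <- threshold_study(les)
sprintf("unstratified: AUC %.3f, J %.3f, criterion SUV > %.2f",
        ts$none$auc, ts$none$j, ts$none$criterion)
#> "unstratified: AUC 0.939, J 0.725, criterion SUV > 8.51"
```

The reader-confidence table shows the zonal method (xB) producing confident
reads about three times as often as the reference (F3D) when classifying
lesions without CT (R_C = 3.03), shrinking to 1.32 once CT is shown — the
anatomical information in the reconstruction substitutes for part of what
readers otherwise extract from the fused CT. In the simulated study the
zonal reconstruction (CGZAS) recovers the highest mean and maximum SUV in
both small bone lesions, the expected consequence of its edge-preserving
5 mm bone smoothing versus the 10 mm isotropic smoothing of the other
variants. The ROC block turns a synthetic lesion population with lognormal
class SUV distributions into an operating point: the Youden-optimal rule
calls lesions above SUV 8.51 malignant.

The same steps are scriptable from a shell through the thin CLI wrapper in
`inst/cli/zonespect.R` (`run`, `phantom`, `concordance`, `roc` subcommands).

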