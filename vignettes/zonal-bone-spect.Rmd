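---
title: "Zonal bone SPECT: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zonal bone SPECT: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Planar and conventional SPECT bone scans with Tc-99m diphosphonates show
tracer uptake at sites of bone turnover, but the reconstructed images are
smooth and poorly localized relative to the underlying anatomy. When a CT is
acquired alongside the SPECT, its high-resolution attenuation information
can do more than correct for photon attenuation: a threshold segmentation of
the 140 keV attenuation map into tissue classes ("zones") provides sharp
anatomical boundaries that a reconstruction can respect, so that bone uptake
is not smeared into adjacent soft tissue. `zonespect` implements a complete,
desk-scale model of this idea — phantom simulation, projection physics,
zone-aware reconstruction, absolute quantification — together with the
statistical machinery used to evaluate such reconstructions in reader
studies: confidence likelihood ratios, contingency chi-squared, intraclass
correlation, majority-vote surrogate truth, and SUV-threshold ROC analysis.

## Forward model

The projector is rotation-based. For each of the `n_views` angles (default
120 over 360 degrees) the activity volume is rotated in-plane so the
detector lies along a fixed axis, attenuated voxel-by-voxel toward the
detector, blurred slab-by-slab with the distance-dependent collimator
response, and summed along the ray axis:

* **Rotation.** Bilinear interpolation, as a sparse matrix per view. The
  forward model uses the *transpose* of the sampling matrix (splatting):
  its column sums are exactly 1 in the interior, so total counts are
  conserved per view to machine precision when attenuation is off. The back
  projection uses the sampling matrix itself, making the projector pair an
  exact adjoint by construction — the property every MLEM-type algorithm
  needs, and the first thing the test suite checks.
* **Attenuation.** Discrete Beer–Lambert accumulated at voxel resolution
  from each voxel to the detector, with a half-voxel self-attenuation
  convention (the emitting voxel contributes half its own attenuation
  length).
* **Collimator response.** A Gaussian whose FWHM grows with distance `d`
  from the collimator face, `FWHM(d) = sqrt(f0^2 + (s d)^2)` with defaults
  `f0 = 3.8` mm and `s = 0.047` (about 7.4 mm at 10 cm, typical of an LEHR
  collimator; the true response of the clinical collimator is unpublished,
  so these are declared, configurable assumptions). Inside the system model
  the convolution matrices are symmetric with zero padding — self-adjoint,
  which keeps the adjoint identity exact; kernel mass lost at the detector
  rim is the price, visible only within 4 sigma of the edge.
* **Scaling.** Expected counts are activity (Bq per voxel) times system
  sensitivity (cps/Bq) times dwell time, so a point-source acquisition
  calibrates the chain end to end.

The acquisition defaults mirror a clinical bone protocol: 2.4 mm isotropic
pixels, a nominal 256 detector matrix, 20 s per view, a 15% peak window with
an adjacent 15% lower scatter window. Projections are sampled on the volume
grid, so the detector pixel must equal the voxel size.

## Scatter

Scatter is estimated with the dual-energy-window convention: the scatter
projection estimate (SPE) is `k * (width_peak / width_lower)` times the
lower-window counts, with `k = 0.5` (the classic factor; the clinical
chain specifies the windows but not `k`, so it is configurable), smoothed
per view with a 15 mm FWHM 2-D Gaussian to limit noise propagation. The
smoothing kernel is renormalized at the borders to be mass-preserving
(column-stochastic), avoiding rim bias in the SPE. Because the chain is
linear, smoothing after scaling equals scaling after smoothing; the code
smooths after scaling. The SPE enters all reconstructions identically, as
the additive term in the Poisson mean `A x + s`.

The package also *generates* lower-window data for testing: a fraction
(default 0.35) of the expected peak counts, broadened by a 30 mm FWHM
Gaussian and Poisson-sampled. This is a generative stand-in, not a physics
model — adequate for exercising the estimator, not for studying scatter
physics.

## Zone maps

The 140 keV attenuation map is segmented into five classes — 1 lung/air,
2 adipose, 3 soft tissue, 4 spongy bone, 5 cortical bone — by thresholds at
0.07, 0.147, 0.165 and 0.230 cm^-1, chosen to bracket the canonical tissue
coefficients (0.03, 0.140, 0.153, 0.190, 0.280 cm^-1); the commercial
thresholds are unpublished, so these are configurable package defaults. The
conversion is smooth: within ±0.01 cm^-1 of a boundary, membership mixes
the adjacent classes through a cubic smoothstep, exactly 0.5/0.5 at the
boundary. Memberships are built telescopically from the per-boundary
step functions, so they always lie in [0, 1] and sum to 1 even where
transition bands overlap — which they do, by a small margin, between the
adipose|soft (0.147) and soft|spongy (0.165) boundaries at the default
half-width: with these defaults no attenuation value maps to *pure* soft
tissue (maximum membership ≈ 0.99). This is a documented consequence of the
chosen defaults, not an error; narrow the half-width if pure memberships
matter. Zone maps on a finer CT grid are brought to the reconstruction grid
by integer block averaging (each SPECT voxel containing a whole number of
CT voxels), which preserves the partition of unity.

"Bone" for all zonal masking means dominant zone 4 or 5.

## Reconstruction variants

All three variants maximize the same Poisson log-likelihood
`sum(y log(Ax + s) - (Ax + s))`:

* **OSEM** (the reference method): the standard multiplicative update
  `x <- x / (A_k' 1) * A_k'(y_k / (A_k x + s_k))` over interleaved view
  subsets. The default is one subset, for which each update provably does
  not decrease the likelihood. Post-smoothing: isotropic 10 mm Gaussian.
* **CGAS**: Polak–Ribière nonlinear conjugate gradient with an
  EM-preconditioned gradient (`precond = x / A'1`), so the first step from
  a uniform start *is* an EM step; a monotone expanding/backtracking line
  search; nonnegativity by projection onto the feasible set. One CG update
  is empirically worth about four OSEM updates in likelihood, which the
  tests check directionally (12 CG updates reach at least the likelihood of
  48 OSEM updates). The commercial CG algebra is unpublished; this
  construction is the package's own, chosen to reproduce the stated
  OSEM-to-CG update-rate relationship.
* **CGZAS**: CGAS plus zone information, in two places: a gentle zonal
  smoothing between CG iterations (regularization; default FWHM half the
  post-smoothing values) and an edge-preserving zonal post-smoothing, 5 mm
  inside bone-dominant voxels and 10 mm elsewhere. Whether the clinical
  implementation regularizes inside iterations, only at the end, or both is
  not specified; both hooks exist here and both are on by default, each
  independently switchable.

The update count follows the total-count rule: 48 updates at or above
6 Mc total counts, 24 below (the boundary itself is taken inclusive, since
the published rule covers ">" and "<" but not "=").

### Masked smoothing that conserves, reproduces constants, and preserves edges

The zonal smoothing operator has to satisfy three properties at once: no
intensity may cross the bone/non-bone boundary, a constant within a set
must be reproduced (otherwise smoothing would bias uniform uptake), and the
total activity within each set must be conserved (otherwise smoothing would
destroy quantification). A masked kernel renormalized over rows gives the
second property; renormalized over columns, the third; to get both, the
masked Gaussian kernel is made symmetric *doubly stochastic* by a Sinkhorn
diagonal scaling (`d * K(d x)` with `d` solving `d * K d = 1`, converged to
1e-12). Because the kernel is truncated at 4 sigma, the scaling is exactly 1
farther than the truncation radius from any boundary, where the operator
coincides with the plain Gaussian. The non-zonal post-smoothing uses the
same operator with an all-true mask, so on a single-zone phantom the zonal
and non-zonal variants are *identical* given equal FWHM — a test, and the
reason the interior-uptake comparisons between variants are clean. A
practical consequence of the same-zone kernel renormalization is an
implicit partial-volume-correction-like behavior: small bone lesions keep
their counts inside bone instead of bleeding into soft tissue, which is why
the zonal variant recovers at least the non-zonal mean in small
(≤ 6 ml) bone lesions — asserted directionally in the tests.

## Quantification

A point-source acquisition (nominal 111 MBq reference source, stated
accuracy ±3% at 99% CL) calibrates the system sensitivity as total detected
count rate per unit activity. Reconstructions run with unit sensitivity
come out in cps/ml; dividing by the calibrated sensitivity and
decay-correcting to injection time (`2^(dt/T_half)`, Tc-99m
`T_half = 6.0067 h`) yields Bq/ml. Body-weight SUV is
`concentration * body_weight / injected_dose` with density 1 g/ml, so a
uniform distribution of the dose over the body mass gives SUV 1 everywhere.

Lesions are ellipsoid VOIs (axis-aligned, voxel-center containment).
Within a VOI, voxels at or above 50% of the VOI maximum form the lesion
segment (the threshold is inclusive so the maximum voxel always survives);
the record carries segmented volume (ml = cm^3 exactly), mean and maximum.
The mean over the segmented region — not the whole VOI — is the reported
SUV_mean, the convention implied by the 50%-threshold segmentation. No
partial-volume correction is applied anywhere, deliberately.

## Reader-study statistics

Five-point confidence ratings (-2..+2) collapse to confident
(`|r| = 2`, "H") versus equivocal (-1/0/+1, "L"). The confidence likelihood
ratio between methods a and b is `R_C = (H_a/L_a) / (H_b/L_b)`;
`R_C(a,b) * R_C(b,a) = 1` identically. The packaged fixture table of
published contingency counts reproduces all four printed R_C values
(3.03, 1.41, 1.21, 1.32 at 2 decimals) — that computation is what
`scripts/acceptance.R` re-runs.

For the 2x2 correlation tables both the uncorrected Pearson chi-squared and
the Yates-corrected one are computed. The published values (704, 124, 378)
match the *uncorrected* statistic despite being labeled Yates-corrected in
their source; the package exposes both and the fixture tests assert the
uncorrected ones. Intraclass correlation for absolute agreement is the
two-way random-effects ICC(2,1)/ICC(2,k) from ANOVA mean squares with
F-based confidence intervals (average-measures limits stepped up by
Spearman–Brown). Surrogate truth is the strict majority over per-reader
binary calls (rating sign; zeros abstain), with ties flagged
"needs consensus" rather than resolved silently.

The generative reader model behind `simulate_rating_study()` is
deliberately minimal — per-variant probabilities of a confident read and of
a correct call, independent across cells. It exists to exercise the
concordance pipeline with known ground truth, not to model reader
psychology, fatigue or learning; passing those tests says the statistics
are computed correctly, not that real readers behave this way.

## ROC machinery

Scores are oriented "higher SUV = more malignant" and criteria reported as
"positive if SUV > c". The AUC is computed as the Mann–Whitney pair
statistic (ties count one half) and is tested against exhaustive pair
counting; the Youden criterion `J = max(sens + spec - 1)` is searched over
observed score values (ties broken toward the smaller criterion, i.e.
higher sensitivity) and tested against brute force. Standard errors come
from the Hanley–McNeil closed form and from DeLong placement values; paired
AUC comparisons use the DeLong covariance of the structural components.
Confidence intervals for J and the criterion are BCa bootstrap (default
1000 resamples, seeded); sensitivity/specificity intervals are
Clopper–Pearson. The stratified threshold study applies the
location/volume strata (all; not-joint; joint; not-joint ≤ 6 ml;
not-joint > 6 ml), with lesions of exactly 6 ml assigned to the "≤"
stratum. On synthetic populations with lognormal class SUVs the recovered
criterion is checked against the analytic density-crossing point
(`exp((m1+m2)/2)` for equal sdlog).

## What the synthetic generator does and does not emulate

The phantom module produces axis-aligned ellipsoids on isotropic grids with
voxel-center rasterization (activity totals exact to one-voxel
discretization, by construction), canonical per-class attenuation values,
lognormal lesion SUV and volume distributions with the study's class mix
(40% malignant, 40% benign, 10% questionable, 10% negative controls), and
seeded reader ratings. It does not emulate anthropomorphic anatomy,
respiratory or patient motion, non-circular orbits fitted to a body
contour, septal penetration, or detector dead time. Tests passing on these
phantoms validate the algebra and the statistics; claims about clinical
image quality are outside what this package can show.

## Numerical choices and problem sizes

Interpolation is bilinear with zero padding outside the field of view;
attenuation uses the half-voxel self-attenuation convention; PSF kernels
truncate at 4 sigma; Sinkhorn scaling converges to 1e-12; OSEM initializes
from a uniform positive image scaled to the total counts; CG restarts on
non-ascent directions; the line search expands up to 16x and backtracks up
to 25 halvings. Voxel isotropization after reconstruction is an identity
hook here because all grids are generated isotropic; anisotropic input is
rejected rather than silently resampled.

The test suite and the examples run on 20^3–48^3 grids with 12–60 views —
sizes chosen so the whole suite completes in a few minutes on one CPU while
every property (adjointness, monotonicity, fixed points, conservation,
recovery) is scale-free. The clinical 256-matrix geometry is reachable
through the same configuration objects; nothing in the code is specialized
to the small sizes.

## Known limitations

The CG algebra, the zone thresholds, the collimator response and the
dual-window scale factor are declared assumptions where the clinical chain
leaves them unpublished. The scatter simulator is generative, not physical.
Reconstruction-grid detector sampling ties the detector pixel to the voxel
size. DICOM, CT reconstruction, SPECT–CT registration and motion correction
are out of scope; volumes are assumed co-registered on a common grid.
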