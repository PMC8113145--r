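---
title: "Methods: sequential perfusion MRI and dynamic FET PET classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential perfusion MRI and dynamic FET PET classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwifet)
```

## The diagnostic problem and the model

After radio-chemotherapy of glioma, new or growing contrast enhancement can
be true tumor progression (TP) or treatment-related change (TRC). `pwifet`
implements a two-modality quantitative workup: dynamic susceptibility
contrast (DSC) perfusion MRI summarized as the hotspot relative cerebral
blood volume (rCBVmax), and dynamic amino-acid ([18F]FET) PET summarized as
tumor-to-brain ratios (TBRmean, TBRmax), time-to-peak (TTP, min) and the
late slope of the time–activity curve (SUV/h).

The classifier is deliberately sequential rather than multivariable. High
perfusion above an ROC-derived cutoff is highly specific for TP (recurrent
tumor is hypervascular; treatment effects rarely are), so stage 1 calls TP
whenever `rCBV_max > rcbv_cut` and commits no one to TRC. Patients below
the gate — where perfusion is uninformative, since gliomas can lack
hypervascularity — fall through to stage 2, which exploits the high
sensitivity of amino-acid PET: TP is called if `TBR_max > tbr_cut` **or**
`Slope < slope_cut` (washout indicates active tumor), TRC otherwise. All
three comparisons are strict; values exactly at a cutoff do not cross it.

## DSC quantification

Signal is converted to transverse relaxivity change
`dR2*(t) = -log(S(t)/S0)/TE`, with `S0` the mean over a pre-bolus baseline
window. The Boxerman–Weisskoff leakage model regresses the tumor curve on
the average nonenhancing reference curve and its running integral,

`target(t) = K1 * ref(t) - K2 * R(t)`,   `R(t) = ∫0..t ref`,

solved as closed-form 2×2 linear least squares (QR; a rank-deficient
design, e.g. a constant reference, raises a degenerate-fit error). The
corrected curve is `target + K2*R`: for T1-dominant leakage (`K2 > 0`,
depressed tail) correction restores blood-volume area, and the corrected
area is never smaller than the uncorrected one. CBV is the plain trapezoid
integral of `dR2*` over the whole post-baseline acquisition — a fitted
bolus model would be more elegant but is fragile at clinical SNR, and the
cutoffs downstream only require a consistent area convention. `rcbv_max`
is the mean of the `k` largest per-voxel CBV values in the tumor mask
(default `k = 10`, emulating a small visually placed hotspot ROI whose
exact size the clinical protocol leaves open) divided by the mean over an
equally sized contralateral ROI supplied by the caller (placement is a
manual, anatomical act we do not automate). All frame windows in the R
interface are 1-based inclusive index vectors, the natural R convention.

Everything here is invariant to global signal scaling, which the tests
exercise; `K2` carries units 1/s, `K1` is the dimensionless blood-volume
ratio.

## PET parameterization

`SUV = activity [Bq/g] * weight [g] / injected activity [Bq]`. TBRs are
ratios of frame-averaged tumor to frame-averaged background SUV over the
20–40 min window (the standard late uptake period for static FET reading);
dose and weight cancel. TTP is the frame mid-time of the tumor curve
maximum, ties resolving to the earliest frame. Slope is the
equally-weighted OLS slope of tumor SUV against time over frames with
mid-times in [20, 40] min, scaled to SUV/h; frames are weighted equally
because frame durations are not part of the input contract. At least two
frames must fall in the window.

## Cutoffs, inference, validation

Candidate thresholds sit at midpoints between consecutive distinct scores
(plus infinite endpoints). The working criterion is the **product** of
sensitivity and specificity, maximized over finite thresholds; criterion
ties break toward higher specificity, then the lower threshold. The
product criterion is not the Youden index: the test suite contains a small
instance where the product selects sens 0.9/spec 0.58 while Youden prefers
sens 0.5/spec 1.0. (One can show the product criterion can never *prefer*
a spec-1.0 point that Youden rejects — the disagreement always runs the
other way.) Lower-positive parameters (Slope) are negated internally and
their cutoffs reported back on the original scale.

AUC is the trapezoid area, identical to the midrank Mann–Whitney
`U/(n1*n2)` (a tested invariant); its CI and p value against 0.5 use the
DeLong placement-value variance — assumption-light and standard, though
printed intervals from other software may differ in the third decimal.
Proportions get Clopper–Pearson exact intervals (conservative coverage at
the small subgroup sizes involved, 21–104); rates with zero denominator
are reported as undefined rather than imputed. Group comparisons use the
Mann–Whitney U test via `stats::wilcox.test` (exact enumeration for
tie-free samples up to n = 12, otherwise the tie-corrected normal
approximation with continuity correction). Two-sided tests throughout.

`fit_cutoffs()` derives all three cutoffs independently on the **full**
training cohort; stage 2 applies the globally fitted PET cutoffs to the
stage-1 remainder rather than refitting on that subset — that matches the
clinical procedure being modeled and avoids optimizing on a selected
subsample. `loocv()` refits all three cutoffs on every fold of n−1
patients and classifies the held-out patient; this validates the entire
fitting procedure, not just the frozen thresholds. Folds whose training
set loses a class are skipped with a warning. Missing parameter values are
rejected, never imputed. Subgroup analyses (e.g. by IDH status) are plain
row filters ahead of the same machinery.

## What the synthetic generator emulates

`gen_parameter_cohort()` draws class-conditional parameter values
calibrated so each within-class median and *unscaled* MAD
(`median(|x - median(x)|)`, no 1.4826 factor — the convention of the
clinical summary tables) match published cohort summaries. Strictly
positive parameters are lognormal — `lognormal_from_median_mad()` fixes
`mu = log(median)` and bisects `sigma` until the interval median ± MAD
carries probability 1/2, to 1e-8 absolute tolerance on that probability
(a tolerance on `sigma` alone is insufficient near the degenerate
`sigma -> 0` limit). Slope, which is negative under washout, is normal
with `sd = mad/qnorm(0.75)`. Within-class dependence between rCBVmax,
TBRmax and TBRmean uses a latent Gaussian copula whose correlations are
back-calculated from the lognormal moment formula so the *observed*
Pearson r hits its target (defaults 0.55 for rCBVmax–TBRmax, 0.93 for
TBRmax–TBRmean, the published cross-modality and redundancy
correlations); Slope and TTP are drawn independently. The
`binormal_auc` family places both classes as unit-variance normals with
mean separation `sqrt(2)*qnorm(AUC)`, making a target AUC exact by
construction — this is what the AUC-recovery checks rely on.

Curve-level generators mirror the estimation models exactly: the DSC
simulator uses a gamma-variate bolus (defaults: arrival at frame 10,
shape 3, scale 1.5 frames, peak 10 1/s on a 50-frame, TE 0.032 s,
TR 1.9 s acquisition — the clinical protocol fixes only frame count and
TE/TR ranges, and any smooth unimodal bolus serves the correction
algebra) plus the `-K2*R(t)` leakage term, so at zero noise `bw_fit()`
recovers `K1`/`K2` to machine-level accuracy and the corrected area
equals the true leakage-free area. Noise is additive Gaussian on signal,
not Rician: the leakage fit is linear, so the noise family is not
structural, and at perfusion SNR the difference is negligible. The PET
simulator makes the 20–40 min segment exactly linear and scales a
constant background to the requested TBR, so `pet_params()` round-trips
its truths to 1e-9; an optional `peak_time` instead places an exact
unimodal peak (overriding the slope prescription — both cannot hold at
once within a linear late phase).

A deterministic 104-patient cohort, `gen_fig4_fixture()` (83 TP / 21
TRC), is engineered at ±0.1 margins around the cutoffs (2.85, 1.95,
0.69): 44 TP above the rCBV gate, then 37 TP + 12 TRC PET-positive and
2 TP + 9 TRC PET-negative among the 60 below it. Those placements force
the complete published flow arithmetic (stage counts 44/60/49/11, overall
accuracy 90/104 → 87%, sensitivity 81/83 → 98%, specificity 9/21 → 43%,
stage-2 sensitivity 37/39 and NPV 9/11) and — because every parameter
takes exactly two values — make refitting on the fixture return the
cutoff midpoints themselves. No value ever ties with a cutoff, keeping
the strict-inequality rule unambiguous.

What the generator does **not** emulate: image space (no 3D anatomy,
registration, motion, partial-volume or arterial-input effects), scanner
or field-strength differences, frame-duration weighting, reader
variability in ROI placement, or any dependence between a patient's
parameter noise and their class beyond the marginal distributions. Tests
passing on these cohorts therefore demonstrate correctness of the
estimators, the cutoff machinery and the classifier logic — not clinical
performance on real data, and the engineered-cohort metrics are forced by
construction, not evidence of generalization.

## Numerical choices and display

Reports round rates half away from zero (2 decimals; headline accuracies
as integer percent) so that 0.625 displays as 0.63 and 86.5% as 87%,
while JSON output keeps full precision. Degenerate inputs are first-class:
constant parameters yield an undefined-cutoff row in the performance
table instead of an error; a ±Inf rCBV gate reduces the sequential rule
to the PET-only rule or an everyone-TP call; `p_exp = 1` defines Cohen's
kappa as 1; all-identical Mann–Whitney samples return `U = n1*n2/2`,
`p = 1`.

Problem sizes in the test suite are chosen to keep every stochastic check
decisively inside its tolerance at interactive runtimes: 10^6 draws for
the calibration round trip (median/MAD to 1%), 10^4 per class for AUC and
correlation recovery (±0.01 / ±0.02), 200 replicates for the noisy
leakage fit (5% peak noise, K2 bias under 10%), and 2,000 simulated
binomials for interval coverage at n ∈ {21, 60, 83, 104}.

## Known limitations

Cutoff values are dataset- and toolbox-specific: the integration window,
hotspot size and leakage-correction details all shift them, so fitted
cutoffs should be recalibrated per site rather than transplanted. The
product-of-sens-and-spec criterion ignores prevalence and misclassification
costs. LOOCV validates threshold refitting but not ROI placement or
acquisition variability. The package neither segments images nor models
tracer kinetics compartmentally; inputs arrive as ROI-level curves or
parameter tables.
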