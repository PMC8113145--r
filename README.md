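# pwifet

Distinguishing true glioma progression (TP) from treatment-related changes
(TRC — pseudoprogression, radiation necrosis) is a routine dilemma after
radio-chemotherapy: both enhance on contrast MRI. `pwifet` implements a
quantitative two-modality workup for this decision and the statistical
machinery to calibrate and validate it:

* **DSC perfusion MRI.** Dynamic susceptibility contrast signal curves are
  converted to transverse-relaxivity changes, ΔR2\*(t) = −ln(S(t)/S₀)/TE,
  leakage-corrected with the Boxerman–Weisskoff linear model
  (ΔR2\*<sub>tumor</sub>(t) ≈ K1·ΔR2\*<sub>ref</sub>(t) − K2·∫ΔR2\*<sub>ref</sub>),
  and integrated into cerebral blood volume. The hotspot tumor CBV over an
  equally sized contralateral normal-appearing ROI gives
  rCBV<sub>max</sub> = CBV<sub>tumor</sub>/CBV<sub>normal</sub>.
* **Dynamic [¹⁸F]FET PET.** Time–activity curves yield the standardized
  uptake value (SUV = activity · weight / injected dose), mean and maximum
  tumor-to-brain ratios (TBR<sub>mean</sub>, TBR<sub>max</sub>),
  time-to-peak (TTP), and the late washout slope — the OLS trend of tumor
  SUV over 20–40 min post-injection, in SUV/h.
* **Sequential classifier.** Cutoffs are chosen on ROC curves at the
  maximum of sensitivity × specificity. Stage 1 calls TP when
  rCBV<sub>max</sub> exceeds its high-specificity cutoff; everyone else
  goes to stage 2, which calls TP when TBR<sub>max</sub> is above its
  cutoff **or** the Slope is below its cutoff, and TRC otherwise.
  Performance is reported with exact binomial (Clopper–Pearson) intervals,
  AUCs with DeLong inference, and the whole fitting procedure is validated
  by leave-one-out cross-validation (cutoffs refitted per fold).

Patient-level inputs are CSV parameter tables (or ROI-level DSC/PET curve
files); a synthetic-cohort module generates parameter tables calibrated to
published class-conditional medians/MADs, curve-level DSC boluses with
leakage, and PET time–activity curves, so the full pipeline runs and is
tested end-to-end without any clinical data.

## Worked example

```r
library(pwifet)

coh  <- gen_parameter_cohort(cohort_config(n_tp = 83, n_trc = 21, seed = 1))
cuts <- fit_cutoffs(coh)
flow <- evaluate_flow(coh, cuts)
print(flow)
#> Sequential PWI + PET classification flow
#>   cutoffs: rCBVmax > 2.606, TBRmax > 1.809, Slope < 0.5196 SUV/h
#>   cohort                     n = 104
#>   stage 1: called TP         n = 60 (spec 0.81, PPV 0.93)
#>   stage 1: left unclassified n = 44
#>   stage 2: called TP         n = 31
#>   stage 2: called TRC        n = 13  (stage-2 acc 68%, sens 0.81, NPV 0.62)
#>   overall: acc 83%, sens 94%, spec 38%

cv <- loocv(coh)
#> LOOCV: accuracy 0.808, sensitivity 0.940, specificity 0.286
```

The flow report reads like the clinical decision path: of 104 simulated
patients, 60 exceed the fitted rCBV<sub>max</sub> gate and are called TP
immediately; the combined PET rule splits the remaining 44 into 31 TP and
13 TRC calls. Overall accuracy (83%) is driven by high sensitivity (94%)
at modest specificity — exactly the asymmetry the sequential design
trades on. Held-out accuracy (81%) sits a little below resubstitution, as
expected when cutoffs are refitted per fold. Per-parameter ROC summaries
come from `cohort_performance(coh)` (medians, MADs, Mann–Whitney p, AUC
with CI, optimal cutoff, confusion block).

A deterministic 104-patient cohort whose values are engineered around the
cutoffs (2.85, 1.95, 0.69) is available as `gen_fig4_fixture()`; running
`evaluate_flow()` on it with those cutoffs produces stage counts
44/60/49/11, overall accuracy 87% and sensitivity 98%, and stage-2 NPV
0.82.

A thin command-line wrapper over the same functions lives at
`inst/cli/pwifet` (subcommands `simulate`, `fixture`, `dsc`, `pet`,
`fit`, `classify`, `evaluate`, `loocv`).

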