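# rtdecide

Decision support for breast radiotherapy planning: should this patient
be treated with opposed tangential fields (3D-CRT) or with
intensity-modulated radiotherapy (IMRT)?

Clinically the preferred policy is *3D-CRT by default, IMRT only when
the conformal plan cannot meet the organ-at-risk constraints* — but
whether it can is normally only known after a plan has been made.
`rtdecide` short-circuits that loop: a 2D U-Net regresses the per-slice
absolute dose distribution of **both** candidate techniques directly
from the CT slice and the structure masks (body, ipsilateral lung,
heart, breast PTV, nodal PTV), dose–volume histogram (DVH) metrics are
extracted from the predicted volumes, and the clinical constraint set

* ipsilateral lung V20Gy < 30 %
* heart V25Gy < 10 %
* mean heart dose < 3 Gy (all comparisons strict)

selects the technique. Recommendations are validated against
ground-truth labels with a 2×2 confusion matrix (3D-CRT as positive
class) and accuracy / recall / precision / F1.

The package is self-contained and fully testable at desk scale: it
ships a synthetic thorax-phantom cohort generator with paired analytic
3D-CRT/IMRT dose engines (two emulated institutions differing in slice
thickness, 3.75 mm vs 3 mm, node-positive fraction and complexity mix),
the full data-preparation chain (dose renormalization to
2 Gy × 25 fx = 50 Gy, body-fitting crop, nearest-neighbour resampling
to a fixed square, patient-level k-fold splitting), the U-Net regressor
with from-scratch and fine-tuning (transfer) training regimes — the
forward/backward passes and Adam loop are implemented in compiled code
inside the package — and the DVH / isodose-Dice evaluation and decision
modules. See `vignettes/methods.Rmd` for the models, engine equations
and design choices.

## Worked example

```r
library(rtdecide)

## 1. a small synthetic cohort from the 3D-CRT-only institution
spec   <- cohort_spec(n_cases = 12, institution = "inst1", seed = 3)
cohort <- generate_cohort(spec)
print(cohort)
#> <phantom_cohort> inst1: 12 cases (8 3DCRT / 4 IMRT labels)

## 2. patient-level cross-validated U-Net training on the 3D-CRT doses
prep <- prep_config(target_size = c(64, 64))
cfg  <- dosenet_config(input_channels = 6, base_filters = 16, depth = 3)
ctl  <- dosenet_control(epochs = 20, batch_size = 16, seed = 1)
cv <- run_cross_validation(cohort, "3DCRT", k = 2, prep = prep,
                           config = cfg, control = ctl,
                           regime_name = "ModelA")
print(cv$models[[1]])
#> 2D U-Net dose regressor (from_scratch)
#>   depth 3, base filters 16, separable encoder, 6 input channels, 115,799 parameters
#>   trained 20 epochs on 60 slices (64x64)
#>   training MSE: 171.750 -> 20.763 Gy^2

## 3. out-of-fold isodose agreement (Dice over the 30-70% band)
dsc <- cv_dsc_summary(cv, band = c(30, 70))
round(mean(dsc$band_mean), 3)
#> [1] 0.887

## 4. DVH metrics of a predicted volume
e <- cohort[[1]]
pred <- cv$predictions[[e$case$case_id]]
extract_metrics(pred, e$case$masks$heart, prescription = 50,
                structure = "heart", spacing = e$case$spacing)
#> <dvh_metrics> heart (402 voxels): Dmean 20.22 Gy, D95 0.00 Gy, V95 13.2%, V20Gy 45.3%, V25Gy 40.0%

## 5. a technique recommendation from per-technique metrics
e <- cohort[[4]]
oar <- function(dm) list(
  lung  = extract_metrics(dm, e$case$masks$lung_ipsi, 50, "lung_ipsi", e$case$spacing),
  heart = extract_metrics(dm, e$case$masks$heart,     50, "heart",     e$case$spacing))
recommend(oar(e$dose_crt), oar(e$dose_imrt), case_id = e$case$case_id)
#> <decision> inst1_case004: IMRT (3D-CRT pass: FALSE, IMRT pass: TRUE)
#>  technique  constraint observed threshold
#>      3DCRT heart_Dmean 6.122561         3

## 6. scoring decisions against ground truth
classification_report(confusion_from_counts(22, 2, 1, 5))
#> accuracy 90.0%  recall 95.7%  precision 91.7%  F1 93.6%
```

Reading the output: the mean out-of-fold Dice of 0.89 says the
predicted and reference 30–70 % isodose volumes overlap well even with
only six training patients per fold; case 4's conformal plan breaches
the 3 Gy mean-heart limit (6.12 Gy) while its IMRT plan passes, so the
framework escalates that patient to IMRT; and a decision set with 22
true 3D-CRT, 2 false 3D-CRT, 1 missed 3D-CRT and 5 true IMRT scores
90 % accuracy with 95.7 % recall for the conformal class.

A thin command-line wrapper for cohort simulation and batch decisions
is in `inst/cli/rtdecide.R` (`simulate` and `decide` subcommands).

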