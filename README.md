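# punctasurv

Longitudinal single-neuron survival analysis and coefficient-of-variation
(CV) aggregate scoring for two-channel fluorescence time-lapse microscopy,
with a ground-truthed synthetic movie generator so the whole pipeline runs
and is tested without any microscope data.

## The problem

Automated longitudinal microscopy follows individual transfected neurons
for ten daily imaging sessions. A constitutive cell-fill fluorophore (the
*tracking* channel) marks each cell and reports its death as loss of
signal; a GFP-tagged reporter (the *reporter* channel) is either diffusely
distributed or concentrated into inclusions. Two quantitative questions
drive the analysis:

1. **Which neurons carry aggregates?** The CV of reporter intensity within
   a cell's ROI — population standard deviation over mean — is low for
   diffuse cells and high for punctate cells. A threshold of CV ≥ 1.0,
   calibrated by ROC analysis on a labelled validation set (50 ROIs per
   class), gives a sensitive and specific aggregate call; a neuron is
   aggregate-bearing if any live-timepoint ROI crosses the threshold.
2. **Does aggregation change survival?** Each neuron contributes a
   right-censored survival time (death interval × 24 h, censored at
   240 h). Cumulative risk of death, 1 − S(t), is estimated by
   Kaplan–Meier, and group and aggregate effects by a Cox
   proportional-hazards model fitted from first principles
   (Efron-corrected partial likelihood, Newton–Raphson, Wald and
   likelihood-ratio tests) — ties are pervasive because deaths land on
   the 24 h grid.

The package also provides Pearson and Manders (M1/M2, intensity-weighted
and pixel-count) colocalization for two-channel confocal images.

## What's inside

| Stage | Functions |
| --- | --- |
| Synthetic cohorts | `generator_config()`, `cohort_group()`, `sample_cohort()`, `render_movie()`, `generate_labeled_roiset()` |
| Imaging | `subtract_background()`, `segment_frame()`, `segment_movie()`, `link_tracks()`, `call_death()`, `compute_cv()`, `match_truth()` |
| Classification | `roc_curve()`, `youden_threshold()`, `classify_roi()`, `classify_neurons()`, `confusion_metrics()`, `calibrate_classifier()` |
| Survival | `build_records()`, `kaplan_meier()`, `cox_ph()`, `cox_fit()`, `wald_test()`, `lr_test()` |
| Colocalization | `pearson_r()`, `manders()` |
| Orchestration & I/O | `pipeline_config()`, `run_pipeline()`, `read_movie()`/`write_movie()` (multi-page TIFF), `read_tracks()`/`write_tracks()`, `read_records()`/`write_records()` |

The synthetic generator plants per-group aggregate probabilities and
per-interval death hazards (geometric on the 24 h grid), renders
flux-conserving diffuse vs punctate phenotypes with Poisson + Gaussian
noise, and is bit-reproducible from one root seed. See the methods
vignette (`vignettes/punctasurv-methods.Rmd`) for the model, parameter
meanings and design decisions.

## Worked example

```r
library(punctasurv)

cfg <- pipeline_config(generator_config(
  groups = list(cohort_group("control", 0, 0.02),
                cohort_group("CGG", 0.485, 0.04, 2.5)),
  n_neurons_per_group = 60, seed = 11))
report <- run_pipeline(cfg)
print(report)
```

```
Longitudinal survival pipeline report (seed 11)
Calibration: AUC 1.000, Youden threshold 1.026, applied 1.00, sens 100.0%, spec 100.0%
Group control    n =   58, deaths =   15, aggregate-bearing =   0.0%
Group CGG        n =   58, deaths =   27, aggregate-bearing =  36.2%

Cox group model:
Cox proportional-hazards fit (efron ties), n = 116, events = 42
               coef        se      HR  lower95  upper95        z      p
group=CGG 0.7801823 0.3224696 2.18187 1.159691 4.105022 2.419398 0.0155
Likelihood ratio test: 6.156 on 1 df, p = 0.0131

Aggregate-stratified Cox model,control: skipped (aggregate and diffuse classes not both present)

Aggregate-stratified Cox model, CGG :
Cox proportional-hazards fit (efron ties), n = 58, events = 27
                coef        se       HR   lower95  upper95        z      p
aggregated 0.6885363 0.3855573 1.990799 0.9350623 4.238523 1.785821 0.0741
Likelihood ratio test: 3.103 on 1 df, p = 0.0782

Excluded neurons: 0
```

Reading it: the classifier calibration on a 10-per-class labelled set
separated the classes perfectly with a Youden threshold of 1.03; none of
the 58 analyzable control neurons but 36% of the aggregation-prone
group's neurons were called aggregate-bearing; expressing the
aggregation-prone construct multiplied the death hazard by 2.2 (95% CI
1.2–4.1), and within that group aggregate-bearing neurons died at about
twice the rate of diffuse ones, not significant at this small cohort
size. The exclusion log accounts for every tracked neuron.

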