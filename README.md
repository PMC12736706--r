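# ppgbiom

Robust evaluation of photoplethysmography (PPG) based biometric
recognition.

Wearable devices measure PPG continuously, and the pulse waveform carries
enough person-specific morphology that a classifier can often tell enrolled
users apart. Reported recognition scores, however, are routinely inflated
by four evaluation shortcuts: laboratory-quality recordings, small user
populations, test sets containing only enrolled users, and train/test
splits that ignore time. `ppgbiom` is a toolkit for researchers who want to
measure — rather than assume away — the effect of each of those shortcuts.

It provides:

* a **synthetic multi-user, multi-day PPG cohort generator** with
  controllable difficulty (laboratory vs. real-world artifact/noise
  presets, day-to-day morphology drift, homogeneous vs. heterogeneous
  populations), so every protocol can run without access-restricted data;
* **two preprocessing chains**: cardiac/respiratory/blood-volume (AC/RS/DC)
  band decomposition, and detrend → systolic peak detection → quadratic-
  spline cycle standardisation → multicycle averaging;
* **two feature extractors**: a 38-value spectral/statistical + MFCC set,
  and a 160-value set (144 time-domain + 16 frequency-domain statistics
  over raw, FFT, Welch, db1/db4/sym4 wavelet components);
* **three model families**: a random-forest identifier, gradient-boosted
  identification and pair re-identification models, and a compact 1D
  Siamese convolutional re-identifier implemented in base R;
* an **evaluation harness**: multi-class Matthews correlation coefficient
  (MCC), balanced accuracy, uniform random baselines, random / temporal /
  leave-one-out split planners, user-count scaling and unseen-user
  protocols, exact one-sided Wilcoxon signed-rank comparisons with
  Bonferroni correction, and a guideline-adherence checklist.

The central metric is the multi-class MCC computed from the full confusion
matrix,

    MCC = (c·s − Σₖ pₖtₖ) / √((s² − Σₖ pₖ²)(s² − Σₖ tₖ²)),

with `c` the trace, `s` the sample count and `pₖ`, `tₖ` the predicted/true
marginals; it stays informative under the heavy class imbalance that
unseen-user and pairwise protocols create, and a constant or uniform-random
predictor scores 0 by convention.

## Worked example: how much does the real world cost?

Identify 10 synthetic users from 40 s windows (12 per user), first under
laboratory conditions, then under a naturalistic preset with motion
artifacts and extra noise — same users, same protocol:

```r
library(ppgbiom)

cohort <- synthesize_cohort(n_users = 10, n_days = 1, session_s = 480,
                            fs = 50, condition = "laboratory", seed = 1)
windows <- unlist(lapply(cohort, segment_record, window_s = 40),
                  recursive = FALSE)
length(windows)
#> [1] 120

report <- run_experiment(windows, method = "baseline_gbt",
                         split_kind = "random", n_seeds = 10)
report
#> <metric_report> baseline_gbt / random split (10 seeds)
#>   accuracy           0.992 +/- 0.004
#>   balanced_accuracy  0.993 +/- 0.004
#>   mcc                0.991 +/- 0.005

rw <- synthesize_cohort(10, 1, 480, 50, condition = "real_world", seed = 1)
rw_windows <- unlist(lapply(rw, segment_record, window_s = 40),
                     recursive = FALSE)
rw_report <- run_experiment(rw_windows, "baseline_gbt", "random", n_seeds = 10)
rw_report
#> <metric_report> baseline_gbt / random split (10 seeds)
#>   accuracy           0.831 +/- 0.016
#>   balanced_accuracy  0.842 +/- 0.025
#>   mcc                0.815 +/- 0.018

wilcoxon_one_sided(rw_report$per_seed$mcc, report$per_seed$mcc)
#> [1] 0.0009765625
```

The identical pipeline loses ~0.18 MCC points when the recordings become
naturalistic, and the seed-paired one-sided Wilcoxon test confirms the drop
(p ≈ 0.001). The numbers after `+/-` are standard errors over the ten
seeds.

Higher-level protocols follow the same pattern: `user_scaling_curve()`
traces MCC against the number of enrolled users, `unseen_user_eval()`
quantifies how a closed-set identifier degrades (and misassigns every
window) as strangers enter the test set, and `run_named_experiment()`
drives six config-file experiments end-to-end, including random- vs.
temporal-split comparisons on drifting multi-day cohorts. A thin CLI is
installed at `inst/cli/ppgbiom` (`synth`, `features`, `run`, `report`
subcommands).

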