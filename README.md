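# dexeeg

Quantifying the effect of a sedative drug on newborn cortical activity from
bedside EEG.

## The problem

Sedatives such as dexmedetomidine (DEX) are increasingly used in neonatal
intensive care, but their cerebral effects are hard to assess: visual review
of the EEG or of the compressed aEEG trend is subjective and insensitive to
subtle, individually varying changes. `dexeeg` implements a fully automated,
quantitative pipeline for four-channel neonatal EEG (F3, F4, P3, P4 against a
common reference, 250 Hz) recorded around a drug-administration timestamp,
aimed at clinical neurophysiologists and researchers studying drug effects in
the NICU.

Two computationally light features capture two distinct aspects of brain
function:

- **range-EEG (rEEG)** — the overall level of cortical activity. For
  non-overlapping 2-s windows, `rEEG = max(x) − min(x)` (peak-to-peak
  amplitude, µV), an objective analogue of the aEEG trend.
- **Activation Synchrony Index (ASI)** — cortico-cortical communication,
  measured as the co-occurrence of activity bursts (spontaneous activity
  transients) between two signals. Amplitude envelopes (1-s RMS) are
  quantized at their own quartiles, and

  `ASI = log2( I(A, B) / median I(A, B_shifted) )`

  where `I` is the mutual information of the paired quantized envelopes and
  the denominator is a circular-time-shift surrogate null. Independent
  channels score ≈ 0; larger values mean more burst co-occurrence.

The analysis design is a baseline-versus-post-drug contrast: a 12-min
baseline window and a 10-min post window, separated from the noted
administration time by 1-min gaps (the exact time is uncertain at the
bedside), each divided into 2.5-min epochs. Per subject and derivation, the
**delta value** = median(post epochs) − median(baseline epochs). The cohort
statistics layer is nonparametric (Spearman for delta-vs-baseline and
GA-vs-baseline, Wilcoxon rank sum for pre/post and fentanyl, Kruskal–Wallis
for diagnosis groups), restricted to an a-priori comparison plan. The
scientific question it answers: *is the drug-induced change proportional to
the activity level before administration?* — a negative delta-vs-baseline
correlation means higher pre-drug activity links to a stronger reduction.

Because clinical recordings cannot be redistributed, the package includes a
synthetic generator of discontinuous neonatal-like EEG (burst/interburst
renewal process, controllable interhemispheric synchrony, a step drug effect
proportional to the subject's normalized baseline, and injectable artifacts)
with full ground truth, so the entire pipeline is testable end to end.

## Worked example

Simulate a small cohort with a strong baseline-proportional drug effect
(slope 0.5: the highest-baseline subject loses half its burst amplitude) and
run the short-term analysis:

```r
library(dexeeg)

cfg <- sim_cohort_config(n_subjects = 8, duration_pre = 840,
                         duration_post = 780, sfreq = 100, rng_seed = 42)
cohort <- synthesize_cohort(cfg, drug_effect_slope = 0.5)

plan <- default_comparison_plan()
plan$reeg <- "P3-P4"; plan$asi <- "interhemispheric"
plan$primary <- c(rEEG = "P3-P4", ASI = "interhemispheric")

st <- cohort_short_term(cohort$recordings, plan = plan,
                        asi_par = asi_params(rng_seed = 1))
subset(st, feature == "rEEG")
#>   subject_id feature comparison baseline_median post_median  delta ...
#>          S01    rEEG      P3-P4            81.2        41.2 -39.94
#>          S02    rEEG      P3-P4            90.8        42.4 -48.41
#>          S03    rEEG      P3-P4            38.7        32.1  -6.54
#>          ...
#>          S08    rEEG      P3-P4            23.8        19.9  -3.88
```

Every delta is negative (the drug suppresses activity) and subjects who
started high (S02: 90.8 µV) drop far more than those who started low
(S08: 23.8 µV). The planned cohort statistics quantify exactly that:

```r
clin <- cohort$truth[, c("subject_id", "gestational_age_days",
                         "fentanyl", "diagnosis_group")]
res <- run_cohort_analyses(st, clin, plan)
res$stats[, c("test", "comparison", "statistic", "p_value")]
#>               test                          comparison statistic  p_value
#>           spearman           rEEG P3-P4 delta~baseline   -0.9762 0.000397
#>   wilcoxon_ranksum                 rEEG P3-P4 pre~post   52.0000 0.037918
#>           spearman ASI interhemispheric delta~baseline   -0.6667 0.083085
#>   wilcoxon_ranksum       ASI interhemispheric pre~post   58.0000 0.004662
#>           spearman              rEEG P3-P4 GA~baseline   -0.1429 0.752034
#>   ...
```

The rEEG delta-vs-baseline Spearman rho of −0.98 (p < 0.001) recovers the
generator's built-in proportional effect; the clinical covariates, drawn
independently of the EEG, stay non-significant. `plot_delta_scatter(res$scatter)`
and `plot_long_term_trend(cohort_long_term(...))` reproduce the standard
scatter and trend displays.

Recordings round-trip through standard EDF+ (`write_edf()` /
`read_recording()`, with the drug timestamp as a `DEX` annotation), and thin
command-line wrappers live in `inst/cli/` (`simulate.R`, `analyze.R`).

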