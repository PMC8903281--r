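# batkit

Scoring and group-level analysis for the Beat Alignment Test (BAT), the
two-part assessment of musical beat processing used with healthy and
clinical populations (including people with early-stage Parkinson's
disease): judging whether beeps overlaid on music fall **on the beat**,
and **tapping** in time with the beat.

The package covers the whole analysis path:

* **Stimuli** — beat grids and perturbed click tracks: phase shifts
  (beeps displaced by a fixed fraction of the inter-beat interval, IBI)
  and period shifts (beeps at a tempo off by a fixed percentage, so the
  misalignment accumulates), assembled into randomized trial batteries
  with practice and test phases.
* **Scoring** — perception percent correct, and the three production
  scores, all normalised by the mean IBI:
  * asynchrony = mean<sub>k</sub> |tap<sub>k</sub> − nearest beat| / mean IBI (phase matching),
  * CDEV = mean<sub>i</sub> |IRI<sub>i</sub> − mean IBI| / mean IBI (tempo matching;
    IRI = inter-response interval),
  * CoV = SD(IRI) / mean(IRI) (stimulus-independent variability),

  with nearest-beat matching, validity filtering, and two-stage
  participant aggregation (repetitions within excerpt, then excerpts).
* **Frequentist statistics** — training-year binning (0–2 vs 3+ years),
  factorial ANOVA/ANCOVA with Type III sums of squares and partial eta
  squared, simple main effects, Bonferroni pairwise comparisons, Welch
  *t* (raw or summary-statistic input) and age–score regressions.
* **Bayesian model comparison** — posterior model probabilities
  P(M|data) ∝ P(M)·BF₁₀, BF_M (posterior over prior odds), conventional
  evidence bands (0.1 / 0.33 / 3 / 10), and BIC-approximated Bayes
  factors over the standard five-model ANOVA candidate set.
* **Synthetic cohorts** — a parametric perceiver (lapse-adjusted logistic
  observer) and tapper (linear phase, period scaling, Gaussian motor
  noise, misses/extras) whose parameters map one-to-one onto the scores,
  for ground-truth validation of the full pipeline.
* **I/O and CLI** — CSV readers/writers for tap logs, responses, beat
  annotations, demographics and result tables, plus a
  `simulate` / `score` / `analyze` / `bayes` / `report` command-line
  driver.

## Worked example

```r
library(batkit)

design <- default_cohort_design(n_per_cell = 10, seed = 1)
cohort <- simulate_cohort(design)
scores <- score_cohort(cohort)

dplyr::summarise(dplyr::group_by(scores, music_bin),
                 n = dplyr::n(), pct_correct = mean(pct_correct),
                 asynchrony = mean(asynchrony), cov = mean(cov))
#> # A tibble: 2 × 5
#>   music_bin     n pct_correct asynchrony   cov
#>   <chr>     <int>       <dbl>      <dbl> <dbl>
#> 1 0-2          60        58.0      0.134 0.177
#> 2 3+           60        72.1      0.103 0.161

factorial_anova(scores, "pct_correct", c("group", "music_bin"))
#> # A tibble: 3 × 7
#>   effect          df_num df_den sum_sq     F             p eta_p2
#>   <chr>            <dbl>  <dbl>  <dbl> <dbl>         <dbl>  <dbl>
#> 1 group                2    114   307.  1.07 0.347         0.0184
#> 2 music_bin            1    114  5896. 41.1  0.00000000336 0.265
#> 3 group:music_bin      2    114   307.  1.07 0.347         0.0184
```

The simulated cohort encodes a true music-training effect on perception
(psychometric slope 16 vs 10) and none for group, and the ANOVA recovers
exactly that: a large training main effect (F(1, 114) = 41.1,
ηp² = 0.265) and nothing else.

Model-comparison bookkeeping works from any BF₁₀ column, e.g. a published
five-model beat-perception comparison:

```r
bayes_model_table(
  c("null", "music", "music + group + music:group", "music + group",
    "group"),
  c(1, 685845, 46220, 36339, 0.12))
#> # A tibble: 5 × 6
#>   model                       prior_prob posterior_prob        bf_m    bf10 evidence
#>   <chr>                            <dbl>          <dbl>       <dbl>   <dbl> <fct>
#> 1 null                               0.2    0.00000130   0.00000521      1  insufficient
#> 2 music                              0.2    0.893       33.2        685845  strong_alt
#> 3 music + group + music:group        0.2    0.0602       0.256       46220  strong_alt
#> 4 music + group                      0.2    0.0473       0.199       36339  strong_alt
#> 5 group                              0.2    0.000000156  0.000000625     0.12 moderate_null
```

The music-only model takes 89% of the posterior mass with BF_M = 33.2 —
the data overwhelmingly favour a music-training effect on beat
perception.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/batkit.R simulate --seed 7 --n-per-cell 10 --out data/
Rscript inst/cli/batkit.R score --taps data/taps.csv \
    --responses data/responses.csv --beats data/beats.csv \
    --demographics data/demographics.csv --out results/
Rscript inst/cli/batkit.R analyze --scores results/participant_scores.csv \
    --out results/
```

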