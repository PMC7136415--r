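# actimark

Two-state Markov modelling of rodent rest-activity behavior.

## What it is for

Chronobiologists record spontaneous locomotor activity of mice with
passive-infrared sensors in 10-second bins, under light-dark T-cycles
(22/24/26 h, equal light and dark) or constant darkness. A basic question
about such records is how bouts of activity and rest — not just total
activity — are regulated across the circadian cycle, at time scales of
seconds to minutes.

`actimark` implements a probabilistic analysis of this question. Counts
are encoded to a binary state per bin (`A` if count > 0, else `R`) and
modelled as a two-state Markov chain with phase-dependent transition
probabilities: from rest the animal activates with probability α(X) per
bin, from activity it rests with probability β(X), where X is DAY or
NIGHT (subjective day/night under constant darkness, inferred by cosinor
fitting). The estimators are conditional transition frequencies:

    α(X) = #(Sₙ₊₁ = A | Sₙ = R, Lₙ = X) / #(Sₙ = R, Lₙ = X)
    β(X) = #(Sₙ₊₁ = R | Sₙ = A, Lₙ = X) / #(Sₙ = A, Lₙ = X)

Under the model, bout lengths are geometric; with 10-s bins the mean
rest and activity bouts are 1/(6α) and 1/(6β) minutes, and the fraction
of time spent active in a phase is α/(α+β). The chain is generative, so
fitted models simulate surrogate cohorts for rhythm testing.

The package provides, module by module: record I/O and state encoding
(`read_activity_record`, `encode_activity`), phase labelling from light
flags or a cosinor grid fit (`label_from_light`, `fit_cosine_phase`),
estimation and bout statistics (`fit_markov`, `extract_bouts`,
`geometric_bout_pmf`), a synthetic cohort generator standing in for the
unreleased recordings (`simulate_cohort`, `simulate_sequence`), model
diagnostics (`split_half_stability`, `conditional_mutual_information`,
`bout_distribution_comparison`), the Enright chi-squared periodogram with
Bonferroni control for ultradian/circadian screens (`chi2_periodogram`,
`ultradian_screen`), and cohort-level fold-change summaries with
bootstrap confidence intervals (`summarize_cohort`,
`night_day_activity_report`, `condition_contrast`).

## A worked example

```r
library(actimark)

coh <- simulate_cohort("LD24", n_animals = 8, record_days = 7, seed = 11)
fit_markov(coh$sequences[[1]])
#> Two-state Markov model of rest/activity -- ld24_01
#>
#>                             DAY  NIGHT
#> alpha (R->A)             0.0302 0.0872
#> beta  (A->R)             0.2975 0.2230
#> mean rest bout (min)     5.5106 1.9114
#> mean activity bout (min) 0.5603 0.7475
#> average activity         0.0923 0.2811
```

This animal rests in bouts of ~5.5 min by day but only ~1.9 min by
night, while its activity bouts barely change (0.56 vs 0.75 min) — the
day-night difference in activity (9% vs 28% of time active) is driven by
rest-bout regulation. At the cohort level:

```r
summarize_cohort(coh, n_boot = 2000, seed = 12)
#> Cohort summary (8 animals; geometric means with 95% bootstrap CIs)
#>
#> Day/night fold changes:
#>  condition               quantity estimate lower upper n
#>       LD24       average_activity    0.366 0.313 0.434 8
#>       LD24     mean_rest_bout_min    2.617 2.215 3.043 8
#>       LD24 mean_activity_bout_min    0.746 0.672 0.831 8
#>       LD24            total_bouts    0.491 0.428 0.571 8
#>
#> Rest/activity bout-length ratios:
#>  condition phase estimate lower upper n
#>       LD24   DAY    7.722 6.288 9.200 8
#>       LD24 NIGHT    2.202 1.997 2.412 8
```

Days are about a third as active as nights (fold 0.37), rest bouts are
2.6-fold longer by day while activity bouts shrink only 0.75-fold, and
rest bouts exceed activity bouts ~8-fold by day versus ~2-fold by night.
Finally, the model predicts no ultradian *rhythms* despite this ultradian
*regulation*:

```r
ultradian_screen(coh)$total
#> [1] 0
```

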