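---
title: "A two-state Markov model of rodent rest-activity behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-state Markov model of rodent rest-activity behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimark)
```

## The model

Passive-infrared actigraphy of a mouse, recorded in 10-second bins, is
encoded into a binary state sequence: a bin is *active* (`A`) when its
activity count exceeds zero and *resting* (`R`) otherwise. Only the
duration of activity is modelled, never its intensity.

`actimark` models the encoded sequence as a two-state Markov chain whose
transition probabilities depend on the phase of the circadian cycle. In
each 10-s step, a resting animal becomes active with probability
$\alpha(X)$, and an active animal returns to rest with probability
$\beta(X)$, where $X \in \{\mathrm{DAY}, \mathrm{NIGHT}\}$ is the phase of
the current bin. Everything else follows from this chain:

* **Bouts** — maximal runs of one state — have geometric length
  distributions: $P(K = k) = (1-p)^{k-1} p$ with exit probability
  $p = \alpha$ for rest and $p = \beta$ for activity. Mean bout lengths
  are $1/\alpha$ and $1/\beta$ bins; with 10-s bins, $1/(6\alpha)$ and
  $1/(6\beta)$ minutes.
* **Average activity** — the long-run fraction of active bins in a phase —
  is $\alpha/(\alpha+\beta)$.
* The chain is generative: `simulate()` on a fitted model produces
  surrogate records with exactly the fitted bout structure, which is how
  rhythm predictions are tested.

The maximum-likelihood estimator is transition counting
(`count_transitions()` / `fit_markov()`): each adjacent bin pair
contributes to the cell indexed by its ordered states under the phase of
the *origin* bin (the conditioning variable), and
$\hat\alpha(X) = n_{RA}(X)/(n_{RA}(X)+n_{RR}(X))$, likewise $\hat\beta$.
Pairs spanning a recording gap are dropped: counting across a gap would
treat a missing stretch as a single transition and bias both rates
downward. A phase in which a state never occurs yields `NaN` with a
classed warning rather than a silent zero — degenerate records should
fail loudly.

Transitions that straddle a phase boundary are attributed to the phase of
the origin bin. Any convention affects at most two pairs per cycle out of
thousands, but the origin-bin rule is the literal reading of
$P(S_{n+1} \mid S_n, L_n = X)$.

## Phase labels

Under entrained light-dark housing (T-cycles of 22, 24 or 26 h with equal
light and dark), phase is read off the recorded light flags
(`label_from_light()`): lights-on is DAY.

Under constant darkness the rhythm free-runs and phase must be inferred
from the behavior itself. `fit_cosine_phase()` fits
$\mu + a\cos\omega t + b\sin\omega t$ to the raw counts at each candidate
period on a grid (default 20–28 h in 0.1-h steps, bracketing murine
free-running periods), by exact linear least squares per period — the
cosinor parameterisation. Each per-period fit is convex, so a grid search
plus linear algebra is fully reproducible where a nonlinear optimiser
might not be. The winning period maximises variance explained; the
acrophase is the fitted peak. Because mice are nocturnal, subjective
NIGHT is defined as the half-period window centred on the acrophase,
tiled periodically; the complementary half-cycle is subjective DAY. The
half-cycle boundary is a convention — nothing in the data marks where
subjective night "really" starts — and centring on the activity peak is
the choice that makes subjective and entrained night comparable.

Records must span at least four cycles of the longest candidate period
(the study's inclusion rule); shorter records are refused rather than
fitted badly.

## The synthetic cohort generator

No public accession of the original recordings exists, so
`simulate_cohort()` is a first-class module that generates cohorts with
the statistical structure the analysis assumes:

* **Cohort means.** The default transition probabilities derive from the
  published cohort-mean bout lengths (`reference_bout_minutes()`):
  activity/rest of 0.75/1.75 min at night and 0.54/4.50 min in the day
  under LD; 0.67/2.68 and 0.55/4.05 min for subjective night and day
  under DD.
* **Composition.** Default cohort sizes follow the study design: 8, 16
  and 8 animals at the 22-, 24- and 26-h T-cycles and 16 in DD.
* **Record length.** 7 days of 10-s bins by default — comfortably above
  the four-cycle inclusion rule and small enough that a full 48-animal
  composition simulates and screens in minutes on one CPU. Tests that
  only exercise interfaces use shorter records (4–5 days).
* **Heterogeneity.** Per-animal $\alpha$ and $\beta$ are drawn
  independently and lognormally around the cohort means with a
  coefficient of variation of 0.2 (mean-preserving parameterisation).
  The published figures show substantial per-animal scatter but no
  distribution; cv = 0.2 is a knob chosen to give visually comparable
  spread, not a claim about mice.
* **DD periods.** Free-running periods are drawn around 23.8 h
  (SD 0.2 h, truncated to 20–28 h) — slightly short of 24 h, as typical
  for C57BL/6 mice — so that cosinor recovery is exercised on
  non-trivial periods.
* **Initial state.** Stationary by default ($P(A) = \alpha/(\alpha+\beta)$
  of the first bin's phase), avoiding a burn-in transient; stationarity
  is the model's own working assumption.

Cohorts are bit-reproducible from their seed, and the generating truth is
returned next to the data so estimator recovery can be asserted, not
assumed.

What the generator deliberately does *not* emulate: activity intensities
(counts beyond 0/1), light-masking dynamics beyond the phase-switched
parameters, within-phase nonstationarity, and non-geometric rest-bout
tails. Real recordings show all of these to some degree — the published
distributions have an excess of very short and very long rest bouts —
so passing recovery tests on synthetic data demonstrates correctness of
the estimators under the model, not fidelity of the model to any
particular mouse.

## Diagnostics

`split_half_stability()` refits the model independently on the first and
second halves of a record, split at the midpoint bin — the simplest
reproducible rule. Under stationarity the halves agree; across a cohort,
`split_half_correlation()` reports the Pearson correlation of first- vs
second-half estimates.

`conditional_mutual_information()` is the Markov-order check: the plug-in
estimate of $I(S_{n+1}; S_{n-1} \mid S_n)$ in bits from empirical triple
frequencies. For any first-order chain it converges to zero; the
deterministic pattern `R,R,A` gives exactly $2/3$ bit and serves as the
positive control. No bias correction is applied — at the record lengths
involved ($10^5$–$10^6$ bins) plug-in bias is far below the effect sizes
of interest, and the quantity is interpreted against thresholds stated
per record length (e.g. $<10^{-3}$ bits at $10^6$ bins), not as an
absolute.

`bout_distribution_comparison()` contrasts the observed bout-length
histogram with the fitted geometric law. Truncated bouts (those touching
a record edge or a gap) are excluded from observed histograms by default
because censoring biases observed lengths; they are still counted in
transition estimation, which is pair-based and unaffected.

## The chi-squared periodogram

`chi2_periodogram()` folds the series at each integer candidate period
$P$ into $K = \lfloor N/P \rfloor$ complete rows (the partial row is
discarded — the conservative complete-fold variant) and computes
$$Q_P = K N' \sum_h (M_h - \bar M)^2 \Big/ \sum_i (x_i - \bar M)^2,$$
referred to $\chi^2_{P-1}$, with Bonferroni correction over the tested
grid. $Q$ is invariant to affine transforms, so binary sequences and raw
counts can both be tested; the encoded binary series is the default.

Two calibration points matter in practice:

* **Analysis bins.** The $\chi^2$ reference presumes approximately
  exchangeable bins. A 10-s rest/activity series is strongly serially
  correlated (lag-one autocorrelation $1-\alpha-\beta \approx 0.7$ at the
  default parameters), which fattens the tail of $Q$ and makes a
  raw-resolution screen anticonservative — in simulation, a
  phase-homogeneous Markov chain was flagged in essentially every run at
  native resolution. Aggregating to one-minute analysis bins (on the
  order of the mean activity bout, so adjacent bins decorrelate) restores
  the nominal family-wise error; this mirrors standard actigraphy
  periodogram practice of computing on minute-scale bins. The ultradian
  screen therefore defaults to 60-s analysis bins with the grid of all
  integer periods up to 2 h; the circadian scan uses 6-min bins over
  20–28 h.
* **The family.** `ultradian_screen()` corrects over the period grid per
  animal by default. Each animal then carries its own 5% false-alarm
  chance, so a 48-animal screen is *expected* to collect a few flags even
  when the model is exactly true. When the claim under test is
  cohort-wide — "no ultradian rhythm in any animal" — the screen should
  control the error over the whole cohort (`familywise = "cohort"`,
  an additional Bonferroni factor over animals).

The generative prediction is tested the way it was originally made: fit
each animal, simulate an artificial cohort from the fitted models matched
in composition and record length, and screen the artificial data. The
acceptance suite runs exactly this pipeline on the default 48-animal
composition and additionally confirms that the imposed T-cycle period is
detected in every entrained animal, and that an injected 90-minute
modulation of $\alpha$ is flagged (the screen has power where power is
due).

## Cohort summaries

`summarize_cohort()` aggregates per-animal model summaries into
cohort-level fold changes (day/night, paired within animal) and
rest/activity ratios. These are multiplicative quantities, so animals are
averaged on the log scale (geometric mean) and intervals come from an
animal-level nonparametric bootstrap (2000 resamples, seeded). This
replaces the mixed-model machinery a full reanalysis would use: the
estimands — ratios with confidence intervals — are preserved, the
log transform is the natural variance-stabiliser for fold changes, and
the bootstrap is self-contained and exactly reproducible. The intervals
are comparable to, not identical with, mixed-model intervals.

Per-phase bout totals are derived from the transition counts
($n_{RA} + n_{AR}$ started in the phase): because rest and activity bouts
alternate, their counts in any interval differ by at most one, and the
total is the meaningful summary.

## Numerical conventions and edge cases

* Bins are indexed 1-based; a bout occupies the closed bin range
  `[start_bin, start_bin + length_bins - 1]`.
* Gap markers are bin indices `i` such that the pair `(i, i+1)` is
  discontinuous; estimation, bout extraction, CMI triples and split-half
  fitting all respect them.
* Zero-variance series give an `NaN` periodogram statistic with a
  warning; zero-denominator phases give `NaN` estimates with a classed
  warning (`actimark_undefined_estimate`); cohort summaries exclude such
  animals with a warning and report the effective n.
* The cosinor refuses all-zero and constant-count records (zero
  amplitude) instead of returning an arbitrary phase.
* Problem sizes in the test suite were chosen so the full suite runs in
  well under a minute of simulation-heavy work: long-run consistency at
  $10^6$ bins, goodness-of-fit at $\geq 10^4$ bouts, the full 48-animal
  composition once, shared across the slow suites.

## Known limitations

* The geometric law understates very short and very long rest bouts in
  real data; the package measures this (the distribution comparison and
  its mixture test) but the core model does not capture it.
* Phase labels are binary; twilight transitions, split rhythms and
  entrainment failure are out of scope.
* The periodogram's Bonferroni correction is conservative for dense,
  highly correlated period grids; it trades power for a clean
  family-wise guarantee.
* One animal per record; proprietary binary actigraphy formats are not
  parsed.

## A worked example

```{r example, fig.width = 6, fig.height = 5}
coh <- simulate_cohort("LD24", n_animals = 4, record_days = 5, seed = 11)
fit <- fit_markov(coh$sequences[[1]])
fit
summarize_cohort(coh, n_boot = 500, seed = 12)
```
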