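---
title: "Building, administering, scoring and simulating implicit association tests"
author: "iatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, administering, scoring and simulating implicit association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatkit)
```

## The measurement problem

The Implicit Association Test (IAT) measures how strongly two *concept*
categories (say, silhouettes of overweight vs. normal-weight people) are
associated with two contrasting *attribute* categories (positively
vs. negatively connoted words). Respondents sort stimuli left or right as
fast as they can; when a concept shares a response side with the attribute
it is implicitly associated with (the *compatible* pairing), sorting is
faster than under the reversed (*incompatible*) pairing. The latency
difference, standardized, is the D score.

`iatkit` is a headless engine for this paradigm: it builds the randomized
seven-block task, administers it trial by trial against a pluggable
responder, cleans latencies and computes D scores, simulates synthetic
respondents and whole crossed-design studies, and reproduces the group
comparisons such studies report. Nothing in the package renders stimuli;
image stimuli are opaque identifiers.

## Task construction

A task follows the canonical seven-block sequence: concept sorting (B1),
attribute sorting (B2), combined pairing practice and test (B3, B4),
concept sorting with sides exchanged (B5), and the reversed pairing
practice and test (B6, B7). Default trial counts are
(20, 20, 20, 40, 28, 20, 40); the `"german"` preset raises B5 to 40.
With the stimulus overview, the general instruction, one instruction step
per block and a completion step, a full task has 17 steps:

```{r}
task <- build_task(example_stimuli(), iat_config(seed = 42))
task
```

Construction decisions worth knowing:

* **Side randomization.** The concept shown on the left in B1–B4 is chosen
  at random per task (and always swapped for B5–B7); the first attribute
  stays on the left for the whole task unless attribute randomization is
  switched on. Over many administrations this prevents side-of-screen
  artifacts at the group level.
* **Balance.** Pairing blocks must have counts divisible by 4: they
  contain exactly equal numbers of the two attribute polarities and of the
  two concepts. Sorting blocks are also built balanced across their two
  categories (the extra trial of an odd count goes to a random category);
  the underlying requirement is only "random selection", and balancing is
  the least surprising way to satisfy it.
* **Sampling.** Stimuli are drawn by cycling independently reshuffled
  copies of a category list, so no item repeats before its whole list has
  been used. Whether the original instruments sample with or without
  replacement when a list is shorter than a block is not documented
  anywhere we know of; cycling is this package's choice.
* **Interleaving.** The balanced multiset of a pairing block is fully
  shuffled by default; `strict_alternation = TRUE` forces
  attribute/concept alternation instead, since published implementations
  differ on this point.
* **Reproducibility.** All randomization runs through R's seedable RNG;
  `iat_config(seed =)` rebuilds a byte-identical task without disturbing
  the caller's RNG stream. (Production apps have used stream ciphers such
  as RC4 for shuffling; the statistical properties that matter here —
  uniform shuffles, reproducibility — do not depend on that choice.)

## Session administration

`run_session()` walks the task's steps. Non-block steps consume a
responder acknowledgment; each trial accepts response events until the
first one on the correct side, mirroring a touch app that shows a red ×
and forces reclassification after every wrong tap. The recorded latency is
onset-to-first-correct-response, and a trial counts as **one** error if
any wrong event preceded the correct one — errors are per trial, not per
tap, which is the convention under which published per-test error counts
(about 6–7 per session) make sense.

Responders are plain objects, so sessions can be driven by scripts,
recorded event logs (`responder_replay()`, which reproduces a session
exactly), or the latency model below (`responder_profile()`). An exhausted
responder aborts the session with the partial results attached and flagged
incomplete.

## Latency cleaning and D scores

Latencies strictly below 400 ms or strictly above 10,000 ms are removed
before any analysis; the boundary values themselves are kept, reading
"below"/"above" strictly. Cleaning is order-preserving and idempotent, and
removal counts are reported so table Ns reconcile.

For the practice pair (B3, B6) and the test pair (B4, B7) separately,

$$D = \frac{M_{\text{incompatible}} - M_{\text{compatible}}}{SD_{\text{pooled}}},$$

where the pooled SD is the standard deviation of the two blocks' cleaned
latencies *combined* (not an average of per-block SDs — the conventional
improved scoring procedure). The overall D is the mean of the two pair
scores. Positive D indicates an implicit preference for concept 1. D is
invariant to adding a constant to all latencies and to positive rescaling
— which is exactly why device- or input-method-driven latency shifts should
not move D — and flipping the compatible orientation flips its sign
exactly.

The default algorithm scores error trials by their full
latency-until-correct with no added penalty, because the engine forces
reclassification and that latency already embodies the error cost. Two
penalty variants (replace error-trial latencies by the block's
correct-trial mean + 600 ms, or + 2 SD) are provided for data collected
without forced correction; which member of the published D1–D6 family a
given external implementation uses is often unstated, so no cross-variant
numerical agreement is claimed. A block with fewer than two cleaned trials
makes the score undefined and raises a classed error with diagnostics.

The qualitative labels use the conventional breakpoints 0.15 / 0.35 / 0.65
on |D| (slight / moderate / strong); these are feedback conventions, not
estimands, and are configurable.

## The synthetic respondent model

`simulate_study()` exists so every downstream stage is testable without
human data. A trial's latency is

* a non-decision floor (`shift_ms`, default 550 ms), reduced by
  `practice_ms` (default 50 ms) for each test the participant has already
  taken that day;
* plus a log-normal decision component (default meanlog
  `log(230) − 1.39²/2`, sdlog 1.39 — mean ≈ 230 ms with a heavy right
  tail);
* plus additive millisecond-scale shifts: the variant effect of the app
  type × input method combination (defaults 0 / 10 / 53 / 146 ms), an
  error-correction cost (400 ms at per-trial error probability 0.03), and
  the association bias.

The **bias** term adds `abs(bias_ms)` to whichever pairing is
*disfavoured*: incompatible blocks when `bias_ms > 0` (preference for
concept 1), compatible blocks when `bias_ms < 0`. A signed additive shift
would be the more literal parameterization, but subtracting a few hundred
milliseconds from a distribution whose floor sits near 400 ms would push
many trials under the cleaning bound and distort calibration; adding to
the slower pairing preserves the sign convention (sign of D = sign of
`bias_ms`) with latencies always above the floor. About 1% of trials are
replaced by outliers (90% anticipations in 150–399 ms, 10% lapses above
10 s), which cleaning is expected to remove.

Across participants, a study draws random effects shared by each
participant's four sessions: a base-speed offset (SD 0.25 on the log
scale), a bias offset (SD 130 ms), and an error-rate offset (SD 0.6 on the
logit scale — raw binomial error counts are far less dispersed than real
per-participant error counts, whose SDs run around 5).

The defaults were calibrated once against the printed moments of a
published 51-participant native-app vs. web comparison of the weight IAT:
per-variant mean scored latencies ≈ 865–1010 ms with SDs ≈ 500–620 ms,
mean D ≈ −0.6 (SD ≈ 0.35) toward the thin concept, and ≈ 6–7 errors per
188-trial session. They reproduce those moments to within sampling error;
they are moments-level emulation, not a cognitive process model. What the
simulator deliberately does **not** emulate: within-session autocorrelation
and fatigue dynamics, stimulus-item effects, speed–accuracy trade-offs
(errors are independent of the latency draw), or any dependence of D on
the variant or order — so passing tests demonstrate the pipeline's
statistical behavior under a realistic null/alternative structure, not
facts about human respondents.

## Study analysis

`iat_describe()` reproduces the shape of the familiar comparison tables:
per-group n / mean / SD / range of latencies (trial level, cleaned pairing
blocks), D scores or error counts (participant-per-test level), grouped by
variant or order, with a Kruskal–Wallis or ANOVA p attached.
`test_group_effect()` is the corresponding one-way test; trial-level
latency tests deliberately ignore within-participant clustering because
that is how the published tables are computed (a clustered variant that
aggregates to session means first is available behind `cluster = TRUE`,
with a warning). No multiple-testing correction is applied, matching the
analyses being reproduced. `randomization_check()` computes the 4×4
variant-by-order contingency table and Pearson's χ² with 9 df.

Post-hoc power for the "linear ANOVA" uses the noncentral F distribution
with numerator df `u` (number of predictors), denominator df
`N − u − 1`, and noncentrality `λ = f² · N` — the G*Power
multiple-regression convention:

```{r}
posthoc_power(f2 = 0.25, alpha = 0.05, n_predictors = 4, n_total = 51)
```

which rounds to the conventionally reported 0.8 at these settings.

## Numerical and degenerate-input choices

* Cleaning bounds are strict inequalities; exactly 400 or 10,000 ms
  survives. `exclusive_bounds = FALSE` flips that reading.
* A constant measure across groups would make both group tests undefined;
  they return p = 1 with a warning instead.
* `compute_d()` on an all-identical latency multiset returns D = 0 (zero
  numerator with a zero pooled SD is taken as "no difference" rather than
  NaN).
* |D| values outside ±2 are possible on tiny cleaned samples and are
  labelled, not rejected.
* Session JSON carries a schema version; files without one, or with a
  different one, are rejected by name. Unknown top-level fields round-trip
  untouched, and field order is fixed so write → read → write is
  byte-identical.

## Problem sizes used in the shipped checks

The package's test suite exercises the statistical properties at sizes
chosen to make the Monte-Carlo error small relative to the asserted
effect: D-score invariance/antisymmetry and oracle agreement over 1,000
random sessions; pairing-block balance over 200 task builds; bias-sign
recovery at ±50 ms over 100 replicate 51-participant studies; null
calibration of the ANOVA and Kruskal–Wallis rejection rates over 500
replicate small studies (10 participants, reduced trial counts — level
calibration is a property of the tests, not of the study size); and the
latency-vs-D dissociation over 10 replicate full-size studies.

## Known limitations

* The simulator is a moments-level emulator; do not use it to study
  process-level questions (drift, caching of stimulus–response mappings,
  sequential effects).
* Scoring assumes the forced-correction latency definition; data from
  implementations that freeze input after a wrong response need the
  penalty variants, and exact agreement with any specific external D
  implementation is not asserted.
* The analysis layer mirrors one-way, uncorrected, unclustered published
  analyses by design; it is a reproduction surface, not a recommendation
  for new confirmatory work.
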