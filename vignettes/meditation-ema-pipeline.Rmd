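---
title: "Modelling mood, equanimity, resilience, and adherence from meditation session streams"
author: "medema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mood, equanimity, resilience, and adherence from meditation session streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement setting

Digital meditation apps can attach a one-item mood check-in ("How are you
today?", five ordered categories from *terrible* to *great*) to every
meditation session. The result is an ecological momentary assessment (EMA)
stream: per user, an irregular sequence of timestamped sessions, each with
an ordinal mood, a session length, and content labels (practice type,
worldview, orientation, whether the object of attention is inside the body
— *interoceptive*, e.g. breath or body scan — or outside it —
*exteroceptive*, e.g. compassion, mantra, affirmations). `medema`
implements a complete analysis pipeline for such streams: outcome
engineering, dose–response and habit modelling, and a synthetic generator
with known ground truth so that every stage can be validated by parameter
recovery rather than by eyeballing.

## Outcome engineering

**Practice periods and shifted mood.** Mood is reported *before* each
session, so session $j$'s practice can plausibly influence the check-in at
session $j+1$. The feature table therefore pairs the predictors of session
$j$ with the mood of session $j+1$ (a forward shift), and the first mood
of each run is removed from the outcomes and kept as a baseline covariate.
The shift is only credible while practice is ongoing: a maximal run of
sessions with every consecutive gap at most 7 calendar days forms a
*practice period*, and shifting never crosses period boundaries. The
7-day rule is the package default (`gap_days = 7`); under the default
synthetic gap distribution roughly 90% of gaps fall within it, which is
also why a weekly cycle is the natural segmentation unit for habit data.
Gaps are calendar-day differences, not 24-hour blocks, so that the same
day resolution underlies the gap rule and the days/week feature.

**Habit features.** Per session and user, the pipeline accumulates: the
cumulative session count; days since the previous session; the number of
distinct days meditated in the trailing 7-day window (inclusive of the
current day — the anchoring is a documented choice, switchable via
`week_window`); the cumulative exteroceptive:interoceptive ratio (left
missing until the first interoceptive session, since a ratio with a zero
denominator carries no information; linear models either keep those rows
with a missingness indicator, the default, or drop them); and the running
count of distinct practice types. Cumulative counts and session lengths
are harmonized to the nearest 5 units (ties away from zero) to reduce
sparsity, and box-plot trimming (values beyond $1.5\,\mathrm{IQR}$ from
the quartiles; type-7 quantiles by default, the convention is a
parameter) removes spurious extremes. Children-related and sleep
meditations are removed before any feature is computed — the account
holder may not have completed a children's track, and a user may fall
asleep during sleep content, which would corrupt any dose–response
reading. The filter matches content labels only; the *sleep* mood
attribution is a covariate, not excluded content.

**Equanimity.** Even-mindedness is operationalized as mood stability: the
rolling 5-session sample standard deviation (the $n-1$ denominator is a
documented choice) of the mood series, sign-flipped so that higher values
mean more stability, then min–max rescaled to $[1, 5]$ so it shares the
mood scale. Rescaling is fitted on the pooled corpus of defined window
SDs across users (global scope) so values are comparable between users;
per-user scope is available (`scope = "user"`). If every defined SD is
equal the normalization is degenerate and maps everything to the scale
maximum 5 — by construction, zero variability is maximal equanimity.

**Resilience.** Recovery speed after a mood dip: when a check-in falls at
least 1 point below the user's trailing-week mean mood (the current
check-in is excluded from its own reference, otherwise a drop would
dilute the very mean it is compared against), an event opens with the
reference frozen at drop time, and a counter runs over subsequent
sessions until the first whose mood returns to or above the reference.
Events still open at the end of a stream are censored — such users may
simply have churned — and excluded from analysis datasets. Two documented
alternatives are switchable: a rolling (recomputed) reference instead of
a frozen one, via `freeze_reference = FALSE`. Only one event can be
active per user at a time, and a deeper drop during recovery does not
reset the counter.

**Adherence.** Long-term engagement is a binary label — did the user's
full stream reach 150 sessions? — predicted strictly from the first 30
sessions' habits (dominant time of day, mean days/week, mean days since
last session, the ratio at session 30, mean length, distinct practice
types, baseline mood, onboarding covariates). Users with fewer than 30
sessions are excluded; the 30/150 defaults mirror a median-sized early
window and a top-decile long-term milestone and are both parameters.

## Models

Habit levels for stratified and logistic models use fixed groupings:
days/week $\{1, 2, 3, 4\!-\!7\}$; days since last session
$\{1, 2, 3\!-\!7\}$ (and $\{1, 2, 3\!-\!4, 5\!-\!7\}$ for adherence);
length $\{5\!-\!10, 11\!-\!20, 21\!-\!30\}$ minutes; practice types
$\{1\!-\!4, 5\!-\!8, 9\!-\!12\}$; ratio levels $0\!:\!1$ through
$9\!:\!1$.

**Linear mixed models** (`fit_linear_mixed`, via `lme4::lmer`, REML):
shifted mood, equanimity, or resilience outcomes on the habit predictors
and covariates, with a random intercept per user, optionally nested
within continent (`(1 | continent / user_id)`) to absorb regional level
differences. Inference is Wald throughout — symmetric 95% intervals and
normal-approximation p-values — and each model's coefficient table is
corrected for multiple testing with Benjamini–Hochberg q-values. The FDR
family is one model's coefficient table, not the union of models.

**Generalized additive mixed models** (`fit_nonlinear_mixed`, via
`mgcv::gam`/`bam`): penalized thin-plate regression splines of the
outcome against cumulative session count, optionally one smooth per
habit level (`by =` factor), parametric covariate adjustment, and a
user-level random intercept (`s(user, bs = "re")`). The penalty is
selected automatically by (f)REML; the basis dimension defaults to
`k = 20`. Two support guards keep smooths honest at sparse extremes:
levels with fewer than `min_level_n` rows are dropped with a warning,
and each level's session axis is truncated at the `cutoff_quantile` of
its own support (the exact cutoff rule is a parameter because no single
relative-frequency rule suits all stream-length distributions). Fitted
smooths are exported on evaluation grids with pointwise 95% bands. A
constant outcome (zero residual variance) cannot be represented by the
REML machinery and is returned as the exact degenerate answer: intercept
equal to the constant, identically-zero smooths.

**Adherence logistic regression** (`fit_adherence_logit`, via `glm`):
odds ratios with Wald intervals and q-values; the reference level of
each habit factor is its first level. Complete separation is flagged on
the result rather than raised, since separation is a data property the
analyst needs to see, not a programming error.

## The synthetic generator and what passing tests mean

`simulate_cohort()` draws users (continent, truncated-normal age at 18+,
reasons for meditating, experience indicators, a Gaussian baseline) and
session streams from a latent-threshold ordinal model:

$$
\ell_{ui} = b_u + \beta_s (i - 1) + \beta_c\,\mathrm{dpw}_{ui}
          + g(i) + \varepsilon_{ui},
\qquad
\text{mood}_{ui} = 1 + \#\{k : c_k < \ell_{ui}\},
$$

with fixed global cutpoints $c = (-1.5, -0.5, 0.5, 1.5)$, noise
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 1$, baseline SD $0.5$,
a linear dose slope $\beta_s$, a practice-consistency slope $\beta_c$ on
trailing days/week, and an optional tabulated nonlinear profile $g$
(`saturating_profile()` for a fast-rise/plateau dose–response).
Inter-session gaps are geometric on $1\ldots14$ days with success
probability $0.28$, putting about 90% of gaps within 7 days; churn is an
absorbing per-session dropout with hazard $1/\text{mean sessions}$, so
session counts are geometric; a returning-user mode mixes in 8–30-day
gaps to exercise multi-period logic. All draws flow from one root seed
(the user table uses `seed`, the session table `seed + 1`), so stages
are reproducible in isolation. The generator writes mood and a
ground-truth latent table joined 1:1 to the sessions.

The latent-threshold construction makes recovery expectations
computable: a latent slope $\beta$ appears on the observed 1–5 scale as
$\beta \cdot \lambda$, where
$\lambda = \sum_k \varphi\!\big((m - c_k)/s\big)/s$ with
$s^2 = \sigma^2 + \tau_b^2$ is the link derivative (`mood_link_slope`),
and the marginal mean check-in is
$1 + \sum_k \Phi\!\big((m - c_k)/s\big)$ (`expected_mood`). The test
suite verifies both against direct numerical integration before using
them as recovery truths.

What the generator does **not** emulate: real content popularity and its
coupling to mood, seasonal and weekly periodicity, mood-dependent churn
(dropout is independent of the latent state), time-zone structure, and
any feedback from outcomes to practice habits. Passing recovery tests
therefore shows that the pipeline estimates what it claims to estimate
under a known data-generating process — not that real meditation data
satisfy that process.

For adherence recovery, simulating thousands of 150-session streams per
replicate would be wasteful; `simulate_adherence_cohort()` instead draws
first-30-session features at the user level and labels from a logistic
model with a configurable true odds ratio (default 2 for practicing 4–7
days/week). This validates the estimator, not the feature extraction,
which is validated separately against brute-force oracles.

## Validation design and problem sizes

Every engineered quantity has an independent oracle in the test suite: a
linear scan for segmentation, an $O(n^2)$ recompute for habit features,
direct `sd()` on every window for equanimity, a naive trailing-mean
scanner for resilience, and a hand-rolled step-up for BH. The suite runs
these on 500 random streams (and 1000 random p-vectors) and requires
exact agreement. Parameter recovery uses 100 seeded replicates at 500
users (about 10 sessions each) for the linear mixed model and 100
replicates at 2000 users for the adherence model, asserting at least 90%
CI coverage against the nominal 95%; the bound leaves room for Monte
Carlo error and mild Wald anticonservatism. Nonlinear recovery fits one
cohort of 1000 users (about 45 sessions each) generated from a
saturating profile (amplitude 0.8 latent units, e-folding 20 sessions)
and requires the fitted smooth, mapped back through the average link
derivative, to track the true profile within 0.05 latent units RMSE and
to place the bulk of the gain in the early-session region. These sizes
were chosen so that Monte Carlo error is small relative to the asserted
tolerances while a full run stays comfortably interactive.

`scripts/acceptance.R` re-runs the same computations from scratch
against the installed package and writes the resulting quantities as
JSON; `run_pipeline()` writes per-stage CSVs, a deterministic manifest
(seed, configuration digest, file hashes), and an attrition log counting
rows entering and leaving every filter so sample attrition is auditable.

## Known limitations

- Mood is modelled as numeric in the mixed models (as is common for
  5-point EMA scales); ordinal-response mixed models are out of scope.
- Wald inference everywhere; profile or bootstrap intervals are not
  provided.
- The trailing-week resilience reference needs at least one prior
  check-in within 7 days; early-stream drops without one are not events.
- Box-plot trimming is not idempotent for arbitrary heavy-tailed data
  under any quantile convention; the suite asserts idempotence only as a
  regression property on fixed series.
- The continent nesting uses variance components; fixed continent
  effects are a reasonable alternative the package does not currently
  expose.
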