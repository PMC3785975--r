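---
title: "Models and methods behind alcsms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alcsms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcsms)
```

alcsms implements the computational core of a tailored web- and SMS-based
program to reduce problem drinking in adolescents and young adults, together
with the machinery needed to evaluate such a program in a pre-post design.
This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohort does and does
not emulate.

## Instruments and derivations

The screening instrument carries demographics, smoking, weekly physical
activity, and three alcohol items: the 30-day RSOD frequency category (eight
ordered levels from "never" to "more than 12 times"), a 7-day typical-week
drinking calendar in standard drinks, and the maximum number of drinks on a
single occasion. Derivations are deliberately minimal and total: the weekly
total is the calendar sum; current daily and occasional smokers count as
smokers; the eight RSOD categories collapse into the three bands the risk
rules need (none, 1–2, more than 2 occasions); and a person has "any
alcohol-related problem" iff at least one of ten yes/no items is endorsed.
Missing problem items count as *no problem* — the outcome is a plain binary
and inventing endorsements from missingness would inflate prevalence. Ages
outside 15–25 warn rather than fail, since a vocational-school cohort can
contain older students.

## Risk stratification

Two published indicators anchor the tiers: RSOD (≥ 5 standard drinks on one
occasion for men, ≥ 4 for women) and average daily volume (≥ 30 g pure
alcohol for men, ≥ 20 g for women). Classification uses the categorical RSOD
band, not an imputed count, because the instrument is categorical; the
weekly cutoffs are 18 (men) / 12 (women) drinks, *exclusive* for the
non-risk tier and inclusive for low risk, and boundary tests pin exactly
that. A person with 1–2 RSOD occasions never escalates to high risk on
volume alone — the printed rules are implemented as printed, and the
exhaustive truth-table test enumerates every (gender × band × 0..60 drinks)
cell against an independent restatement of the rules.

The mass of a standard drink defaults to 12 g of ethanol and is
configurable, because Swiss serving conventions range from 10 to 12 g; at
12 g the 18/12 weekly cutoffs correspond to daily averages of 30.9/20.6 g,
i.e. the weekly rule is the drink-denominated version of the volume
indicator.

## Normative feedback

The one-shot feedback is tailored on exactly four variables — gender, age,
weekly drinks, and RSOD frequency — and produces four sections in fixed
order: consumption percentile, cost, calories, and RSOD percentile.

* **Percentile.** Mid-rank convention: `100 × (#below + ½·#equal) / n`.
  It is monotone, permutation-invariant, and places the values of a
  distinct reference sample at `(i − ½)/n × 100`. Reference strata are
  keyed by gender and age band ({15–16, 17–18, 19–20, 21+}, matching the
  cohort's age structure); a missing stratum falls back to the nearest age
  band (younger first), then to the gender's pooled sample. The package
  ships a *synthetic* normative table — the original reference survey is
  unpublished — so shipped percentiles illustrate the mechanism, not real
  norms.
* **Cost.** `weekly drinks × price × 52/12`, rounded half-up to 2 decimals.
  The price per drink (default 5.00) is a config value; no published figure
  exists.
* **Calories.** `drinks × g/drink × 7.1 kcal/g`; mixer calories are out of
  scope.
* **BAC.** Widmark: `(drinks × g/drink) / (r × weight)` in per-mille, with
  r = 0.68 (men) / 0.55 (women) and default weights 72/60 kg. No
  elimination term is subtracted because the figure addresses the peak of a
  single occasion. Under these defaults 14 drinks give 3.43‰, consistent
  with the "about 0.34%" phrasing used in percent-of-g/mL convention; the
  original constants are unknown, so this is a sanity anchor, not an exact
  target.

`build_feedback()` is a pure function of (baseline, norms, config) — the
purity test asserts byte-identical reports on repeated calls.

## Message planning

Dose and pool by tier: non-risk participants get one weekly message from
categories {1–4}; low-risk from {1–3, 5–9}; high-risk from {1–3, 5–10},
category 10 being local counseling services. Category 4 (maintaining
sensible drinking) is exclusive to the non-risk tier, as the printed pools
imply. Low- and high-risk participants additionally receive messages on
their stated typical drinking day and time in weeks 1, 3, 5, 7, 9, 11 —
"biweekly" is read as every second week, 6 messages over the 12 weeks, and
the phase (odd vs even weeks) is configurable because it is otherwise
unstated.

The rotation of categories across weeks is not specified anywhere, so the
planner uses a seeded random shuffle of the pool cycled over the 12 weeks:
deterministic given the seed, no immediate repeats, and every pool category
appears at least once (pools have at most 9 elements). The weekly slot
defaults to Wednesday 17:00 (only the drinking-day timing is prescribed by
the design). Templates are English with `{placeholder}` tailoring slots;
rendering fails loudly on a missing value, an unresolved marker, or a text
exceeding the configured SMS limit (480 characters ≈ three concatenated
SMS).

Unsubscription is keyword-based (default {stop, ende, weg},
case-insensitive) with a manual-override flag for free-text withdrawal
requests, since the program accepts *any* expressed request to withdraw and
keyword matching is only the automatable proxy. The log is append-only and
time-ordered per person; after an unsubscription no outgoing event can be
recorded and pending plan entries are cancelled — a property test drives
random event sequences against these invariants.

## The synthetic cohort

`sim_config()` encodes the study conditions: 490 students present in 36
classes, 488 consenting, 477 phone owners; gender, age, migration,
education, smoking and RSOD-category marginals from the participant profile;
weekly drinks with mean 14.1 / SD 16.1 and max drinks with mean 11.6 / SD
10.8. Those moment pairs are far overdispersed relative to Poisson, so both
counts are zero-inflated negative binomial with NB parameters solved by
method of moments given the structural-zero share (defaults 0.15 and 0.10 —
roughly the abstaining fraction; only the mean/SD pairs are published, so
the zero mass is a modelling choice).

Structure beyond the marginals:

* **Class clustering.** A class-level random intercept enters the latent
  drinking propensity with weight √icc (default icc = 0.05, a typical
  school-class value; the real within-class correlation is unreported).
  This is precisely the dependence that motivates cluster-robust variance
  in the evaluation.
* **Within-person coupling.** RSOD category, weekly drinks and max drinks
  derive from correlated Gaussian latents (correlations 0.6 / 0.7), so
  heavy episodic drinkers also report higher volumes.
* **Selection processes.** Participation (among phone owners) is logistic
  in lower education (+) and max drinks (+); unsubscription is logistic in
  smoking (+) and RSOD band (+); follow-up attendance is logistic in the
  same two with negative signs. Intercepts were calibrated once, in closed
  form at the covariate means, to the marginal rates 76.3%, 6.3% and 76.9%.
* **Pre-post effects.** Binary outcomes transition with a target odds
  ratio: the follow-up prevalence is solved from
  `odds(p2) = OR × odds(p1)` and each person moves through a transition
  matrix interpolating between independence and maximal concordance
  (default concordance 0.5 — enough discordance to be realistic; the true
  within-person correlation is unreported). The two nested RSOD binaries
  transition hierarchically (any RSOD first, then frequent among the
  positives at the conditional target), so a person can never be frequent
  without being positive while both marginals hit their targets. Counts
  shift through a Gaussian copula on the mid-CDF latent with the NB mean
  scaled by the rate ratio (within-person rho 0.5). Effects apply to
  participants only; nonparticipants evolve under the null. Default
  effects: OR 0.66 / 0.76, IRR 0.83 / 0.91, OR 0.60.
* **Item missingness.** Follow-up items go missing at rates (RSOD 0.007,
  weekly drinks 0.118, max drinks 0.018, problems 0) that reproduce the
  per-outcome complete-case denominators of the emulated cohort (278, 247,
  275 and 280 of 280 attenders).

What the simulator does *not* emulate: message-level behavioural mechanisms
(the effect is a marginal pre-post shift, not a dose-response), seasonal or
school-level heterogeneity beyond the class intercept, gender-specific
drinking distributions (only overall moments are published), and
measurement error in self-report. Passing tests therefore demonstrate that
the pipeline recovers known effects from data with the right moments,
clustering and selection structure — not that the intervention works.

## Estimation

The evaluation model is `g(E[y]) = β₀ + β₁·I(followup)` fitted by
iteratively reweighted least squares under an **independence working
correlation**. With a saturated two-time-point mean model the point
estimates are invariant to the working correlation, so nothing is lost, and
all dependence — repeated measures within person, persons within class — is
handled by the cluster-robust sandwich variance with scores aggregated at
the school-class level (persons are nested in classes, so class aggregation
absorbs the person level too; `cluster_by = "person"` exists for
sensitivity). The exponentiated time coefficient is the OR (logistic) or
IRR (Poisson); no dispersion parameter is estimated because the sandwich CI
does not depend on one. No small-sample cluster correction is applied by
default (an optional G/(G−1) factor is available), matching common
large-sample practice.

Numerical choices: convergence at relative coefficient change < 1e-8
(Fisher scoring for canonical links is Newton's method, so the terminal
error is far below the tolerance — the saturated-model identity test holds
at 1e-8), at most 100 iterations, non-convergence flagged in the result
rather than silently returned (complete separation in a degenerate fixture
is the test case), and at least two clusters required. The independent
cross-check in the tests is `stats::glm` plus `sandwich::vcovCL(type =
"HC0", cadjust = FALSE)`, which agrees with the hand-rolled IRLS and
sandwich to 1e-6 over random datasets.

Simulation checks: type-I error of the time effect is 5.0% at 500 null
replicates of 278 paired binaries in 36 classes, and fitting data generated
with OR 0.66 recovers it with ~94% CI coverage. These simulations use a
generator with *fixed* transition probabilities; the package's
`transition_binary()` anchors on the realised baseline prevalence (the
right behaviour for constructing a cohort with a target effect), which
would couple the two time points within a replicate and understate the null
rejection rate.

The companion tests — Pearson chi-square (no continuity correction) and
Mann-Whitney U with mid-ranks — are small hand implementations because the
U test's contract here includes exact enumeration over all
`choose(nx+ny, nx)` labelings for combined samples up to 12 *including
ties*, which `stats::wilcox.test` does not provide; both are verified
against their base-R counterparts where the definitions coincide.

## Reporting conventions

Every percentage is rounded half-up to one decimal (the convention of the
reports being mirrored; IEEE round-half-even would print 76.25% as 76.2%).
Flow percentages use the conventional stage denominators (consent/present,
owners/consented, registered/owners, followed-up/owners,
unsubscribed/registered). Outcome and program-use tables carry per-outcome
and per-item complete-case denominators — never listwise deletion — because
item missingness varies by item; a fully missing item is reported with
n = 0 rather than dropped. A self-consistency test recomputes every emitted
percentage from its emitted numerator and denominator.

## Problem sizes used in the test suite

The default suite simulates cohorts of 60–10,000 students (10,000 for
marginal checks, 40 replicates of the full 488-student cohort for parameter
recovery, 500 replicates of 278 paired outcomes for the type-I and coverage
checks, 1,000 random participants for the plan invariants) and runs in
about 40 seconds on one core. These sizes were chosen so Monte-Carlo error
is well below each assertion's tolerance while the suite stays fast enough
to run on every change.

## Known limitations

* The shipped normative table is synthetic; real deployments must supply
  their own reference norms.
* Working correlations other than independence (exchangeable, AR(1)) are
  out of scope, as are mixed-effects alternatives to GEE.
* The BAC figure ignores elimination and individual variation in r; it is
  a communication device, not a forensic estimate.
* Stop-keyword matching will miss free-text withdrawal requests unless the
  operator sets the manual-override flag.
* `transition_binary()` targets the odds ratio in expectation at the
  cohort level; it is not a person-level causal model.
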