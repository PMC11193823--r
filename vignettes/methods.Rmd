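---
title: "Models and methods: treatment-efficacy expectations and reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`placeborl` implements a complete simulation-and-inference pipeline for a
probabilistic reinforcement learning (RL) task performed under five levels
of purported treatment efficacy (0, 25, 50, 75, 100 percent). This
vignette documents the models, the choices behind the defaults, and the
numerical decisions a user or reviewer would want to audit.

## The task

Three fixed pairs of opaque stimuli carry reward contingencies 80:20,
70:30 and 60:40 for the better versus worse option; each pair is presented
40 times, for 120 trials per participant, in a uniformly random
interleaving. "Balanced stimulus position" is interpreted strictly: within
a pair, each stimulus appears on the left on exactly half of that pair's
trials, which makes the balance testable; the trial order itself is an
unconstrained uniform permutation of the 120 slots (run-length constraints
on pair repetitions were considered and not adopted, since nothing in the
task's logic depends on them). Feedback is a Bernoulli draw with the chosen
stimulus's contingency. Timing fields (1700 ms response window, 1000 ms
feedback) are carried as design metadata only; nothing temporal is
simulated, and reaction times attached by the cohort generator are
log-normal decoration so that code paths averaging reaction times can be
exercised — they carry no model content.

## Model family

Four likelihood variants are implemented behind one interface:

* **SWo / SSo** — dual-rate Q-learning. Gain prediction errors
  (`r − Q > 0`) are weighted by `a_gain`, loss errors by `a_loss` (both in
  `[0, 1]`); choices follow an inverse-*gain* softmax in which Q-values are
  *divided* by `beta ≥ 0`, so larger `beta` is noisier. SWo and SSo share
  this likelihood and differ only in priors (below).
* **ES** — the dual-rate model extended by a forgetting rate `phi`
  (all six Q-values decay toward 0 each trial), an initial bias `q0`
  (a pair's first-chosen stimulus starts at `q0`), and irreducible noise
  `xi` mixing the softmax with a coin flip; here `beta` is an inverse
  *temperature* in `[0, 20]` that multiplies the Q-values.
* **RLf-CK** — a single learning rate `alpha`, forgetting `phi`, and a
  choice kernel: `CK` of the chosen (unchosen) option moves toward 1 (0)
  with rate `a_ck`, and enters the softmax weighted by a choice inverse
  temperature `tau` in `[−5, 5]`, capturing perseveration. Five parameters
  in total.

Three decisions had to be made where the model family is underdetermined:

* **Initial Q-values are 0 for every model.** The ES decay explicitly
  targets initial values of 0; for family consistency the dual-rate models
  start there too (0.5 would be the other defensible choice; the starting
  value only affects the first trials of each pair, before feedback
  dominates).
* **Within-trial operation order** (ES, RLf-CK): choice probability from
  the current state, then the reward update of the chosen stimulus, then
  the forgetting decay of all six values, then the choice-kernel update.
  Decay-after-update is adopted; "trial-by-trial" decay does not fix the
  order, and the alternative merely rescales `phi`.
* **ES initial bias**: on a pair's first trial the choice itself is made
  from equal (zero) values; immediately after that choice the chosen
  stimulus's value is set to `q0`, *before* the reward update. This is the
  only reading consistent with the constraint that the first-chosen option
  starts no lower than its partner.

## Numerical choices

Softmax probabilities are computed from logit differences through
`log1p(exp(·))`, never by exponentiating large logits. For the
inverse-gain rule, `beta` is clamped at `1e-6` from below, and an exact
value tie returns probability 0.5 *before* any division, so the tie
contract holds for every `beta` including 0. In simulation, ties are
detected by exact equality of the two computed probabilities and resolved
by a fair coin; all other choices compare a uniform threshold against the
choice probability. Bounded non-unit parameters (`beta ≤ 20`, `tau` in
`[−5, 5]`) use scaled-logit transforms `lo + (hi − lo) · logistic(x)`;
learning rates use plain logits and the inverse gain a log transform.
Transform round-trips are exact to 1e−12 across the ranges (tested).
Trials with missing responses are dropped from likelihoods, state updates
and rate denominators, and break stay-probability windows.

## Hierarchical inference

Each subject-level parameter `x` has, on its unconstrained scale, a normal
population model `x ~ N(mu0 + delta_j, sigma)` with the baseline group's
offset fixed at zero. Priors parameterize normals by the *standard
deviation* (the convention of the samplers this design descends from):
wide variant `mu0 ~ N(0, 100)`, `sigma ~ U(0, 100)`; narrow variant
`mu0 ~ N(0, 1)` and a half-normal `sigma ~ N+(0, 0.2)` — a plain normal is
stated for a positive quantity, so truncation to the positive half-line is
forced. The offset prior stays `delta ~ N(0, 3)` under both variants, since
only the mean and spread priors are described as changing. Offsets apply
to *every* model parameter, and subject draws are independent normals per
parameter (no correlation structure).

Sampling uses a blocked Metropolis-within-Gibbs kernel targeting exactly
the density exposed as `log_joint()`:

1. component-wise adaptive random-walk Metropolis on each subject
   parameter (vectorized across subjects, which are conditionally
   independent), with per-(subject, parameter) step sizes adapted toward
   0.44 acceptance during warm-up only — the retained chain is a fixed,
   valid Markov kernel;
2. an exact joint Gibbs draw of `(mu0, delta)` per parameter from its
   5-dimensional normal conditional (one-at-a-time Gibbs stalls because
   only `mu0 + delta_j` is likelihood-identified);
3. stepping-out slice sampling for each `sigma`;
4. interweaved translation moves that shift a group-level mean *together
   with its subjects' parameters* (residuals held fixed), and an analogous
   log-scale move rescaling residuals with `sigma` — without these,
   group-level quantities can only drift at the speed of the subjects'
   local walks, and the spread/parameter funnel mixes poorly.

Two full sweeps of this kernel make up one recorded iteration. Chains run
sequentially with seeds derived from the configuration seed, so results
are bit-reproducible. The `paper` preset mirrors the published bookkeeping
(8 chains × 10,000 warm-up + 10,000 retained = 80,000 group-level draws);
`target_accept = 0.99` and `max_tree_depth = 15` are recorded as metadata
of that tree-based configuration and have no analogue in this kernel. The
`test` preset (4 × 500/500) is used throughout the test suite; at that
scale a 141-subject fit converges (all split R-hat < 1.1) in about 80
seconds, while small cohorts (≈30 subjects) under the *wide* priors can
leave split R-hat slightly above 1.1 on heavy-tailed group-level
quantities — this is flagged in the returned object rather than hidden.
Split R-hat halves each chain before comparing between- to within-half
variance; effective sample sizes come from `coda::effectiveSize`.

`fit_mle()` is the fast point-estimation path (multi-start L-BFGS-B on the
unconstrained scale, box `[-8, 8]`, one start at the origin plus random
`N(0, 1.5)` starts). With 120 trials per subject its estimates are noisy
and boundary-prone — that is a property of the design, not the optimizer —
which is why recovery studies report *rank* correlations.

## Synthetic cohorts

The generator emulates the study's structure: uniform i.i.d. assignment to
the five groups (sizes unbalanced, as under online randomization), subject
parameters drawn around group-level means, and full trial tables simulated
at the true parameters. Preset group-offset shapes operationalize the
competing hypotheses on the gain learning rate: `monotonic` (offsets
0 … 0.8, increasing), `inverted_u` (0, 0.4, 0.8, 0.4, 0; peak 0.8 on the
logit scale, comparable to the large pairwise effects the design is meant
to detect) and `null`. The subject spread defaults to 0.4 on all
unconstrained scales: at that spread the *true* group means of cohorts of
100+ subjects show the peaked ordering in well over 95% of seeds, so
recovery failures indicate estimation, not generation. Baseline means are
`logit(0.35)` for the gain rate, `logit(0.12)` for the loss rate (floored,
as observed empirically in this task class) and `log(0.15)` for the
inverse gain (fairly informative choices).

What the generator does *not* emulate: real participants' reaction-time
structure, attention lapses, non-responses, session effects, or any
questionnaire-linked individual differences. Passing recovery tests on
these cohorts therefore shows that the estimation machinery works when the
model is true — not that the model is true of people.

## Hypothesis statistics

Pattern fractions count retained draws whose five group-level means
satisfy every inequality of a chain; inequalities are strict, so ties
fail. The reduced three-group patterns omit the 25% and 75% conditions.
Contrasts are summarized by the posterior mean, the equal-tailed 95%
credible interval, `pd = max(P(d>0), P(d<0))` (reported as missing, with a
warning, for an all-zero difference, where neither direction has mass),
`ps` (mass beyond the ROPE bound in the direction of the median — the
ROPE-based convention), and the percentage of draws inside
`ROPE = [−0.1, 0.1]` on the unconstrained scale. The trend regression
codes groups as centered values −50 … 50 and compares linear against
linear+quadratic least-squares fits; a constant response returns zero
coefficients and R² = 0 rather than an error. BIC-based Bayes factors
default to the conventional orientation
`BF10 = exp((BIC_null − BIC_alt)/2)`; the reversed sign occasionally seen
in print is available explicitly as `orientation = "printed"` rather than
guessed at.

## Model evaluation

Model accuracy is the mean likelihood assigned to observed choices at
subject-level *posterior-mean* parameters (draw-averaged accuracy is
available through the pointwise likelihood matrix, but the mean-parameter
version is canonical). Posterior predictive simulation re-draws choices on
the observed task structure and on fresh schedules, 20-fold because
choices are sampled against uniform thresholds. PSIS-LOO treats the single
trial as the observation unit, matching the pointwise likelihood
construction; importance ratios have their largest 20% replaced by
expected order statistics of a generalized Pareto distribution fitted to
that tail (Zhang–Stephens-style profile fit, weak prior pulling the shape
toward 0.5), truncated at the raw maximum; tail shapes above 0.7 are
flagged, and degenerate tails (ties, too few exceedances) fall back to
unsmoothed ratios. The implementation is checked against exact
leave-one-out on an enumerable grid posterior (tolerance 0.05 on elpd).
Parameter recovery simulates fresh sessions at true parameters, refits
(maximum likelihood by default, for runtime; hierarchical optionally) and
reports Spearman correlations per parameter, with constant-truth
parameters reported as missing.

## Problem sizes

The packaged analyses and tests run at desk scale by choice: 141-subject
cohorts for the main pipeline, 30–50 subjects for recovery studies, the
4 × 500/500 sampler preset, 20-fold predictive repeats, and enumeration
oracles over all 2^8 choice sequences. All of these are configuration
arguments; the paper-scale sampler preset is constructed (and its
bookkeeping tested) but not run by default.

## Known limitations

* The random-walk kernel, although exact, is far less draw-efficient than
  a gradient sampler; paper-scale runs are possible but slow, and wide-
  prior fits of very small cohorts may need more than the test preset's
  iterations to pass strict convergence thresholds.
* Under near-deterministic generating regimes (inverse gain ≪ 0.2) the
  gain learning rate is only weakly likelihood-identified in 120 trials;
  estimates legitimately pile toward 1 and only orderings are meaningful.
* Reaction times are carried but never modelled; stay-probability windows
  assume consecutive same-pair presentations.
* The hierarchy assumes independent normal populations per parameter; no
  subject-level correlation structure is estimated.
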