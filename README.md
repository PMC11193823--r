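# placeborl

Does *uncertainty* about whether a treatment works change how people learn
from reward? If placebo responses and reward processing share dopaminergic
machinery, the interesting prediction is non-monotonic: reward sensitivity
should peak when a purported treatment's efficacy is maximally uncertain
(50%), not when it is most certain. `placeborl` implements the full
computational pipeline for testing that prediction with a probabilistic
reinforcement learning (RL) task performed under five levels of purported
treatment efficacy (0/25/50/75/100%): task simulation, synthetic cohorts,
hierarchical Bayesian Q-learning, bespoke posterior pattern statistics, and
model evaluation. It is aimed at computational-psychiatry researchers who
want to simulate, fit and power-check this class of design without the
original participant data.

## The task and the models

Participants learn three fixed stimulus pairs with reward contingencies
80:20, 70:30 and 60:40 (40 trials per pair, 120 trials total, positions
balanced). The core model is dual-rate Q-learning: the chosen stimulus's
expected value is updated by

    Q(t+1) = Q(t) + alpha_G * [r - Q(t)]+  +  alpha_L * [r - Q(t)]-

with separate learning rates for gain (`r - Q > 0`) and loss prediction
errors, and choices follow an inverse-*gain* softmax,

    P(A) = exp(Q_A / beta) / (exp(Q_A / beta) + exp(Q_B / beta)),

where larger `beta` means noisier choice. Subject parameters live on
unconstrained scales (logit for learning rates, log for `beta`) and are
drawn from five group-level normal distributions,

    logit(alpha_j) ~ Normal(mu_alpha0 + delta_alpha_j, sigma_alpha),
    j in {0, 25, 50, 75, 100},  delta_0 = 0,

under wide (`mu ~ N(0,100)`, `sigma ~ U(0,100)`; "SWo") or narrow
(`mu ~ N(0,1)`, half-`N(0,0.2)`; "SSo") priors, with `delta ~ N(0,3)`.
Two extended variants are included: **ES** (forgetting decay of all six
Q-values toward 0, an initial bias for a pair's first-chosen option, and
irreducible decision noise) and **RLf-CK** (a single learning rate plus
forgetting and a choice kernel capturing perseveration).

The hypothesis statistics count posterior draws in which the five
group-level means satisfy strict inequality chains — a monotonic increase
`mu(0) < mu(25) < mu(50) < mu(75) < mu(100)` versus an inverted U
`mu(0) < mu(25) < mu(50) > mu(75) > mu(100)` — and summarize pairwise group
contrasts by the probability of direction (pd), practical significance (ps)
and the share of draws inside the ROPE `[-0.1, 0.1]`. Model evaluation
covers model accuracy (mean likelihood of observed choices), 20-fold
posterior predictive simulation, trial-level PSIS-LOO, and parameter
recovery by rank correlation.

## Worked example

The numbered scripts under `analysis/` run the whole study at desk scale;
each stage writes its tables under `results/`.

```sh
Rscript analysis/01_simulate_cohort.R     # 141 subjects, inverted-U scenario
Rscript analysis/02_fit_hierarchical.R    # hierarchical SWo fit (~80 s)
Rscript analysis/03_hypothesis_tests.R
Rscript analysis/04_model_evaluation.R
Rscript analysis/05_behavioral_metrics.R
```

Stage 2 prints, for the simulated cohort (truth: gain-rate offsets
0 / 0.4 / 0.8 / 0.4 / 0 on the logit scale, peaked at the 50% group):

    Hierarchical posterior: SWo / wide priors / 4 chains x 500 retained iterations
    141 subjects; mean subject-block acceptance 0.45
    max split R-hat: 1.0843 (converged)
    Model accuracy (mean likelihood of observed choices): 0.905
    Group-level gain-learning-rate means (posterior means, logit scale):
         0     25     50     75    100
    -0.352 -0.228  0.327 -0.450 -0.691

The posterior means reproduce the generative peak at maximum uncertainty.
Stage 3 then quantifies the pattern evidence:

    Pattern fractions for the gain learning rate:
      inverted-U (5 groups):  53.8%
      monotonic  (5 groups):  0.0%
      inverted-U (0/50/100):  99.2%
      monotonic  (0/50/100):  0.0%

so over half of all retained draws satisfy the full five-group inverted-U
chain and essentially none the monotonic one; the strongest pairwise
contrasts are 0–50% (mean −0.68, pd 0.993) and 50–100% (mean 1.02,
pd 1.000), and adding a quadratic term to the trend regression raises R²
from 0.13 to 0.63. Stage 4 reports trial-level PSIS-LOO (LOOIC 5493.8,
se 60.4) and maximum-likelihood parameter recovery (rank correlations
0.43 / 0.35 / 0.66 for the gain rate, loss rate and inverse gain).

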