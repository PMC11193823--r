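#!/usr/bin/env Rscript
# Stage 4: model evaluation.
#
# (a) 20-fold posterior predictive choice simulation at the subject
#     posterior means, on the observed task structure and on fresh
#     schedules; (b) PSIS-LOO (trial-level) for the fitted model;
# (c) maximum-likelihood parameter recovery for the full cohort
#     (simulate fresh sessions at the true parameters, refit, rank-correlate).
#
# Reads results/trials.csv, results/posterior.rds, results/cohort_truth.csv;
# writes results/evaluation.json.

suppressPackageStartupMessages(library(placeborl))

table <- read_trial_table("results/trials.csv")
draws <- readRDS("results/posterior.rds")
means <- subject_posterior_means(draws)

ppc <- posterior_predictive(table, means, "SWo", repeats = 20, seed = 401)
obs_rate <- mean(table$optimal)
sim_rate <- mean(unlist(lapply(ppc$sim_tables, function(t) t$optimal)))
cat(sprintf("Observed optimal-choice rate: %.3f\n", obs_rate))
cat(sprintf("Simulated optimal-choice rate (20 repeats, fresh schedules): %.3f\n",
            sim_rate))

loo <- psis_loo(pointwise_loglik(draws, table,
                                 thin = max(1L, floor(dim(draws$subj)[1] / 400))))
print(loo)

truth <- read.csv("results/cohort_truth.csv")
rec <- parameter_recovery("SWo", truth, fit_method = "mle", seed = 402)
print(rec)

jsonlite::write_json(
  list(model_accuracy = model_accuracy(table, means, "SWo"),
       observed_optimal_rate = obs_rate,
       simulated_optimal_rate = sim_rate,
       looic = loo$looic, elpd_loo = loo$elpd_loo, loo_se = loo$se,
       recovery = rec$per_parameter, mean_recovery_rho = rec$mean_rho),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/evaluation.json\n")
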