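#!/usr/bin/env Rscript
# Stage 3: posterior hypothesis statistics.
#
# Tests the two competing accounts of how purported treatment efficacy
# moderates reward learning: a monotonic increase vs. an inverted U peaking
# under maximum uncertainty (50%). Counts the fraction of retained draws in
# which the five group-level gain-learning-rate means satisfy each strict
# inequality chain, computes all ten pairwise group contrasts
# (pd / ps / %-in-ROPE, ROPE = [-0.1, 0.1]), and runs the linear+quadratic
# trend regression on centered group values (-50..50).
#
# Reads results/posterior.rds; writes results/hypotheses.json.

suppressPackageStartupMessages(library(placeborl))

draws <- readRDS("results/posterior.rds")

frac <- pattern_fractions(draws, "a_gain")
cat("Pattern fractions for the gain learning rate:\n")
cat(sprintf("  inverted-U (5 groups):  %.1f%%\n", 100 * frac[["invU5"]]))
cat(sprintf("  monotonic  (5 groups):  %.1f%%\n", 100 * frac[["monotonic5"]]))
cat(sprintf("  inverted-U (0/50/100):  %.1f%%\n", 100 * frac[["invU3"]]))
cat(sprintf("  monotonic  (0/50/100):  %.1f%%\n", 100 * frac[["monotonic3"]]))

cat("\nPairwise group contrasts (gain learning rate, logit scale):\n")
print(within(contrast_table(draws, "a_gain"), {
  mean <- round(mean, 2); ci_lower <- round(ci_lower, 2)
  ci_upper <- round(ci_upper, 2); pd <- round(pd, 3)
  ps <- round(ps, 2); pct_rope <- round(pct_rope, 1)
}), row.names = FALSE)

means <- subject_posterior_means(draws)
tr <- quadratic_trend(means$u_a_gain, means$group)
cat(sprintf("\nTrend regression on subject posterior means (logit gain rate):\n"))
cat(sprintf("  linear b = %.4f, quadratic b = %.6f\n", tr$b_linear, tr$b_quadratic))
cat(sprintf("  R2 linear = %.3f, R2 full = %.3f, delta R2 = %.3f\n",
            tr$r2_linear, tr$r2_full, tr$delta_r2))

report <- hypothesis_report(draws, path = "results/hypotheses.json")
cat("\nWrote results/hypotheses.json\n")
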