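#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds the probabilistic RL task (three pairs, 80:20 / 70:30 / 60:40,
# 40 trials per pair) and a synthetic cohort of 141 participants assigned
# uniformly at random to the five purported treatment-efficacy groups
# (0/25/50/75/100%). The cohort follows the inverted-U scenario: group-level
# gain-learning-rate offsets peak in the maximum-uncertainty (50%) group.
# Writes results/trials.csv and results/cohort_truth.csv.

suppressPackageStartupMessages(library(placeborl))
dir.create("results", showWarnings = FALSE)

design <- default_design()
scenario <- make_scenario("inverted_u", model_id = "SWo", n_subjects = 141)
print(scenario)

cohort <- draw_cohort(scenario, seed = 101)
table <- simulate_cohort(cohort, design, seed = 102)

write.csv(as.data.frame(cohort), "results/cohort_truth.csv", row.names = FALSE)
write_trial_table(table, "results/trials.csv")

cat("\nGroup sizes:\n")
print(table(cohort$group))

beh <- aggregate_behavior(table)
cat("\nBehavioral summary (means across subjects):\n")
cat(sprintf("  optimal choices: %.3f\n", mean(beh$optimal_rate)))
cat(sprintf("  collected reward: %.3f\n", mean(beh$reward_rate)))
cat(sprintf("  stay probability: %.3f\n", mean(beh$stay_prob, na.rm = TRUE)))

kept <- exclusion_filter(table)
cat(sprintf("\nExclusion rule (count < mean - 3 sd): %d of %d subjects retained\n",
            length(kept), nrow(beh)))

for (p in 1:3) {
  rows <- table[table$pair == p, ]
  cat(sprintf("  pair %d (%.0f:%.0f): optimal-choice rate %.3f\n", p,
              100 * design$pairs$p_reward_better[p],
              100 * (1 - design$pairs$p_reward_better[p]),
              mean(rows$optimal)))
}
cat("\nWrote results/trials.csv and results/cohort_truth.csv\n")
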