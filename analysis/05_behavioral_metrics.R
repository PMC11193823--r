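#!/usr/bin/env Rscript
# Stage 5: conventional behavioral summaries.
#
# Per-subject aggregates (optimal choices, collected reward, stay
# probability, reaction time), within-pair cumulative-mean learning curves,
# and sliding-window correlations (window 20, step 1, first window at
# trial 20) between each subject's fitted inverse gain and the windowed
# mean of optimal choices.
#
# Reads results/trials.csv and results/subject_posterior_means.csv; writes
# results/behavior_subjects.csv, results/learning_curves.csv and
# results/window_correlations.csv.

suppressPackageStartupMessages(library(placeborl))

table <- read_trial_table("results/trials.csv")
beh <- aggregate_behavior(table)
write.csv(beh, "results/behavior_subjects.csv", row.names = FALSE)

cat("Behavioral aggregates by group:\n")
print(aggregate(cbind(optimal_rate, reward_rate, stay_prob) ~ group, beh, mean),
      row.names = FALSE)

curves <- cumulative_curves(table, "optimal")
write.csv(curves$summary, "results/learning_curves.csv", row.names = FALSE)
last <- curves$summary[curves$summary$pair_trial == max(curves$summary$pair_trial), ]
cat("\nFinal cumulative optimal-choice mean per pair:\n")
print(last, row.names = FALSE)

means <- read.csv("results/subject_posterior_means.csv")
stat <- data.frame(subject_id = means$subject_id, value = means$u_beta)
wc <- sliding_window_correlation(table, stat, "optimal", window = 20, step = 1)
write.csv(wc, "results/window_correlations.csv", row.names = FALSE)
cat(sprintf("\nInverse gain vs. windowed optimal choices: r ranges %.2f to %.2f over %d windows\n",
            min(wc$r, na.rm = TRUE), max(wc$r, na.rm = TRUE), nrow(wc)))
cat("Wrote results/behavior_subjects.csv, learning_curves.csv, window_correlations.csv\n")
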