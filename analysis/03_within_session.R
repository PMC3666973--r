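#!/usr/bin/env Rscript

# Within-session decoding: for every participant and session, a Gaussian
# naive Bayes classifier under leave-one-out cross-validation, for the
# four-task and the two-scene-task designs, with four and eight features.

library(gazetask)

cfg <- experiment_config(cohort = "results/events.csv",
                         schemes = "within_loocv")
res <- run_experiment(cfg)

acc <- res$accuracies
write.csv(acc, "results/within_accuracies.csv", row.names = FALSE)

cat("Within-session leave-one-out accuracy (mean +/- SD over",
    length(unique(acc$participant)), "participants x 2 sessions):\n\n")
print(res$summary, row.names = FALSE, digits = 3)
cat("\nChance is 25% for the four-task design and ~50% for the",
    "scene-task design.\n")
cat("wrote results/within_accuracies.csv\n")
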