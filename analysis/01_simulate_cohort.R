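#!/usr/bin/env Rscript

# Simulate the default synthetic cohort: 12 participants x 2 sessions,
# per-session trial counts 40 memorization / 35 reading / 48 search /
# 35 pseudo-reading, 12-second trials. Writes the raw event table that
# the rest of the analysis consumes.

library(gazetask)

dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(rng_seed = 1)
events <- generate_cohort(cfg)
write_event_table(events, "results/events.csv")

trials <- unique(events[c("participant", "session", "task", "trial")])
cat("Simulated cohort:\n")
cat("  events:", nrow(events), "\n")
cat("  trials:", nrow(trials), "across",
    length(unique(events$participant)), "participants x",
    length(unique(events$session)), "sessions\n")
print(table(trials$task) / (cfg$n_participants * cfg$n_sessions))

search <- unique(events[events$task == "scene_search",
                        c("participant", "session", "trial",
                          "target_present", "target_found")])
cat(sprintf("  search trials without a target: %.1f%% (design: 33.3%%)\n",
            100 * mean(!search$target_present)))
cat(sprintf("  search trials with the target found: %.1f%%%s\n",
            100 * mean(search$target_found),
            " (these are excluded in preprocessing)"))
cat("wrote results/events.csv\n")
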