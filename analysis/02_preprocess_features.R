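#!/usr/bin/env Rscript

# Apply the exclusion rules (fixations > 1500 ms, blink-adjacent events,
# search trials where the target was found) and build the four- and
# eight-feature trial summaries.

library(gazetask)

events <- read_event_table("results/events.csv")
n_fix_before <- sum(events$event_type == "fixation")

clean <- preprocess_events(events)
n_fix_after <- sum(clean$event_type == "fixation")
trials_before <- nrow(unique(events[c("participant", "session", "task",
                                      "trial")]))
trials_after <- nrow(unique(clean[c("participant", "session", "task",
                                    "trial")]))
cat("Preprocessing:\n")
cat(sprintf("  fixations: %d -> %d (%.2f%% removed)\n", n_fix_before,
            n_fix_after, 100 * (1 - n_fix_after / n_fix_before)))
cat(sprintf("  trials:    %d -> %d (found-target search trials and\n",
            trials_before, trials_after))
cat("             starved trials removed)\n")

for (mode in c("four", "eight")) {
  ft <- feature_table(clean, mode = mode)
  out <- sprintf("results/features_%s.csv", mode)
  write.csv(ft, out, row.names = FALSE)
  cat(sprintf("  %s-feature table: %d trials -> %s\n", mode, nrow(ft), out))
}
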