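#!/usr/bin/env Rscript
# Generate the default synthetic session (the study conditions for every
# downstream analysis) and summarize its task statistics.

library(popdyn)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
s <- simulate_session(cfg)
write_session(s, "results/session.rds")

trs <- trials_of(s)
has_refix <- vapply(trs, function(tr) any(tr$fixations$is_refixation),
                    logical(1))
durs <- unlist(lapply(trs, function(tr) {
  k <- nrow(tr$fixations)
  if (k > 1) tr$fixations$offset[-k] - tr$fixations$onset[-k] else numeric(0)
}))
behav <- data.frame(
  n_trials = length(s$trials),
  n_correct = length(trs),
  accuracy_pct = 100 * length(trs) / length(s$trials),
  mean_fixations_per_trial = mean(vapply(trs, `[[`, 0L, "n_fixations")),
  mean_fixation_duration_ms = mean(durs),
  refixation_trial_pct = 100 * mean(has_refix))
write.csv(behav, "results/behavior.csv", row.names = FALSE)
message(sprintf(
  "session: %d units, %d trials; accuracy %.1f%%; mean fixation %.0f ms; return fixation in %.1f%% of correct trials",
  length(s$units), length(s$trials), behav$accuracy_pct,
  behav$mean_fixation_duration_ms, behav$refixation_trial_pct))
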