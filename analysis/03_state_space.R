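#!/usr/bin/env Rscript
# dPCA state-space trajectories per task epoch with the shuffle/FDR
# separation test: do population dynamics distinguish cue categories during
# cue and delay, and attentional states during search?

library(popdyn)
s <- read_session("results/session_classified.rds")
tab <- unit_label_table(s)
fov <- tab$rf_class %in% c("focal_foveal", "broad_foveal")

out <- list()
for (ep in c("cue", "delay", "search")) {
  cond <- if (ep == "search") "attention" else "category"
  ps <- build_psth_matrix(s, fov, epoch = ep, conditions = cond)
  tst <- trajectory_separation_test(ps, n_perm = 1000,
                                    seed = mix_seed(1, "traj", ep))
  message(sprintf("%s (%s): %d/%d bins separate conditions (FDR 0.05)",
                  ep, cond, sum(tst$significant), length(tst$significant)))
  out[[ep]] <- list(conditions = cond, times = tst$times,
                    distance = tst$distance, p_fdr = tst$p_fdr,
                    significant = tst$significant)
}
jsonlite::write_json(out, "results/state_space.json", auto_unbox = TRUE,
                     digits = NA)
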