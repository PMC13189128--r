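#!/usr/bin/env Rscript
# Spatial representational similarity: does the foveal population preserve
# the physical geometry of the 20 array locations across the four 50-ms
# post-fixation windows?

library(popdyn)
s <- read_session("results/session_classified.rds")
tab <- unit_label_table(s)
fov <- tab$rf_class %in% c("focal_foveal", "broad_foveal")

pdm <- physical_dm(s$array_geometry)
dms <- neural_dm(s, fov)
lays <- spatial_state_space(s, s$array_geometry, fov)
win_names <- c("0-50", "50-100", "100-150", "150-200")
out <- list()
for (i in seq_along(dms)) {
  tst <- rsa_correlation_test(dms[[i]], pdm, n_perm = 1000,
                              seed = mix_seed(1, "rsa", i))
  message(sprintf(
    "window %s ms: Spearman rho = %.2f (perm p = %.3f%s); alignment residual %.2f",
    win_names[i], tst$rho, tst$p,
    if (tst$significant) ", significant after Bonferroni" else "",
    lays[[i]]$residual))
  out[[win_names[i]]] <- list(rho = tst$rho, p = tst$p,
                              significant = tst$significant,
                              alignment_residual = lays[[i]]$residual,
                              n_locations = tst$n_locations)
  write.csv(dms[[i]]$values,
            sprintf("results/neural_dm_%s.csv", gsub("-", "_", win_names[i])))
}
write.csv(pdm$values, "results/physical_dm.csv")
jsonlite::write_json(out, "results/spatial_rsa.json", auto_unbox = TRUE,
                     digits = NA)
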