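#!/usr/bin/env Rscript
# 12-indicator lasso encoding model for localized peripheral units and the
# geometry of the encoded stimulus types per foveal attentional state.

library(popdyn)
s <- read_session("results/session_classified.rds")
tab <- unit_label_table(s)
peri <- which(tab$rf_class == "peripheral_localized")

fits <- list()
for (i in peri) {
  des <- build_design(s, s$units[[i]], s$units[[i]]$rf_locations)
  if (is.null(des) || length(des$y) < 40) next
  fits[[tab$unit_id[i]]] <- fit_lasso_splits(des, n_splits = 100,
                                             seed = mix_seed(1, "lasso", i))
}
cm <- do.call(rbind, lapply(fits, `[[`, "coef_mean"))
write.csv(data.frame(unit_id = rownames(cm), cm),
          "results/encoding_coefficients.csv", row.names = FALSE)
message(sprintf("fitted %d peripheral units (of %d localized)",
                length(fits), length(peri)))
if (length(fits) >= 10) {
  ass <- attention_subspace_summary(cm, seed = mix_seed(1, "enc"))
  message(sprintf(
    "stimulus-type separation: distance %.1f (on-target) vs %.1f (on-distractor), paired t(%d) p = %.2g",
    ass$target_state$distance, ass$distractor_state$distance,
    ass$n_subsets - 1, ass$distance_test$p.value))
  jsonlite::write_json(
    list(n_units = ass$n_units,
         distance_target = ass$target_state$distance,
         distance_distractor = ass$distractor_state$distance,
         angle_target = ass$target_state$angle,
         angle_distractor = ass$distractor_state$angle,
         distance_p = ass$distance_test$p.value,
         angle_p = ass$angle_test$p.value,
         alignment_residual = ass$alignment_residual),
    "results/encoding_geometry.json", auto_unbox = TRUE, digits = NA)
}
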