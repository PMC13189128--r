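#!/usr/bin/env Rscript
# Context effects on foveal responses and coding geometry: first-time vs
# return fixations, before vs after the first target fixation, the angle
# between the category and attention classifier hyperplanes, and the
# divergence of cue representations by the end of search.

library(popdyn)
s <- read_session("results/session_classified.rds")
tab <- unit_label_table(s)
fov <- tab$rf_class %in% c("focal_foveal", "broad_foveal")
out <- list()

for (sp in c("refixation", "target")) {
  cc <- context_comparison(s, fov, split = sp)
  message(sprintf(
    "%s split (%s): t(%d) = %.2f, p = %.2g; distance %s; angle %s",
    sp, paste(cc$groups, collapse = " vs "), cc$n_units - 1,
    cc$paired_test$statistic, cc$paired_test$p.value,
    paste(sprintf("%.2f", cc$distance), collapse = "/"),
    paste(sprintf("%.1f", cc$angle), collapse = "/")))
  out[[sp]] <- list(groups = cc$groups, n_units = cc$n_units,
                    t = unname(cc$paired_test$statistic),
                    p = cc$paired_test$p.value,
                    distance = cc$distance, angle = cc$angle)
}

fixtab <- fixation_table(s)
R <- vapply(s$units[fov], function(u)
  unit_fixation_responses(u, fixtab, c(0, 255)), numeric(nrow(fixtab)))
lab_cat <- ifelse(!fixtab$is_target &
                    fixtab$item_category %in% c("face", "house"),
                  fixtab$item_category, NA)
lab_att <- ifelse(fixtab$item_category %in% c("face", "house"),
                  ifelse(fixtab$is_target, "target", "distractor"), NA)
hp <- suppressWarnings(hyperplane_angle(R, lab_cat, lab_att,
                                        n_subsamples = 100,
                                        n_shuffles = 1000,
                                        seed = mix_seed(1, "hp")))
message(sprintf(
  "category/attention hyperplane angle: %.1f deg (null mean %.1f, p = %.2g)",
  hp$angle, mean(hp$null_angles), hp$p))
out$hyperplane <- list(angle = hp$angle, null_mean = mean(hp$null_angles),
                       p = hp$p)

dv <- divergence_at_search_end(s, fov, seed = mix_seed(1, "div"))
message(sprintf(
  "cue-representation distance: %.2f at search onset -> %.2f at search end (paired p = %.2g)",
  dv$distance["onset"], dv$distance["end"], dv$distance_test$p.value))
out$divergence <- list(distance = as.list(dv$distance),
                       angle = as.list(dv$angle),
                       distance_p = dv$distance_test$p.value,
                       angle_p = dv$angle_test$p.value)
jsonlite::write_json(out, "results/context_geometry.json",
                     auto_unbox = TRUE, digits = NA)
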