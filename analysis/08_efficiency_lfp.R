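#!/usr/bin/env Rscript
# Search-efficiency correlates: presearch firing rate vs fixation count,
# overlap of efficiency-coding units with the selective populations, and
# theta-band LFP power per epoch.

library(popdyn)
s <- read_session("results/session_classified.rds")
tab <- unit_label_table(s)

et <- efficiency_table(s)
write.csv(et, "results/efficiency.csv", row.names = FALSE)
message(sprintf(
  "efficiency-correlated units: %.1f%% positive, %.1f%% negative (delay window)",
  100 * mean(et$class == "positive"), 100 * mean(et$class == "negative")))

cat_sel <- tab$category_class %in% c("face_selective", "house_selective")
att_sel <- tab$attention_selective %in% TRUE
out <- list(prop_positive = mean(et$class == "positive"),
            prop_negative = mean(et$class == "negative"))
for (cl in c("positive", "negative")) {
  mask <- et$class == cl
  if (sum(mask) < 3) next
  ov_c <- overlap_test(mask, cat_sel)
  ov_a <- overlap_test(mask, att_sel)
  message(sprintf(
    "%s units overlap: category-selective %.0f%% vs %.0f%% (p = %.2g); attention-selective %.0f%% vs %.0f%% (p = %.2g)",
    cl, 100 * ov_c$prop_in_a, 100 * ov_c$prop_overall, ov_c$p,
    100 * ov_a$prop_in_a, 100 * ov_a$prop_overall, ov_a$p))
  out[[paste0("overlap_", cl)]] <- list(category_p = ov_c$p,
                                        attention_p = ov_a$p)
}

if (!is.null(s$lfp)) {
  th_c <- theta_power_correlation(s, "cue")
  th_d <- theta_power_correlation(s, "delay")
  message(sprintf(
    "theta power vs fixation count: cue r = %.2f (p = %.2g), delay r = %.2f (p = %.2g)",
    th_c$r, th_c$p, th_d$r, th_d$p))
  out$theta <- list(cue_r = th_c$r, cue_p = th_c$p,
                    delay_r = th_d$r, delay_p = th_d$p,
                    band = th_c$band)
}
jsonlite::write_json(out, "results/efficiency_lfp.json", auto_unbox = TRUE,
                     digits = NA)
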