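#!/usr/bin/env Rscript
# Receptive-field, category and attention classification of every unit,
# plus the overlap between the category- and attention-selective
# populations.

library(popdyn)
s <- read_session("results/session.rds")
s <- classify_units(s)
write_session(s, "results/session_classified.rds")

tab <- unit_label_table(s)
write.csv(tab, "results/unit_labels.csv", row.names = FALSE)
export_unit_labels(s, "results/unit_labels.json")

message(sprintf("RF classes: %s",
                paste(names(table(tab$rf_class)), table(tab$rf_class),
                      sep = "=", collapse = ", ")))
cat_sel <- tab$category_class %in% c("face_selective", "house_selective")
att_sel <- tab$attention_selective %in% TRUE
message(sprintf("category-selective: %d (%.1f%%); attention-selective: %d (%.1f%%)",
                sum(cat_sel), 100 * mean(cat_sel),
                sum(att_sel), 100 * mean(att_sel)))
ov <- overlap_test(cat_sel, att_sel)
message(sprintf(
  "attention-selective within category-selective: %.1f%% vs %.1f%% overall (chi2 = %.2f, p = %.3g)",
  100 * ov$prop_in_a, 100 * ov$prop_overall, ov$chi2, ov$p))
jsonlite::write_json(ov, "results/selective_overlap.json",
                     auto_unbox = TRUE, digits = NA)
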