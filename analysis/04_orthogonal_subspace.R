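#!/usr/bin/env Rscript
# Decompose the 16-stimulus x 2-attention-state condition points into the
# population-average-rate axis and its orthogonal plane, and classify
# attention and category from each component separately.

library(popdyn)
s <- read_session("results/session_classified.rds")
tab <- unit_label_table(s)
fov <- tab$rf_class %in% c("focal_foveal", "broad_foveal")

out <- list()
for (sub in c("attention", "category")) {
  cp <- build_condition_points(s, fov, subspace = sub)
  lab <- rep(if (sub == "attention") cp$labels$attention else
               cp$labels$category, times = length(cp$times))
  par_acc <- classify_component(cp$decomposed, lab, "parallel")
  ort_acc <- classify_component(cp$decomposed, lab, "orthogonal")
  message(sprintf(
    "%s subspace (%d stimuli): parallel accuracy %.2f, orthogonal %.2f",
    sub, length(cp$stimuli), par_acc$accuracy, ort_acc$accuracy))
  out[[sub]] <- list(tau = cp$tau, times = cp$times,
                     n_stimuli = length(cp$stimuli),
                     parallel_accuracy = par_acc$accuracy,
                     orthogonal_accuracy = ort_acc$accuracy,
                     parallel_accuracy_insample = par_acc$accuracy_insample,
                     orthogonal_accuracy_insample = ort_acc$accuracy_insample)
}
jsonlite::write_json(out, "results/orthogonal_subspace.json",
                     auto_unbox = TRUE, digits = NA)
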