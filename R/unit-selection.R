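## Unit classification: receptive field (focal/broad foveal, localized/
## unlocalized peripheral), category selectivity (rank-sum + SI >= 0.13),
## attention selectivity (signed-rank on target vs distractor fixation
## responses), and the selective-population overlap test.

#' Selection configuration
#'
#' Windows follow the analysis conventions: responses 50-200 ms after
#' cue/array onset against a -150-0 ms baseline; attention responses
#' 150-225 ms after fixation onset; alpha 0.05; SI threshold 0.13 (the
#' "at least 130%" rule).
#'
#' @param response_window,baseline_window,attention_window ms windows.
#' @param alpha Significance threshold.
#' @param si_threshold Absolute SI cut for category selectivity.
#' @param min_trials,min_fixations Minimum observations per condition.
#' @return List of class `"selection_config"`.
#' @export
selection_config <- function(response_window = c(50, 200),
                             baseline_window = c(-150, 0),
                             attention_window = c(150, 225),
                             alpha = 0.05, si_threshold = 0.13,
                             min_trials = 10L, min_fixations = 10L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "selection_config")
}

# one-sided rank-sum p for response > baseline, NA-safe
.rs_greater <- function(resp, base) {
  if (length(resp) < 3 || length(base) < 3) return(NA_real_)
  if (all(resp == resp[1]) && all(base == base[1]) && resp[1] == base[1])
    return(1)
  suppressWarnings(stats::wilcox.test(resp, base,
                                      alternative = "greater")$p.value)
}

#' Classify a unit's receptive field
#'
#' Rank-sum tests of post-stimulus versus baseline rate for the cue and for
#' the array: cue-only responders are focal foveal, cue+array broad foveal,
#' array-only peripheral. Peripheral units are split into localized versus
#' unlocalized by a per-location spatial-tuning test: the array response is
#' compared between trials where each location is occupied versus empty
#' (rank-sum, Bonferroni over the 20 locations); any significant location
#' marks the unit localized and defines its RF location set.
#'
#' @param s A [session()].
#' @param unit A [unit_record()].
#' @param config A [selection_config()].
#' @return List: `rf_class`, `p_cue`, `p_array`, `rf_locations` (integer
#'   vector, localized peripheral units only).
#' @export
classify_rf <- function(s, unit, config = selection_config()) {
  tr <- trials_of(s)
  if (length(tr) < config$min_trials)
    return(list(rf_class = "unset", p_cue = NA_real_, p_array = NA_real_,
                rf_locations = integer(0)))
  cue_resp <- unit_event_responses(unit, tr, "cue_on", config$response_window)
  cue_base <- unit_event_responses(unit, tr, "cue_on", config$baseline_window)
  arr_resp <- unit_event_responses(unit, tr, "array_on", config$response_window)
  arr_base <- unit_event_responses(unit, tr, "array_on", config$baseline_window)
  p_cue <- .rs_greater(cue_resp, cue_base)
  p_array <- .rs_greater(arr_resp, arr_base)
  a <- config$alpha
  rf_locations <- integer(0)
  cls <- if (is.na(p_cue) || is.na(p_array)) "unset"
  else if (p_cue < a && p_array >= a) "focal_foveal"
  else if (p_cue < a && p_array < a) "broad_foveal"
  else if (p_cue >= a && p_array < a) {
    occ <- vapply(tr, function(x) {
      v <- logical(20); v[x$array_items$location_index] <- TRUE; v
    }, logical(20))
    p_loc <- vapply(seq_len(20), function(l) {
      if (sum(occ[l, ]) < 5 || sum(!occ[l, ]) < 5) return(NA_real_)
      .rs_greater(arr_resp[occ[l, ]], arr_resp[!occ[l, ]])
    }, numeric(1))
    sig <- which(!is.na(p_loc) & p_loc * 20 < a)
    if (length(sig)) { rf_locations <- sig; "peripheral_localized" }
    else "peripheral_unlocalized"
  } else "nonresponsive"
  list(rf_class = cls, p_cue = p_cue, p_array = p_array,
       rf_locations = rf_locations)
}

#' Selectivity index with sign-clamp rules
#'
#' `SI = (R_face - R_house) / (R_face + R_house)`, set to 1 when
#' `R_face > 0 > R_house`, to -1 when `R_face < 0 < R_house`, and clamped
#' to `[-1, 1]`. Undefined (NA) when the denominator is zero without a
#' clamp rule applying.
#'
#' @param r_face,r_house Baseline-subtracted mean responses (vectorized).
#' @return SI in `[-1, 1]` or NA.
#' @export
compute_selectivity_index <- function(r_face, r_house) {
  si <- ifelse(r_face > 0 & r_house < 0, 1,
        ifelse(r_face < 0 & r_house > 0, -1,
               (r_face - r_house) / (r_face + r_house)))
  si[!is.finite(si)] <- NA_real_
  pmin(pmax(si, -1), 1)
}

# responses and per-observation groups used for category scoring:
# foveal units score the cue; peripheral units score single-item-in-RF
# array responses (the search array stands in for the saccade-mapping task)
.category_responses <- function(s, unit, rf, config) {
  tr <- trials_of(s)
  if (rf$rf_class %in% c("focal_foveal", "broad_foveal")) {
    resp <- unit_event_responses(unit, tr, "cue_on", config$response_window)
    base <- unit_event_responses(unit, tr, "cue_on", config$baseline_window)
    cat <- vapply(tr, `[[`, "", "cue_category")
    list(resp = resp, base = base, category = cat)
  } else if (rf$rf_class == "peripheral_localized") {
    keep <- vapply(tr, function(x)
      sum(x$array_items$location_index %in% rf$rf_locations) == 1L,
      logical(1))
    tr1 <- tr[keep]
    if (!length(tr1)) return(NULL)
    cat <- vapply(tr1, function(x) {
      x$array_items$category[x$array_items$location_index %in% rf$rf_locations]
    }, "")
    resp <- unit_event_responses(unit, tr1, "array_on", config$response_window)
    base <- unit_event_responses(unit, tr1, "array_on", config$baseline_window)
    list(resp = resp, base = base, category = cat)
  } else NULL
}

#' Category-selective classification of one unit
#'
#' Face versus house responses (cue responses for foveal units; single-item-
#' in-RF array responses for localized peripheral units; never search-epoch
#' activity) are compared by rank-sum test; significant units must also
#' pass `|SI| > 0.13` to be labelled, otherwise they are `undefined`.
#'
#' @param s A [session()].
#' @param unit A [unit_record()].
#' @param rf Result of [classify_rf()] for this unit.
#' @param config A [selection_config()].
#' @return List: `category_class`, `si`, `p`.
#' @export
select_category_selective <- function(s, unit, rf,
                                      config = selection_config()) {
  cr <- .category_responses(s, unit, rf, config)
  if (is.null(cr))
    return(list(category_class = "unset", si = NA_real_, p = NA_real_))
  f <- cr$category == "face"; h <- cr$category == "house"
  if (sum(f) < config$min_trials || sum(h) < config$min_trials)
    return(list(category_class = "unset", si = NA_real_, p = NA_real_))
  p <- suppressWarnings(stats::wilcox.test(cr$resp[f], cr$resp[h])$p.value)
  r_face <- mean(cr$resp[f]) - mean(cr$base)
  r_house <- mean(cr$resp[h]) - mean(cr$base)
  si <- compute_selectivity_index(r_face, r_house)
  cls <- if (is.na(p) || is.na(si)) "undefined"
  else if (p >= config$alpha) "nonselective"
  else if (si > config$si_threshold) "face_selective"
  else if (si < -config$si_threshold) "house_selective"
  else "undefined"
  list(category_class = cls, si = si, p = p)
}

#' Attention-selective classification of one unit
#'
#' Fixation responses 150-225 ms after fixation onset are compared between
#' fixations on targets and on distractors. Observations are paired per
#' stimulus exemplar (the same stimuli as targets versus distractors) and
#' tested with a two-tailed Wilcoxon signed-rank test; when fewer than five
#' exemplar pairs exist the test falls back to a rank-sum over fixations.
#' The attentional effect is the mean paired rate difference.
#'
#' For localized peripheral units the comparison is between trials whose
#' single RF-resident item is a target versus a distractor, in the same
#' window aligned to each fixation.
#'
#' @param s A [session()].
#' @param unit A [unit_record()].
#' @param rf Result of [classify_rf()].
#' @param config A [selection_config()].
#' @return List: `attention_selective` (logical or NA), `attentional_effect`,
#'   `p`, `test` (pairing scheme used).
#' @export
select_attention_selective <- function(s, unit, rf,
                                       config = selection_config()) {
  unset <- list(attention_selective = NA, attentional_effect = NA_real_,
                p = NA_real_, test = "none")
  fixtab <- fixation_table(s)
  if (is.null(fixtab)) return(unset)
  if (rf$rf_class %in% c("focal_foveal", "broad_foveal")) {
    resp <- unit_fixation_responses(unit, fixtab, config$attention_window)
    key <- paste(fixtab$item_category, fixtab$item_exemplar)
    is_t <- fixtab$is_target
  } else if (rf$rf_class == "peripheral_localized") {
    tr <- trials_of(s)
    single <- vapply(tr, function(x)
      sum(x$array_items$location_index %in% rf$rf_locations) == 1L, logical(1))
    ids <- as.integer(names(tr)[single])
    fixtab <- fixtab[fixtab$trial_id %in% ids, , drop = FALSE]
    if (!nrow(fixtab)) return(unset)
    rf_item <- function(x) x$array_items[
      x$array_items$location_index %in% rf$rf_locations, , drop = FALSE]
    info <- do.call(rbind, lapply(tr[single], function(x) {
      it <- rf_item(x)
      data.frame(trial_id = x$trial_id, key = paste(it$category, it$exemplar),
                 is_t = it$is_target)
    }))
    m <- match(fixtab$trial_id, info$trial_id)
    resp <- unit_fixation_responses(unit, fixtab, config$attention_window)
    key <- info$key[m]
    is_t <- info$is_t[m]
  } else return(unset)

  if (sum(is_t) < config$min_fixations ||
      sum(!is_t) < config$min_fixations) return(unset)
  mt <- tapply(resp[is_t], key[is_t], mean)
  md <- tapply(resp[!is_t], key[!is_t], mean)
  shared <- intersect(names(mt), names(md))
  if (length(shared) >= 5) {
    p <- suppressWarnings(stats::wilcox.test(mt[shared], md[shared],
                                             paired = TRUE)$p.value)
    eff <- mean(mt[shared] - md[shared])
    test <- "signed_rank_exemplar_paired"
  } else {
    p <- suppressWarnings(stats::wilcox.test(resp[is_t], resp[!is_t])$p.value)
    eff <- mean(resp[is_t]) - mean(resp[!is_t])
    test <- "rank_sum_fallback"
  }
  list(attention_selective = !is.na(p) && p < config$alpha,
       attentional_effect = eff, p = p, test = test)
}

#' Run all unit classifications on a session
#'
#' @param s A [session()].
#' @param config A [selection_config()].
#' @return The session with unit labels filled in; the label table is
#'   available via [unit_label_table()], and per-unit RF location sets are
#'   stored as `rf_locations` on each unit.
#' @export
classify_units <- function(s, config = selection_config()) {
  s$units <- lapply(s$units, function(u) {
    rf <- classify_rf(s, u, config)
    u$rf_class <- rf$rf_class
    u$rf_locations <- rf$rf_locations
    cat_res <- select_category_selective(s, u, rf, config)
    u$category_class <- cat_res$category_class
    u$si <- cat_res$si
    att <- select_attention_selective(s, u, rf, config)
    u$attention_selective <- att$attention_selective
    u$attentional_effect <- att$attentional_effect
    u
  })
  s
}

#' Overlap of two unit populations
#'
#' Tests whether the proportion of B-units within group A (`n_both / n_A`)
#' exceeds the base rate of B in the whole population (`n_B / n_all`).
#' Because group A is part of the whole population, the comparison is
#' carried out as the standard 2x2 chi-square test of independence of the
#' two memberships (which has correct size; the two proportions are equal
#' exactly when the memberships are independent), and both proportions are
#' reported alongside.
#'
#' @param group_a_mask,group_b_mask Logical masks over the same units.
#' @param bonferroni Multiply the p-value by this factor (e.g. number of
#'   brain areas tested), capped at 1.
#' @return List: `chi2`, `p`, `prop_in_a`, `prop_overall`, counts.
#' @export
overlap_test <- function(group_a_mask, group_b_mask, bonferroni = 1) {
  stopifnot(length(group_a_mask) == length(group_b_mask))
  n_a <- sum(group_a_mask)
  if (n_a == 0) stop("overlap_test: empty group A", call. = FALSE)
  n_all <- length(group_a_mask)
  n_both <- sum(group_a_mask & group_b_mask)
  n_b <- sum(group_b_mask)
  tab <- table(factor(group_a_mask, c(FALSE, TRUE)),
               factor(group_b_mask, c(FALSE, TRUE)))
  tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chi2 <- unname(tst$statistic)
  if (!is.finite(chi2)) chi2 <- 0
  p <- unname(tst$p.value)
  if (!is.finite(p)) p <- 1
  list(chi2 = chi2, p = min(1, p * bonferroni),
       prop_in_a = n_both / n_a, prop_overall = n_b / n_all,
       n_both = n_both, n_a = n_a, n_b = n_b, n_all = n_all)
}
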