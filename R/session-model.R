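#' @keywords internal
"_PACKAGE"

## Shared label sets -------------------------------------------------------

AREAS <- c("V4", "IT", "OFC", "LPFC")
RF_CLASSES <- c("focal_foveal", "broad_foveal", "peripheral_localized",
                "peripheral_unlocalized", "nonresponsive", "unset")
CATEGORY_CLASSES <- c("face_selective", "house_selective", "nonselective",
                      "undefined", "unset")
ITEM_CATEGORIES <- c("face", "house", "flower", "hand")
CUE_CATEGORIES <- c("face", "house")

SESSION_FORMAT <- "popdyn-session"
SESSION_FORMAT_VERSION <- 1L

#' Construct a unit record
#'
#' A unit holds one electrode unit's spike times, split per trial, together
#' with the derived labels filled in by the selection stage. Spike times are
#' milliseconds relative to the trial's fixation-spot onset (time 0).
#'
#' @param unit_id Character scalar identifier.
#' @param area Brain area, one of `"V4"`, `"IT"`, `"OFC"`, `"LPFC"`.
#' @param spikes Named list of numeric vectors (sorted, non-negative spike
#'   times in ms), one element per trial, names = trial ids.
#' @param rf_class,category_class Derived labels; `"unset"` until the
#'   selection stage has run.
#' @param attention_selective Logical flag or `NA` (unset).
#' @param si Selectivity index in `[-1, 1]`, or `NA` (unset).
#' @param attentional_effect Firing-rate difference (target minus distractor
#'   for the same stimuli) or `NA`.
#' @return An object of class `"unit_record"`.
#' @export
unit_record <- function(unit_id, area, spikes,
                        rf_class = "unset", category_class = "unset",
                        attention_selective = NA, si = NA_real_,
                        attentional_effect = NA_real_) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L,
            area %in% AREAS, is.list(spikes))
  structure(list(unit_id = unit_id, area = area, spikes = spikes,
                 rf_class = rf_class, category_class = category_class,
                 attention_selective = attention_selective,
                 si = si, attentional_effect = attentional_effect),
            class = "unit_record")
}

#' Construct a trial record
#'
#' Event times are ms relative to fixation-spot onset and must follow the
#' task timeline: 400-ms central fixation, cue (500-1300 ms), 500-ms delay,
#' then the search array with up to 4000 ms of free-gaze search and an
#' 800-ms hold on the chosen target.
#'
#' @param trial_id Integer trial identifier.
#' @param cue_category `"face"` or `"house"`.
#' @param cue_exemplar Integer exemplar index in 1..40.
#' @param events Named list with `fixation_spot_on`, `cue_on`, `cue_off`,
#'   `array_on`, `trial_end` (ms).
#' @param array_items Data frame with columns `location_index` (1..20),
#'   `category`, `exemplar`, `is_target`; exactly 11 rows.
#' @param fixations Data frame of fixation events (see
#'   [fixation_frame()]).
#' @param correct Logical: did the trial end with the required target hold.
#' @return An object of class `"trial_record"`.
#' @export
trial_record <- function(trial_id, cue_category, cue_exemplar, events,
                         array_items, fixations, correct) {
  structure(list(trial_id = as.integer(trial_id),
                 cue_category = cue_category,
                 cue_exemplar = as.integer(cue_exemplar),
                 events = events, array_items = array_items,
                 fixations = fixations, correct = isTRUE(correct),
                 n_fixations = nrow(fixations)),
            class = "trial_record")
}

#' Build a fixation-event data frame
#'
#' Refixation and after-target flags are derived from the sequence itself so
#' they can never disagree with it.
#'
#' @param onset,offset Numeric ms, `offset > onset`.
#' @param location_index Integer 1..20 fixated array location.
#' @param item_category Category of the fixated item.
#' @param is_target Logical: fixated item is a search target.
#' @param item_exemplar Integer exemplar index (1..40) of the fixated item.
#' @return Data frame with the derived columns `ordinal`, `is_refixation`,
#'   and `after_first_target_fix` appended.
#' @export
fixation_frame <- function(onset, offset, location_index, item_category,
                           is_target, item_exemplar = NA_integer_) {
  n <- length(onset)
  is_refix <- logical(n)
  if (n > 1L) {
    for (i in 2:n) is_refix[i] <- location_index[i] %in% location_index[1:(i - 1L)]
  }
  first_tgt <- if (any(is_target)) which(is_target)[1L] else Inf
  data.frame(onset = onset, offset = offset,
             location_index = as.integer(location_index),
             item_category = item_category, is_target = is_target,
             item_exemplar = as.integer(item_exemplar),
             ordinal = seq_len(n), is_refixation = is_refix,
             after_first_target_fix = seq_len(n) > first_tgt)
}

#' Construct an array geometry
#'
#' @param coordinates 20 x 2 numeric matrix of (x, y) coordinates in degrees
#'   of visual angle; fixation point at the origin, x rightward, y upward.
#' @return Object of class `"array_geometry"`.
#' @export
array_geometry <- function(coordinates) {
  stopifnot(is.matrix(coordinates), nrow(coordinates) == 20L,
            ncol(coordinates) == 2L)
  colnames(coordinates) <- c("x", "y")
  structure(list(coordinates = coordinates), class = "array_geometry")
}

#' Construct an LFP trace
#'
#' @param channel_id Character channel identifier.
#' @param area Brain area.
#' @param trial_id Trial the trace belongs to.
#' @param samples Numeric vector sampled at `rate_hz`, spanning the trial
#'   from time 0 to `trial_end`.
#' @param rate_hz Sampling rate; the recording convention is 1000 Hz.
#' @return Object of class `"lfp_trace"`.
#' @export
lfp_trace <- function(channel_id, area, trial_id, samples, rate_hz = 1000) {
  structure(list(channel_id = channel_id, area = area,
                 trial_id = as.integer(trial_id),
                 samples = as.numeric(samples), rate_hz = rate_hz),
            class = "lfp_trace")
}

#' Construct a session
#'
#' The session is the single unit of input for every analysis stage: units,
#' trials, optional LFP traces, the array geometry, and (for synthetic
#' sessions) the planted ground truth.
#'
#' @param session_id Character identifier.
#' @param units List of [unit_record()] objects.
#' @param trials List of [trial_record()] objects.
#' @param geometry An [array_geometry()].
#' @param lfp Optional list of [lfp_trace()] objects.
#' @param ground_truth Optional ground-truth list (synthetic sessions only).
#' @param validate Run [validate_session()] on construction (default TRUE).
#' @return Object of class `"session"`.
#' @export
session <- function(session_id, units, trials, geometry, lfp = NULL,
                    ground_truth = NULL, validate = TRUE) {
  s <- structure(list(session_id = session_id, units = units,
                      trials = trials, lfp = lfp,
                      array_geometry = geometry,
                      ground_truth = ground_truth),
                 class = "session")
  if (validate) validate_session(s)
  s
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session '%s': %d units, %d trials, %s LFP, %s ground truth>\n",
              x$session_id, length(x$units), length(x$trials),
              if (is.null(x$lfp)) "no" else length(x$lfp),
              if (is.null(x$ground_truth)) "no" else "with"))
  invisible(x)
}

#' Validate a session against the data-model invariants
#'
#' Checks the task timeline, array composition (11 distinct locations, two
#' distinct same-category targets matching the cue), fixation sequence flags,
#' spike-time ordering/range, geometry eccentricities and symmetry, and LFP
#' sample counts. Errors name the offending field and trial/unit.
#'
#' @param s A [session()].
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_session <- function(s) {
  fail <- function(fmt, ...) stop(sprintf(paste0("session validation: ", fmt),
                                          ...), call. = FALSE)
  if (!inherits(s, "session")) fail("not a session object")
  trial_ids <- vapply(s$trials, function(tr) tr$trial_id, integer(1))
  if (anyDuplicated(trial_ids)) fail("duplicate trial ids")

  for (tr in s$trials) {
    ev <- tr$events
    need <- c("fixation_spot_on", "cue_on", "cue_off", "array_on", "trial_end")
    if (!all(need %in% names(ev)))
      fail("trial %d: missing event(s) %s", tr$trial_id,
           paste(setdiff(need, names(ev)), collapse = ", "))
    tv <- unlist(ev[need])
    if (any(diff(tv) <= 0))
      fail("trial %d: event times not strictly increasing", tr$trial_id)
    ai <- tr$array_items
    if (nrow(ai) != 11L) fail("trial %d: array has %d items, expected 11",
                              tr$trial_id, nrow(ai))
    if (anyDuplicated(ai$location_index))
      fail("trial %d: duplicate array locations", tr$trial_id)
    tgt <- ai[ai$is_target, , drop = FALSE]
    if (nrow(tgt) != 2L) fail("trial %d: %d targets, expected 2",
                              tr$trial_id, nrow(tgt))
    if (!all(tgt$category == tr$cue_category))
      fail("trial %d: target category does not match cue", tr$trial_id)
    if (tgt$exemplar[1] == tgt$exemplar[2])
      fail("trial %d: targets are not distinct exemplars", tr$trial_id)
    fx <- tr$fixations
    if (nrow(fx) > 0) {
      if (any(fx$offset <= fx$onset))
        fail("trial %d: fixation offset <= onset", tr$trial_id)
      if (any(diff(fx$ordinal) <= 0))
        fail("trial %d: fixation ordinals not increasing", tr$trial_id)
      ref <- fixation_frame(fx$onset, fx$offset, fx$location_index,
                            fx$item_category, fx$is_target)
      if (!identical(ref$is_refixation, fx$is_refixation))
        fail("trial %d: is_refixation inconsistent with sequence", tr$trial_id)
      if (!all(fx$location_index %in% ai$location_index))
        fail("trial %d: fixation on unoccupied location", tr$trial_id)
    }
    if (tr$n_fixations != nrow(fx))
      fail("trial %d: n_fixations (%d) != fixation rows (%d)",
           tr$trial_id, tr$n_fixations, nrow(fx))
  }

  dur <- vapply(s$trials, function(tr) tr$events$trial_end, numeric(1))
  names(dur) <- as.character(trial_ids)
  for (u in s$units) {
    if (!u$area %in% AREAS) fail("unit %s: unknown area '%s'", u$unit_id, u$area)
    if (!u$rf_class %in% RF_CLASSES)
      fail("unit %s: unknown rf_class '%s'", u$unit_id, u$rf_class)
    if (!u$category_class %in% CATEGORY_CLASSES)
      fail("unit %s: unknown category_class '%s'", u$unit_id, u$category_class)
    if (!all(names(u$spikes) %in% names(dur)))
      fail("unit %s: spikes reference unknown trial(s)", u$unit_id)
    for (tn in names(u$spikes)) {
      sp <- u$spikes[[tn]]
      if (length(sp) == 0) next
      if (is.unsorted(sp)) fail("unit %s trial %s: spikes unsorted",
                                u$unit_id, tn)
      if (sp[1] < 0 || sp[length(sp)] > dur[[tn]])
        fail("unit %s trial %s: spike outside trial", u$unit_id, tn)
    }
    ran_cat <- !identical(u$category_class, "unset")
    if (ran_cat != !is.na(u$si) && !identical(u$category_class, "undefined"))
      fail("unit %s: si presence inconsistent with category classification",
           u$unit_id)
  }

  xy <- s$array_geometry$coordinates
  ecc <- sqrt(rowSums(xy^2))
  if (any(ecc < 5 - 1e-9 | ecc > 11 + 1e-9))
    fail("geometry: eccentricity outside [5, 11] degrees")
  n_mid <- sum(abs(xy[, 1]) < 1e-9)
  if (n_mid != 2L) fail("geometry: %d midline locations, expected 2", n_mid)
  side <- xy[abs(xy[, 1]) >= 1e-9, , drop = FALSE]
  mirrored <- cbind(-side[, 1], side[, 2])
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6))
  if (!setequal(key(side), key(mirrored)))
    fail("geometry: lateral locations are not mirror-symmetric")

  if (!is.null(s$lfp)) {
    for (tr_lfp in s$lfp) {
      exp_n <- floor(dur[[as.character(tr_lfp$trial_id)]] / 1000 *
                       tr_lfp$rate_hz) + 1L
      if (abs(length(tr_lfp$samples) - exp_n) > 1L)
        fail("lfp %s trial %d: %d samples, expected ~%d", tr_lfp$channel_id,
             tr_lfp$trial_id, length(tr_lfp$samples), exp_n)
    }
  }
  invisible(TRUE)
}

## Container I/O -----------------------------------------------------------

#' Write a session container file
#'
#' The container is a single hierarchical file: a versioned header wrapping
#' the groups `units`, `trials`, `lfp`, `geometry` and `ground_truth`,
#' serialized with R's native serialization. The session is fully validated
#' before writing; [read_session()] is its exact inverse.
#'
#' @param s A [session()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  payload <- list(format = SESSION_FORMAT, version = SESSION_FORMAT_VERSION,
                  groups = list(session_id = s$session_id,
                                units = s$units, trials = s$trials,
                                lfp = s$lfp, geometry = s$array_geometry,
                                ground_truth = s$ground_truth))
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' Read a session container file
#'
#' Unknown optional groups are ignored with a warning (forward
#' compatibility); a malformed or truncated file raises a parse error and
#' never returns a partial session.
#'
#' @param path File written by [write_session()].
#' @return A validated [session()].
#' @export
read_session <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("session container parse error in '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, SESSION_FORMAT))
    stop("not a ", SESSION_FORMAT, " container: '", path, "'", call. = FALSE)
  if (!identical(payload$version, SESSION_FORMAT_VERSION))
    stop("session container version ", payload$version,
         " unsupported (reader version ", SESSION_FORMAT_VERSION, ")",
         call. = FALSE)
  g <- payload$groups
  known <- c("session_id", "units", "trials", "lfp", "geometry", "ground_truth")
  extra <- setdiff(names(g), known)
  if (length(extra))
    warning("ignoring unknown container group(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  session(g$session_id, g$units, g$trials, g$geometry, lfp = g$lfp,
          ground_truth = g$ground_truth, validate = TRUE)
}

#' Tabulate unit labels
#'
#' @param s A [session()].
#' @return Data frame with one row per unit: id, area, RF class, category
#'   class, SI, attention flag and attentional effect.
#' @export
unit_label_table <- function(s) {
  data.frame(
    unit_id = vapply(s$units, `[[`, "", "unit_id"),
    area = vapply(s$units, `[[`, "", "area"),
    rf_class = vapply(s$units, `[[`, "", "rf_class"),
    category_class = vapply(s$units, `[[`, "", "category_class"),
    si = vapply(s$units, function(u) as.numeric(u$si), numeric(1)),
    attention_selective = vapply(s$units, function(u)
      as.logical(u$attention_selective), logical(1)),
    attentional_effect = vapply(s$units, function(u)
      as.numeric(u$attentional_effect), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Export unit labels as JSON
#'
#' @param s A [session()].
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
export_unit_labels <- function(s, path) {
  jsonlite::write_json(unit_label_table(s), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
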