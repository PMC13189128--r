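## Shared accessors: flat fixation tables and per-unit windowed responses.

#' Flatten a session's fixations into one table
#'
#' @param s A [session()].
#' @param correct_only Keep correct trials only (default TRUE; all
#'   selection and geometry analyses use correct trials).
#' @return Data frame: one row per fixation with its trial's id, cue
#'   category and fixation count attached. `onset`/`offset` are on the
#'   trial clock.
#' @export
fixation_table <- function(s, correct_only = TRUE) {
  rows <- lapply(s$trials, function(tr) {
    if (correct_only && !tr$correct) return(NULL)
    if (nrow(tr$fixations) == 0) return(NULL)
    cbind(trial_id = tr$trial_id, cue_category = tr$cue_category,
          n_fixations = tr$n_fixations, tr$fixations,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-trial event-aligned mean rates for one unit
#'
#' @param unit A [unit_record()].
#' @param trials List of [trial_record()]s.
#' @param event Event name (`"cue_on"`, `"array_on"`, ...).
#' @param window `c(a, b)` ms relative to the event.
#' @param params [kernel_params()].
#' @return Numeric vector, one value per trial.
#' @export
unit_event_responses <- function(unit, trials, event, window,
                                 params = kernel_params()) {
  vapply(trials, function(tr) {
    sp <- unit$spikes[[as.character(tr$trial_id)]]
    window_mean_rate(sp, tr$events[[event]] + window, params)
  }, numeric(1))
}

#' Per-fixation aligned mean rates for one unit
#'
#' @param unit A [unit_record()].
#' @param fixtab A [fixation_table()].
#' @param window `c(a, b)` ms relative to fixation onset.
#' @param params [kernel_params()].
#' @return Numeric vector, one value per fixation row.
#' @export
unit_fixation_responses <- function(unit, fixtab, window,
                                    params = kernel_params()) {
  out <- numeric(nrow(fixtab))
  for (tid in unique(fixtab$trial_id)) {
    i <- which(fixtab$trial_id == tid)
    sp <- unit$spikes[[as.character(tid)]]
    out[i] <- aligned_window_means(sp, fixtab$onset[i], window, params)
  }
  out
}

#' Named list of trials keyed by trial id
#' @param s A [session()].
#' @param correct_only Keep correct trials only.
#' @return Named list of [trial_record()]s.
#' @export
trials_of <- function(s, correct_only = TRUE) {
  tr <- s$trials
  if (correct_only) tr <- Filter(function(x) x$correct, tr)
  names(tr) <- vapply(tr, function(x) as.character(x$trial_id), "")
  tr
}

#' Session-wide baseline rates
#' @param s A [session()].
#' @param params [kernel_params()].
#' @return Named numeric vector of baseline rates (spikes/s) per unit.
#' @export
session_baselines <- function(s, params = kernel_params()) {
  tr <- trials_of(s)
  vapply(s$units, function(u) unit_baseline(u, tr, params = params),
         numeric(1))
}
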