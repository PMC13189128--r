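## Search-efficiency correlates: per-unit presearch firing rate versus the
## number of fixations needed to complete the trial, end-of-search
## representational divergence, and theta-band LFP power.

#' Per-unit firing-rate vs search-efficiency correlation
#'
#' Pearson correlation of the windowed mean rate with the trial's fixation
#' count over correct trials, for the cue window (0-500 ms after cue
#' onset) and the delay window (0-200 ms after delay onset). The unit's
#' efficiency class (`positive` / `negative` / `none`) follows the
#' delay-window result. Separate face-cue and house-cue correlations and
#' group-mean correlations over the `n_groups` lowest fixation counts are
#' also reported.
#'
#' @param s A [session()].
#' @param unit A [unit_record()].
#' @param alpha Significance level, default 0.05.
#' @param min_trials Minimum correct trials, default 20.
#' @param n_groups Fixation-count groups for the group-mean curve,
#'   default 7.
#' @param params [kernel_params()].
#' @return List of class `"efficiency_result"`: per-epoch `r`, `p`,
#'   `class`, `by_cue`, `group_r` (over group means), `n_trials`.
#' @export
unit_efficiency_correlation <- function(s, unit, alpha = 0.05,
                                        min_trials = 20, n_groups = 7,
                                        params = kernel_params()) {
  tr <- trials_of(s)
  nfix <- vapply(tr, `[[`, 0L, "n_fixations")
  none <- list(cue = list(r = NA_real_, p = NA_real_),
               delay = list(r = NA_real_, p = NA_real_),
               class = "none", n_trials = length(tr))
  if (length(tr) < min_trials || length(unique(nfix)) < 3)
    return(structure(none, class = "efficiency_result"))
  cue_r <- unit_event_responses(unit, tr, "cue_on", c(0, 500), params)
  del_r <- unit_event_responses(unit, tr, "cue_off", c(0, 200), params)
  cue_cat <- vapply(tr, `[[`, "", "cue_category")
  cor_safe <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  res <- list(cue = cor_safe(cue_r, nfix), delay = cor_safe(del_r, nfix))
  res$by_cue <- list(
    face = list(cue = cor_safe(cue_r[cue_cat == "face"], nfix[cue_cat == "face"]),
                delay = cor_safe(del_r[cue_cat == "face"], nfix[cue_cat == "face"])),
    house = list(cue = cor_safe(cue_r[cue_cat == "house"], nfix[cue_cat == "house"]),
                 delay = cor_safe(del_r[cue_cat == "house"], nfix[cue_cat == "house"])))
  # group-mean curve over the lowest fixation counts
  lv <- sort(unique(nfix))[seq_len(min(n_groups, length(unique(nfix))))]
  gm_cue <- tapply(cue_r[nfix %in% lv], nfix[nfix %in% lv], mean)
  gm_del <- tapply(del_r[nfix %in% lv], nfix[nfix %in% lv], mean)
  gx <- as.numeric(names(gm_cue))
  res$group_r <- list(cue = cor_safe(gm_cue, gx),
                      delay = cor_safe(gm_del, as.numeric(names(gm_del))))
  d <- res$delay
  res$class <- if (is.na(d$p) || d$p >= alpha) "none"
               else if (d$r > 0) "positive" else "negative"
  res$n_trials <- length(tr)
  structure(res, class = "efficiency_result")
}

#' Efficiency classification table for all units
#'
#' @param s A [session()].
#' @param ... Passed to [unit_efficiency_correlation()].
#' @return Data frame: unit_id, cue/delay r and p, class.
#' @export
efficiency_table <- function(s, ...) {
  rows <- lapply(s$units, function(u) {
    e <- unit_efficiency_correlation(s, u, ...)
    data.frame(unit_id = u$unit_id, r_cue = e$cue$r, p_cue = e$cue$p,
               r_delay = e$delay$r, p_delay = e$delay$p, class = e$class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Representational divergence between search onset and search end
#'
#' Cue-condition (face vs house) population vectors are computed at search
#' onset (0-200 ms after array onset) and at search completion (0-200 ms
#' after the final fixation's onset); the face-house representational
#' distance and vector angle at the two time points are compared by paired
#' t-tests across resampled unit subsets, with a cue-label shuffle null at
#' both time points.
#'
#' @param s A [session()].
#' @param unit_mask Logical unit mask.
#' @param n_subsets Resampled unit subsets, default 15.
#' @param subset_frac Fraction of units per subset, default 0.8.
#' @param n_shuffles Cue-label shuffles for the null, default 200.
#' @param seed RNG seed.
#' @param params [kernel_params()].
#' @return List: `distance` / `angle` (named onset/end), paired tests,
#'   `null` (per time point distance distributions), `n_units`.
#' @export
divergence_at_search_end <- function(s, unit_mask = rep(TRUE, length(s$units)),
                                     n_subsets = 15, subset_frac = 0.8,
                                     n_shuffles = 200, seed = 1L,
                                     params = kernel_params()) {
  tr <- trials_of(s)
  if (length(tr) < 20) stop("insufficient completed trials", call. = FALSE)
  units <- s$units[unit_mask]
  base <- vapply(units, function(u) unit_baseline(u, tr, params = params),
                 numeric(1))
  ok <- is.finite(base) & base > 0
  units <- units[ok]; base <- base[ok]
  N <- length(units)
  cue_cat <- vapply(tr, `[[`, "", "cue_category")
  onset_t <- vapply(tr, function(x) x$events$array_on, 0)
  end_t <- vapply(tr, function(x) x$fixations$onset[nrow(x$fixations)], 0)
  # units x trials response matrices at both time points
  R_on <- t(vapply(units, function(u) vapply(seq_along(tr), function(i)
    window_mean_rate(u$spikes[[names(tr)[i]]], onset_t[i] + c(0, 200), params),
    numeric(1)), numeric(length(tr)))) / base
  R_end <- t(vapply(units, function(u) vapply(seq_along(tr), function(i)
    window_mean_rate(u$spikes[[names(tr)[i]]], end_t[i] + c(0, 200), params),
    numeric(1)), numeric(length(tr)))) / base
  vecs <- function(R, lab) cbind(face = rowMeans(R[, lab == "face", drop = FALSE]),
                                 house = rowMeans(R[, lab == "house", drop = FALSE]))
  stat <- function(R, lab, idx = seq_len(N)) {
    v <- vecs(R[idx, , drop = FALSE], lab)
    c(dist = representational_distance(v[, 1], v[, 2]),
      angle = vector_angle(v[, 1], v[, 2]))
  }
  obs_on <- stat(R_on, cue_cat); obs_end <- stat(R_end, cue_cat)
  m <- max(3, round(subset_frac * N))
  with_seed(seed, {
    sub <- lapply(seq_len(n_subsets), function(k) sample.int(N, m))
    d_on <- vapply(sub, function(i) stat(R_on, cue_cat, i), numeric(2))
    d_end <- vapply(sub, function(i) stat(R_end, cue_cat, i), numeric(2))
    null_on <- vapply(seq_len(n_shuffles), function(k)
      stat(R_on, sample(cue_cat)), numeric(2))
    null_end <- vapply(seq_len(n_shuffles), function(k)
      stat(R_end, sample(cue_cat)), numeric(2))
    list(distance = c(onset = unname(obs_on["dist"]),
                      end = unname(obs_end["dist"])),
         angle = c(onset = unname(obs_on["angle"]),
                   end = unname(obs_end["angle"])),
         distance_test = stats::t.test(d_end["dist", ], d_on["dist", ],
                                       paired = TRUE),
         angle_test = stats::t.test(d_end["angle", ], d_on["angle", ],
                                    paired = TRUE),
         null = list(onset = t(null_on), end = t(null_end)),
         n_units = N)
  })
}

#' Welch power spectral density
#'
#' Hann-windowed overlapping segments, default 200-ms segments with 50%
#' overlap at 1000 Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples, default 200.
#' @param overlap Fractional overlap, default 0.5.
#' @return List: `freq` (Hz), `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = 1000, seg_len = 200, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  U <- sum(w^2)
  acc <- numeric(seg_len)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * U * fs)
  half <- seq_len(floor(seg_len / 2) + 1)
  psd <- psd[half]
  psd[-c(1, length(half))] <- 2 * psd[-c(1, length(half))] # one-sided
  list(freq = (half - 1) * fs / seg_len, psd = psd)
}

#' Band-integrated power of a signal
#'
#' @param x Signal; `fs` sampling rate; `band` `c(lo, hi)` Hz.
#' @param fs,band See above.
#' @param ... Passed to [welch_psd()].
#' @return Scalar band power.
#' @export
band_power <- function(x, fs = 1000, band = c(4, 12), ...) {
  p <- welch_psd(x, fs, ...)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[sel]) * df
}

#' Theta-band LFP power vs search efficiency
#'
#' Per-trial band power (Welch estimate over the epoch, averaged across
#' channels), grouped by the trial's fixation count; Pearson correlation
#' of power with fixation count at the trial level and over the group
#' means of the `n_groups` lowest counts.
#'
#' @param s A [session()] with LFP.
#' @param epoch `"cue"` or `"delay"`.
#' @param band Frequency band (Hz), default `c(4, 12)`.
#' @param n_groups Fixation-count groups, default 7.
#' @return List of class `"theta_result"`: `power_by_group`, `r`, `p`
#'   (trial level), `group_r`, `group_p`, `epoch`.
#' @export
theta_power_correlation <- function(s, epoch = c("cue", "delay"),
                                    band = c(4, 12), n_groups = 7) {
  epoch <- match.arg(epoch)
  if (is.null(s$lfp)) stop("session has no LFP", call. = FALSE)
  tr <- trials_of(s)
  ids <- names(tr)
  win <- function(x) {
    ev <- x$events
    if (epoch == "cue") c(ev$cue_on, ev$cue_off) else c(ev$cue_off, ev$array_on)
  }
  if (min(vapply(tr, function(x) diff(win(x)), 0)) < 2000 / band[1])
    warning("epoch shorter than 2 cycles of the band's low edge",
            call. = FALSE)
  pow <- setNames(numeric(length(tr)), ids)
  cnt <- setNames(numeric(length(tr)), ids)
  for (lf in s$lfp) {
    id <- as.character(lf$trial_id)
    if (!id %in% ids) next
    w <- round(win(tr[[id]])) + 1L
    pow[id] <- pow[id] + band_power(lf$samples[w[1]:min(w[2], length(lf$samples))],
                                    fs = lf$rate_hz, band = band)
    cnt[id] <- cnt[id] + 1
  }
  keep <- cnt > 0
  pow <- pow[keep] / cnt[keep]
  nfix <- vapply(tr[keep], `[[`, 0L, "n_fixations")
  ct <- stats::cor.test(pow, nfix)
  lv <- sort(unique(nfix))[seq_len(min(n_groups, length(unique(nfix))))]
  gm <- tapply(pow[nfix %in% lv], nfix[nfix %in% lv], mean)
  gct <- if (length(gm) >= 3)
    stats::cor.test(as.numeric(gm), as.numeric(names(gm)))
  else list(estimate = NA_real_, p.value = NA_real_)
  structure(list(power_by_group = gm, r = unname(ct$estimate),
                 p = ct$p.value, group_r = unname(gct$estimate),
                 group_p = gct$p.value, epoch = epoch, band = band),
            class = "theta_result")
}
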