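## Synthetic free-gaze search sessions with planted, recorded ground truth.
## Every downstream analysis stage has a recoverable target here: tuned
## inhomogeneous-Poisson units, realistic task/fixation statistics, and LFP
## with an efficiency-dependent theta component.

# Stimulus-type order of the 12-indicator encoding scheme: six stimulus
# types crossed with the current (foveal) fixation type, on-target block
# first. "face target" means a face in a face-search trial, etc.; flowers
# and hands are always distractors.
ENCODING_TYPES <- c("face_target", "face_distractor", "house_target",
                    "house_distractor", "flower_distractor", "hand_distractor")

#' Simulation configuration
#'
#' Defaults encode the task statistics the analyses assume: 400-ms central
#' fixation, 500-1300-ms cue, 500-ms delay, free-gaze search with log-normal
#' fixation durations of mean 208 ms, and a refixation probability of 0.09
#' per post-first fixation, which (with `1 + Poisson(1.6)` fixations per
#' trial) puts a return fixation in about 13.5% of correct trials.
#'
#' @param n_units Named integer vector of unit counts per area.
#' @param n_trials Number of trials.
#' @param seed Session seed; the seed fully determines the session.
#' @param fixation_mean_ms,fixation_sd_ms Log-normal fixation-duration law.
#' @param refixation_prob Probability that a post-first fixation returns to
#'   an already-fixated location.
#' @param nfix_lambda Poisson rate of extra fixations (n_fix = 1 + Pois).
#' @param correct_rate Fraction of trials ending with the required 800-ms
#'   target hold.
#' @param p_category_tuned,g_cat Fraction of units with category tuning and
#'   their multiplicative face-vs-house gain (face gets `g_cat`, house
#'   `1/g_cat`).
#' @param p_attention_tuned,g_att Fraction of units with attention tuning
#'   and their target-vs-distractor gain.
#' @param p_maintenance Fraction of category-tuned units that keep a
#'   (weakened) cue-category-dependent rate through the delay.
#' @param p_eff_pos,p_eff_neg Fractions of units whose cue/delay rate grows
#'   (resp. shrinks) with the trial's eventual fixation count.
#' @param eff_step Per-extra-fixation fractional rate change for efficiency-
#'   tuned units.
#' @param vis_gain Foveal visual response gain (evoked / baseline).
#' @param arr_gain Sustained array-onset gain for broad-foveal and
#'   unlocalized-peripheral units.
#' @param att_state_gain Multiplier on the on-target encoding block for
#'   peripheral units (foveal attentional state spreading the peripheral
#'   code).
#' @param refix_gain Response gain applied to refixated items in foveal
#'   units (< 1 = attenuation).
#' @param rf_sigma Peripheral Gaussian RF width (degrees).
#' @param p_spatial_tuned Fraction of foveal units carrying a gaze-position
#'   gain field (a Gaussian modulation of the fixation response by the
#'   fixated location), the structure spatial RSA recovers.
#' @param spatial_gain,spatial_sigma Gain-field strength (peak fractional
#'   gain) and width (degrees).
#' @param rf_mix Named probabilities over planted RF classes.
#' @param baseline_mean_hz Mean of the per-unit baseline-rate distribution.
#' @param response_latency_ms Visual response latency.
#' @param lfp Generate LFP traces?
#' @param n_lfp_channels LFP channels per session.
#' @param theta_freq_hz,theta_base_amp,theta_cue_slope,theta_delay_slope
#'   Theta-component frequency and epoch-specific amplitude map: amplitude =
#'   `max(0, base + slope * (n_fix - 3))`, with opposite default signs for
#'   cue vs delay.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_units = c(V4 = 40L, IT = 25L, OFC = 20L, LPFC = 15L),
                       n_trials = 200L, seed = 1L,
                       fixation_mean_ms = 208, fixation_sd_ms = 150,
                       refixation_prob = 0.19, nfix_lambda = 1.6,
                       correct_rate = 0.9,
                       p_category_tuned = 0.4, g_cat = 2,
                       p_attention_tuned = 0.35, g_att = 2,
                       p_maintenance = 0.7,
                       p_eff_pos = 0.25, p_eff_neg = 0.11, eff_step = 0.12,
                       vis_gain = 2.5, arr_gain = 1.6,
                       att_state_gain = 1.5, refix_gain = 0.85,
                       rf_sigma = 2.5,
                       p_spatial_tuned = 0.5, spatial_gain = 0.8,
                       spatial_sigma = 3,
                       rf_mix = c(focal_foveal = 0.35, broad_foveal = 0.15,
                                  peripheral_localized = 0.30,
                                  peripheral_unlocalized = 0.10,
                                  nonresponsive = 0.10),
                       baseline_mean_hz = 10,
                       response_latency_ms = 50,
                       lfp = TRUE, n_lfp_channels = 2L,
                       theta_freq_hz = 8, theta_base_amp = 1,
                       theta_cue_slope = 0.12, theta_delay_slope = -0.12) {
  stopifnot(all(names(n_units) %in% AREAS), n_trials >= 1,
            g_cat >= 0, g_att >= 0, refixation_prob >= 0,
            abs(sum(rf_mix) - 1) < 1e-8)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate the 20-location search-array geometry
#'
#' Three concentric arcs at 5.5, 8 and 10.5 degrees eccentricity with three
#' locations per arc per hemifield (9 per side, mirror-symmetric), plus two
#' midline locations at 6 degrees above and below fixation. All
#' eccentricities lie in the task's 5-11 degree range.
#'
#' @param seed Integer seed (used only when `jitter_deg > 0`).
#' @param jitter_deg Optional angular jitter applied symmetrically.
#' @return An [array_geometry()].
#' @export
make_array_geometry <- function(seed = 1L, jitter_deg = 0) {
  radii <- c(5.5, 8, 10.5)
  ang <- c(-50, 0, 50) # polar angle (deg) from the horizontal, right side
  if (jitter_deg > 0)
    ang <- ang + with_seed(mix_seed(seed, "geom"),
                           stats::runif(3, -jitter_deg, jitter_deg))
  right <- do.call(rbind, lapply(radii, function(r)
    cbind(r * cospi(ang / 180), r * sinpi(ang / 180))))
  left <- cbind(-right[, 1], right[, 2])
  xy <- rbind(right, left, c(0, 6), c(0, -6))
  array_geometry(xy)
}

#' Plant per-unit and per-session ground truth
#'
#' @param config A [sim_config()].
#' @param geometry An [array_geometry()].
#' @return Ground-truth list: `units` (per-unit data frame of planted
#'   parameters), `encoding_coefficients` (units x 12 matrix, peripheral
#'   localized units only), `theta_amp_map`, and the config used.
#' @export
make_ground_truth <- function(config, geometry) {
  areas <- rep(names(config$n_units), times = config$n_units)
  n <- length(areas)
  xy <- geometry$coordinates
  # each unit's parameters come from its own substream, so changing the
  # unit count never perturbs the ground truth of existing units
  rows <- lapply(seq_len(n), function(i) with_seed(
    mix_seed(config$seed, "unit_truth", i), {
      rf_class <- sample(names(config$rf_mix), 1, prob = config$rf_mix)
      cat_tuned <- stats::runif(1) < config$p_category_tuned
      att_tuned <- stats::runif(1) < config$p_attention_tuned
      eff_u <- stats::runif(1)
      rf_loc <- sample(nrow(xy), 1)
      sp_loc <- sample(nrow(xy), 1)
      data.frame(
        unit_id = sprintf("u%03d_%s", i, areas[i]),
        area = areas[i], rf_class = rf_class,
        baseline_rate = stats::rgamma(1, shape = 8,
                                      rate = 8 / config$baseline_mean_hz),
        g_cat = if (!cat_tuned) 1 else if (stats::runif(1) < 0.5)
          config$g_cat else 1 / config$g_cat,
        g_att = if (att_tuned) config$g_att else 1,
        maintenance = cat_tuned &&
          (stats::runif(1) < config$p_maintenance),
        # efficiency modulation belongs to visually responsive units;
        # planting it on silent units would leak through the visual-
        # response screen via the heavier-tailed cue-rate distribution
        efficiency_slope = if (rf_class == "nonresponsive") 0
          else if (eff_u < config$p_eff_pos) config$eff_step
          else if (eff_u < config$p_eff_pos + config$p_eff_neg)
            -config$eff_step else 0,
        vis_gain = config$vis_gain, arr_gain = config$arr_gain,
        refix_gain = if (rf_class %in% c("focal_foveal", "broad_foveal"))
          config$refix_gain else 1,
        response_latency = config$response_latency_ms,
        rf_x = xy[rf_loc, 1] + stats::runif(1, -0.5, 0.5),
        rf_y = xy[rf_loc, 2] + stats::runif(1, -0.5, 0.5),
        rf_sigma = config$rf_sigma,
        sp_gain = if (rf_class %in% c("focal_foveal", "broad_foveal") &&
                        stats::runif(1) < config$p_spatial_tuned)
          config$spatial_gain else 0,
        sp_x = xy[sp_loc, 1], sp_y = xy[sp_loc, 2],
        sp_sigma = config$spatial_sigma,
        stringsAsFactors = FALSE)
    }))
  units <- do.call(rbind, rows)
  rownames(units) <- NULL
  # peripheral 12-coefficient response strengths (Hz), jittered per unit
  coefs <- matrix(NA_real_, n, 12,
                  dimnames = list(units$unit_id,
                                  c(paste0(ENCODING_TYPES, "_onT"),
                                    paste0(ENCODING_TYPES, "_onD"))))
  for (i in seq_len(n)) {
    if (units$rf_class[i] != "peripheral_localized") next
    coefs[i, ] <- with_seed(mix_seed(config$seed, "unit_coef", i), {
      r0 <- units$baseline_rate[i] * (config$vis_gain - 1)
      catfac <- c(face_target = units$g_cat[i] * units$g_att[i],
                  face_distractor = units$g_cat[i],
                  house_target = units$g_att[i] / units$g_cat[i],
                  house_distractor = 1 / units$g_cat[i],
                  flower_distractor = 1, hand_distractor = 1)
      base6 <- r0 * catfac * exp(stats::rnorm(6, 0, 0.2))
      c(base6 * config$att_state_gain, base6)
    })
  }
  list(units = units,
       encoding_coefficients = coefs,
       theta_amp_map = list(freq_hz = config$theta_freq_hz,
                            base_amp = config$theta_base_amp,
                            cue_slope = config$theta_cue_slope,
                            delay_slope = config$theta_delay_slope,
                            ref_nfix = 3),
       config = config)
}

#' Simulate one trial's task structure and fixation sequence
#'
#' Timeline: 400-ms central fixation, cue drawn uniform on 500-1300 ms,
#' 500-ms delay, then a search array of 11 items (two distinct same-category
#' targets matching the cue plus nine distractors from the other three
#' categories) on 11 of the 20 locations. The fixation sequence ends on a
#' target held 800 ms for correct trials; refixations return to an
#' already-fixated location with the configured probability.
#'
#' @param config A [sim_config()].
#' @param geometry An [array_geometry()].
#' @param trial_id Integer id.
#' @param seed Substream seed for this trial.
#' @return A [trial_record()].
#' @export
simulate_trial <- function(config, geometry, trial_id,
                           seed = mix_seed(config$seed, "trial", trial_id)) {
  with_seed(seed, {
    cue_cat <- sample(CUE_CATEGORIES, 1)
    cue_ex <- sample.int(40, 1)
    tgt_ex <- sample.int(40, 2)
    other <- setdiff(ITEM_CATEGORIES, cue_cat)
    d_cat <- sample(other, 9, replace = TRUE)
    locs <- sample.int(20, 11)
    array_items <- data.frame(
      location_index = locs,
      category = c(cue_cat, cue_cat, d_cat),
      exemplar = c(tgt_ex, sample.int(40, 9, replace = TRUE)),
      is_target = c(TRUE, TRUE, rep(FALSE, 9)),
      stringsAsFactors = FALSE)

    cue_on <- 400
    cue_off <- cue_on + stats::runif(1, 500, 1300)
    array_on <- cue_off + 500
    correct <- stats::runif(1) < config$correct_rate

    n_fix <- 1L + stats::rpois(1, config$nfix_lambda)
    n_fix <- min(n_fix, 11L)
    # log-normal fixation durations with the configured mean/SD
    cv2 <- (config$fixation_sd_ms / config$fixation_mean_ms)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(config$fixation_mean_ms) - sdlog^2 / 2
    tgt_rows <- which(array_items$is_target)
    dis_rows <- which(!array_items$is_target)

    seq_rows <- integer(n_fix)
    for (i in seq_len(n_fix)) {
      final <- i == n_fix
      if (final && correct) {
        # the completing fixation lands on a not-yet-visited target when
        # one exists (brief early target visits leave the other available)
        fresh <- setdiff(tgt_rows, seq_rows[seq_len(i - 1L)])
        seq_rows[i] <- if (length(fresh)) fresh[sample.int(length(fresh), 1)]
                       else sample(tgt_rows, 1)
      } else if (final) {
        fresh_d <- setdiff(dis_rows, seq_rows[seq_len(i - 1L)])
        seq_rows[i] <- if (length(fresh_d))
          fresh_d[sample.int(length(fresh_d), 1)] else sample(dis_rows, 1)
      } else if (i > 1L && stats::runif(1) < config$refixation_prob) {
        seq_rows[i] <- seq_rows[sample.int(i - 1L, 1)]
      } else {
        pool <- setdiff(seq_len(11L), seq_rows[seq_len(i - 1L)])
        if (!length(pool)) pool <- seq_len(11L)
        # at most one brief target visit before completion, so a fresh
        # target always remains for the final fixation
        w <- ifelse(array_items$is_target[pool],
                    if (any(array_items$is_target[seq_rows[seq_len(i - 1L)]]))
                      0 else 0.35, 1)
        if (all(w == 0)) w <- rep(1, length(pool))
        seq_rows[i] <- pool[sample.int(length(pool), 1, prob = w)]
      }
    }
    dur <- pmin(stats::rlnorm(n_fix, meanlog, sdlog), 750)
    dur <- pmax(dur, 60)
    dur[n_fix] <- 800
    sacc_lat <- stats::rlnorm(1, log(200) - 0.011, 0.15)
    gaps <- stats::runif(n_fix, 25, 40)
    onset <- array_on + sacc_lat + c(0, cumsum(dur[-n_fix] + gaps[-n_fix]))
    # respect the 4000-ms search limit by trimming late fixations
    keep <- onset <= array_on + 4000 - 100
    keep[1] <- TRUE
    if (!all(keep)) {
      n_fix <- max(which(keep))
      onset <- onset[seq_len(n_fix)]
      dur <- dur[seq_len(n_fix)]
      seq_rows <- seq_rows[seq_len(n_fix)]
      if (correct) { # re-point the (new) final fixation at a target
        fresh <- setdiff(tgt_rows, seq_rows[seq_len(n_fix - 1L)])
        seq_rows[n_fix] <- if (length(fresh))
          fresh[sample.int(length(fresh), 1)] else sample(tgt_rows, 1)
        dur[n_fix] <- 800
      }
    }
    offset <- onset + dur
    fx <- fixation_frame(onset, offset,
                         array_items$location_index[seq_rows],
                         array_items$category[seq_rows],
                         array_items$is_target[seq_rows],
                         array_items$exemplar[seq_rows])
    trial_record(trial_id, cue_cat, cue_ex,
                 events = list(fixation_spot_on = 0, cue_on = cue_on,
                               cue_off = cue_off, array_on = array_on,
                               trial_end = max(offset) + 50),
                 array_items = array_items, fixations = fx,
                 correct = correct)
  })
}

## Piecewise-constant rate profile for one unit in one trial -------------
## Collect every epoch/fixation boundary, then evaluate the planted rate at
## elementary-interval midpoints. Returns list(breaks, rates): rates[i]
## holds on [breaks[i], breaks[i+1]).
unit_trial_rate <- function(u, coef12, trial, nfix_ref = 3) {
  ev <- trial$events
  fx <- trial$fixations
  lat <- u$response_latency
  b <- u$baseline_rate
  catmod <- function(cat) ifelse(cat == "face", u$g_cat,
                                 ifelse(cat == "house", 1 / u$g_cat, 1))
  eff <- max(0.2, 1 + u$efficiency_slope * (trial$n_fixations - nfix_ref))
  foveal <- u$rf_class %in% c("focal_foveal", "broad_foveal")
  search_base <- switch(u$rf_class,
                        broad_foveal = b * u$arr_gain,
                        peripheral_unlocalized = b * u$arr_gain,
                        b)

  rf_item_sum <- NULL
  if (u$rf_class == "peripheral_localized") {
    xy <- attr(trial, "geometry_xy")
    d <- sqrt((xy[trial$array_items$location_index, 1] - u$rf_x)^2 +
                (xy[trial$array_items$location_index, 2] - u$rf_y)^2)
    items <- trial$array_items[d <= u$rf_sigma, , drop = FALSE]
    rf_item_sum <- function(on_target_fix) {
      if (!nrow(items)) return(0)
      sum(coef12[encoding_type_index(items$category, items$is_target,
                                     on_target_fix)])
    }
  }

  rate_at <- function(t) {
    if (t < ev$cue_on + lat) return(b)
    if (t < ev$cue_off + lat)
      return(if (foveal) b * u$vis_gain * catmod(trial$cue_category) * eff
             else b * eff)
    if (t < ev$array_on + lat)
      return(b * (if (u$maintenance) catmod(trial$cue_category)^0.5 else 1) * eff)
    # search period
    if (!is.null(rf_item_sum)) {
      cur <- which(fx$onset + lat <= t)
      on_tgt <- if (length(cur)) fx$is_target[max(cur)] else FALSE
      return(b + rf_item_sum(on_tgt))
    }
    if (foveal && nrow(fx) > 0) {
      # response follows the most recently fixated item (after latency),
      # persisting until the next fixation's response takes over
      i <- which(fx$onset + lat <= t)
      if (length(i)) {
        i <- max(i)
        spg <- 1
        if (u$sp_gain > 0) { # gaze-position gain field
          xy <- attr(trial, "geometry_xy")
          loc <- fx$location_index[i]
          d2 <- (xy[loc, 1] - u$sp_x)^2 + (xy[loc, 2] - u$sp_y)^2
          spg <- 1 + u$sp_gain * exp(-d2 / (2 * u$sp_sigma^2))
        }
        return(search_base * u$vis_gain * spg * catmod(fx$item_category[i]) *
                 (if (fx$is_target[i]) u$g_att else 1) *
                 (if (fx$is_refixation[i]) u$refix_gain else 1))
      }
    }
    search_base
  }

  breaks <- c(0, ev$cue_on + lat, ev$cue_off + lat, ev$array_on + lat,
              if (nrow(fx)) c(fx$onset + lat, fx$offset + lat),
              ev$trial_end)
  breaks <- sort(unique(pmin(pmax(breaks, 0), ev$trial_end)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rates <- pmax(vapply(mids, rate_at, numeric(1)), 0)
  list(breaks = breaks, rates = rates)
}

# map (item category, item target status, current fixation type) to the
# 1..12 index of the encoding scheme (on-target block first)
encoding_type_index <- function(category, is_target, on_target_fix) {
  type <- ifelse(category == "face" & is_target, 1L,
          ifelse(category == "face", 2L,
          ifelse(category == "house" & is_target, 3L,
          ifelse(category == "house", 4L,
          ifelse(category == "flower", 5L, 6L)))))
  type + ifelse(on_target_fix, 0L, 6L)
}

#' Simulate one unit's spikes for one trial
#'
#' Inhomogeneous Poisson draw from the unit's piecewise-constant planted
#' rate: baseline before the cue; visual/category/efficiency-modulated rate
#' during cue and delay; during search, foveal units are gated by the
#' fixated item (after the response latency) and peripheral units respond
#' additively to RF-resident array items.
#'
#' @param u One row of the ground-truth unit table (as a list).
#' @param coef12 The unit's 12 planted encoding coefficients (peripheral
#'   localized units; otherwise ignored).
#' @param trial A [trial_record()] carrying the geometry in its
#'   `"geometry_xy"` attribute.
#' @param seed Substream seed.
#' @return Sorted numeric vector of spike times (ms).
#' @export
simulate_spikes <- function(u, coef12, trial, seed) {
  prof <- unit_trial_rate(u, coef12, trial)
  with_seed(seed, {
    br <- prof$breaks
    sp <- lapply(seq_along(prof$rates), function(i) {
      t0 <- br[i]; t1 <- br[i + 1]
      n <- stats::rpois(1, prof$rates[i] * (t1 - t0) / 1000)
      if (n == 0) return(numeric(0))
      stats::runif(n, t0, t1)
    })
    sort(unlist(sp))
  })
}

#' Simulate one LFP trace for one trial
#'
#' 1/f background noise plus a theta-band sinusoid whose amplitude during
#' the cue and delay epochs follows the planted amplitude map as a function
#' of the trial's eventual fixation count (opposite default signs for the
#' two epochs).
#'
#' @param config A [sim_config()].
#' @param trial A [trial_record()].
#' @param ground_truth Ground truth from [make_ground_truth()].
#' @param channel_id Channel label.
#' @param seed Substream seed.
#' @return An [lfp_trace()].
#' @export
simulate_lfp <- function(config, trial, ground_truth, channel_id, seed) {
  tam <- ground_truth$theta_amp_map
  n <- floor(trial$events$trial_end) + 1L
  with_seed(seed, {
    # 1/f background: shape white noise in the frequency domain
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1)) # avoid the DC singularity
    f <- pmin(f, n - f + 1)
    W <- W / sqrt(f)
    noise <- Re(stats::fft(W, inverse = TRUE)) / n
    noise <- noise / stats::sd(noise)

    t_s <- (seq_len(n) - 1) / 1000
    amp <- rep(tam$base_amp, n)
    dn <- trial$n_fixations - tam$ref_nfix
    ev <- trial$events
    in_cue <- t_s * 1000 >= ev$cue_on & t_s * 1000 < ev$cue_off
    in_delay <- t_s * 1000 >= ev$cue_off & t_s * 1000 < ev$array_on
    amp[in_cue] <- max(0, tam$base_amp + tam$cue_slope * dn)
    amp[in_delay] <- max(0, tam$base_amp + tam$delay_slope * dn)
    phase <- stats::runif(1, 0, 2 * pi)
    samples <- noise + amp * sin(2 * pi * tam$freq_hz * t_s + phase)
    lfp_trace(channel_id, "V4", trial$trial_id, samples)
  })
}

#' Simulate a full session
#'
#' Deterministic given `config$seed`: trials, units and LFP channels each
#' draw from their own derived substream, so changing unit counts never
#' perturbs already-generated trials.
#'
#' @param config A [sim_config()].
#' @return A validated [session()] with `ground_truth` attached.
#' @export
simulate_session <- function(config = sim_config()) {
  geometry <- make_array_geometry(config$seed)
  gt <- make_ground_truth(config, geometry)
  trials <- lapply(seq_len(config$n_trials), function(id) {
    tr <- simulate_trial(config, geometry, id)
    attr(tr, "geometry_xy") <- geometry$coordinates
    tr
  })
  tids <- as.character(vapply(trials, `[[`, 0L, "trial_id"))
  ud <- gt$units
  units <- lapply(seq_len(nrow(ud)), function(i) {
    u <- as.list(ud[i, ])
    sp <- lapply(trials, function(tr)
      simulate_spikes(u, gt$encoding_coefficients[i, ], tr,
                      seed = mix_seed(config$seed, "spk", i, tr$trial_id)))
    names(sp) <- tids
    unit_record(u$unit_id, u$area, sp)
  })
  lfp <- NULL
  if (isTRUE(config$lfp)) {
    lfp <- list()
    for (ch in seq_len(config$n_lfp_channels)) {
      for (tr in trials) {
        lfp[[length(lfp) + 1L]] <-
          simulate_lfp(config, tr, gt, sprintf("ch%02d", ch),
                       seed = mix_seed(config$seed, "lfp", ch, tr$trial_id))
      }
    }
  }
  # strip the geometry attribute before storage (it lives in the session)
  trials <- lapply(trials, function(tr) { attr(tr, "geometry_xy") <- NULL; tr })
  session(sprintf("synthetic-%d", config$seed), units, trials, geometry,
          lfp = lfp, ground_truth = gt)
}
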