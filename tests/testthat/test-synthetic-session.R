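test_that("array geometry satisfies the task's spatial constraints", {
  g <- make_array_geometry(1)
  xy <- g$coordinates
  ecc <- sqrt(rowSums(xy^2))
  expect_true(all(ecc >= 5 & ecc <= 11))
  expect_equal(sum(abs(xy[, 1]) < 1e-9), 2)
  right <- xy[xy[, 1] > 1e-9, , drop = FALSE]
  expect_equal(nrow(right), 9)
  for (i in seq_len(nrow(right)))
    expect_true(any(abs(xy[, 1] + right[i, 1]) < 1e-9 &
                      abs(xy[, 2] - right[i, 2]) < 1e-9))
})

test_that("trial timeline and fixation sequence honor the task rules", {
  cfg <- sim_config(seed = 9L)
  geom <- make_array_geometry(9L)
  for (id in 1:50) {
    tr <- simulate_trial(cfg, geom, id)
    ev <- tr$events
    expect_equal(ev$cue_on, 400)
    expect_gte(ev$cue_off - ev$cue_on, 500)
    expect_lte(ev$cue_off - ev$cue_on, 1300)
    expect_equal(ev$array_on - ev$cue_off, 500)
    fx <- tr$fixations
    expect_true(all(fx$onset > ev$array_on))
    expect_lte(fx$onset[nrow(fx)], ev$array_on + 4000)
    if (tr$correct) {
      last <- fx[nrow(fx), ]
      expect_true(last$is_target)
      expect_gte(last$offset - last$onset, 800)
    }
    expect_equal(sum(tr$array_items$is_target), 2)
    expect_true(all(tr$array_items$category[tr$array_items$is_target] ==
                      tr$cue_category))
  }
})

test_that("refixation probability zero yields no return fixations", {
  cfg <- sim_config(seed = 10L, refixation_prob = 0)
  geom <- make_array_geometry(10L)
  for (id in 1:40) {
    tr <- simulate_trial(cfg, geom, id)
    expect_false(any(tr$fixations$is_refixation))
  }
})

test_that("default refixation probability reproduces the return-fixation rate", {
  # target figure: a return fixation in 13.46% of correct trials
  cfg <- sim_config(seed = 11L)
  geom <- make_array_geometry(11L)
  has_refix <- logical(0)
  for (id in 1:4000) {
    tr <- simulate_trial(cfg, geom, id)
    if (tr$correct) has_refix <- c(has_refix, any(tr$fixations$is_refixation))
  }
  expect_lt(abs(mean(has_refix) - 0.1346), 0.03)
})

test_that("untuned units fire at baseline; attention gain scales rates", {
  geom <- make_array_geometry(1)
  cfg <- sim_config(seed = 1L)
  u0 <- list(unit_id = "flat", area = "V4", rf_class = "nonresponsive",
             baseline_rate = 20, g_cat = 1, g_att = 1, maintenance = FALSE,
             efficiency_slope = 0, vis_gain = 1, arr_gain = 1,
             refix_gain = 1, response_latency = 50, rf_x = 0, rf_y = 0,
             rf_sigma = 2.5, sp_gain = 0, sp_x = 0, sp_y = 0, sp_sigma = 3)
  counts <- durs <- numeric(300)
  for (i in 1:300) {
    tr <- simulate_trial(cfg, geom, i)
    sp <- simulate_spikes(u0, rep(NA, 12), tr, seed = mix_seed(1, i))
    counts[i] <- length(sp)
    durs[i] <- tr$events$trial_end
  }
  rate <- sum(counts) / sum(durs) * 1000
  se <- sqrt(sum(counts)) / sum(durs) * 1000
  expect_lt(abs(rate - 20), 3 * se)

  # g_att = 2: empirical target/distractor rate ratio ~ 2
  u1 <- u0
  u1$rf_class <- "focal_foveal"; u1$g_att <- 2; u1$vis_gain <- 2
  r_t <- r_d <- integer(0)
  for (i in 1:300) {
    tr <- simulate_trial(cfg, geom, i)
    attr(tr, "geometry_xy") <- geom$coordinates
    sp <- simulate_spikes(u1, rep(NA, 12), tr, seed = mix_seed(2, i))
    fx <- tr$fixations
    for (k in seq_len(nrow(fx))) {
      w <- c(fx$onset[k] + 60, fx$onset[k] + 160)
      n <- sum(sp >= w[1] & sp < w[2])
      if (fx$is_target[k]) r_t <- c(r_t, n) else r_d <- c(r_d, n)
    }
  }
  ratio <- mean(r_t) / mean(r_d)
  expect_lt(abs(ratio - 2), 0.25)
})

test_that("constant-rate spiking is Poisson (exponential ISIs)", {
  geom <- make_array_geometry(1)
  cfg <- sim_config(seed = 1L)
  u0 <- list(unit_id = "flat", area = "V4", rf_class = "nonresponsive",
             baseline_rate = 30, g_cat = 1, g_att = 1, maintenance = FALSE,
             efficiency_slope = 0, vis_gain = 1, arr_gain = 1,
             refix_gain = 1, response_latency = 50, rf_x = 0, rf_y = 0,
             rf_sigma = 2.5, sp_gain = 0, sp_x = 0, sp_y = 0, sp_sigma = 3)
  isis <- numeric(0)
  for (i in 1:60) {
    tr <- simulate_trial(cfg, geom, i)
    sp <- simulate_spikes(u0, rep(NA, 12), tr, seed = mix_seed(3, i))
    isis <- c(isis, diff(sp))
  }
  ks <- stats::ks.test(isis, "pexp", rate = 30 / 1000)
  expect_gt(ks$p.value, 0.01)
})

test_that("sessions are bit-reproducible and substreams are stable", {
  cfg <- sim_config(n_units = c(V4 = 3L), n_trials = 10L, seed = 21L,
                    lfp = FALSE)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$units, s2$units)
  expect_identical(s1$trials, s2$trials)
  # adding units never perturbs existing trials or earlier units' spikes
  cfg5 <- sim_config(n_units = c(V4 = 5L), n_trials = 10L, seed = 21L,
                     lfp = FALSE)
  s5 <- simulate_session(cfg5)
  expect_identical(s5$trials, s1$trials)
  expect_identical(s5$units[[1]]$spikes, s1$units[[1]]$spikes)
})

test_that("LFP theta amplitude scales band power as planted", {
  cfg <- sim_config(seed = 31L)
  geom <- make_array_geometry(31L)
  tr <- simulate_trial(cfg, geom, 1)
  gt0 <- list(theta_amp_map = list(freq_hz = 8, base_amp = 0, cue_slope = 0,
                                   delay_slope = 0, ref_nfix = 3))
  gt1 <- list(theta_amp_map = list(freq_hz = 8, base_amp = 1, cue_slope = 0,
                                   delay_slope = 0, ref_nfix = 3))
  gt2 <- list(theta_amp_map = list(freq_hz = 8, base_amp = 2, cue_slope = 0,
                                   delay_slope = 0, ref_nfix = 3))
  bp <- vapply(list(gt0, gt1, gt2), function(gt) {
    p <- vapply(1:30, function(k)
      band_power(simulate_lfp(cfg, tr, gt, "ch", seed = k)$samples),
      numeric(1))
    mean(p)
  }, numeric(1))
  # amplitude 0 -> background only; doubling amplitude -> ~4x theta power
  expect_lt(abs((bp[3] - bp[1]) / (bp[2] - bp[1]) - 4), 0.6)
  expect_gt(bp[2], bp[1])
})
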