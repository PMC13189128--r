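# Shared fixtures: sessions are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# mixed-population session used by most module tests
demo_session <- function() cached("demo", {
  simulate_session(sim_config(n_units = c(V4 = 40L, IT = 20L),
                              n_trials = 250L, seed = 42L,
                              n_lfp_channels = 1L))
})

demo_classified <- function() cached("demo_cls", classify_units(demo_session()))

demo_foveal_mask <- function() {
  tab <- unit_label_table(demo_classified())
  tab$rf_class %in% c("focal_foveal", "broad_foveal")
}

# small foveal-only population with planted tuning, for recovery tests
tuned_foveal_session <- function() cached("tuned_fov", {
  simulate_session(sim_config(
    n_units = c(V4 = 40L), n_trials = 200L, seed = 7L, lfp = FALSE,
    p_category_tuned = 1, p_attention_tuned = 1, g_cat = 2, g_att = 2,
    p_eff_pos = 0, p_eff_neg = 0,
    rf_mix = c(focal_foveal = 1, broad_foveal = 0,
               peripheral_localized = 0, peripheral_unlocalized = 0,
               nonresponsive = 0)))
})

# a single-unit "session" wrapper for hand-built spike trains
manual_session <- function(spikes_per_trial, n_trials = length(spikes_per_trial),
                           seed = 1L) {
  geom <- make_array_geometry()
  cfg <- sim_config(n_units = c(V4 = 1L), n_trials = n_trials, seed = seed,
                    lfp = FALSE)
  trials <- lapply(seq_len(n_trials), function(i)
    simulate_trial(cfg, geom, i))
  names(spikes_per_trial) <- vapply(trials, function(t)
    as.character(t$trial_id), "")
  u <- unit_record("u1", "V4", spikes_per_trial)
  session("manual", list(u), trials, geom)
}

# craft a one-trial session with a fully controlled array so the design
# rows can be checked against the documented encoding
make_controlled_session <- function() {
  geom <- make_array_geometry()
  array_items <- data.frame(
    location_index = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 19L),
    category = c("face", "face", "flower", "hand", "house", "flower",
                 "hand", "flower", "hand", "flower", "hand"),
    exemplar = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
    is_target = c(TRUE, TRUE, rep(FALSE, 9)),
    stringsAsFactors = FALSE)
  fx <- fixation_frame(onset = c(2000, 2300, 2600),
                       offset = c(2250, 2550, 3400),
                       location_index = c(5L, 3L, 1L),
                       item_category = c("house", "flower", "face"),
                       is_target = c(FALSE, FALSE, TRUE),
                       item_exemplar = c(5L, 3L, 1L))
  tr <- trial_record(1L, "face", 12L,
                     events = list(fixation_spot_on = 0, cue_on = 400,
                                   cue_off = 1200, array_on = 1700,
                                   trial_end = 3500),
                     array_items = array_items, fixations = fx,
                     correct = TRUE)
  u <- unit_record("u1", "V4", list(`1` = c(100, 500, 2100)))
  session("controlled", list(u), list(tr), geom)
}

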