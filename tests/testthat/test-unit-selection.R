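test_that("selectivity index follows the formula and clamp rules", {
  expect_equal(compute_selectivity_index(3, -1), 1)
  expect_equal(compute_selectivity_index(-2, 5), -1)
  expect_equal(compute_selectivity_index(7, 7), 0)
  expect_equal(compute_selectivity_index(10, 5), 1 / 3)
  expect_true(is.na(compute_selectivity_index(0, 0)))
  # antisymmetry and range over random response pairs (clamps included)
  set.seed(3)
  a <- runif(20000, -10, 10); b <- runif(20000, -10, 10)
  si_ab <- compute_selectivity_index(a, b)
  si_ba <- compute_selectivity_index(b, a)
  ok <- !is.na(si_ab)
  expect_true(all(abs(si_ab[ok] + si_ba[ok]) < 1e-12))
  expect_true(all(si_ab[ok] >= -1 & si_ab[ok] <= 1))
})

test_that("planted RF classes are recovered", {
  s <- demo_classified()
  gt <- s$ground_truth$units
  tab <- unit_label_table(s)
  # focal foveal: majority recovered, never called peripheral
  foc <- gt$rf_class == "focal_foveal"
  expect_gt(mean(tab$rf_class[foc] %in% c("focal_foveal", "broad_foveal")),
            0.9)
  # planted spatial-RF units recovered as localized peripheral
  per <- gt$rf_class == "peripheral_localized"
  expect_gt(mean(tab$rf_class[per] == "peripheral_localized"), 0.7)
})

test_that("unmodulated and silent units are called nonresponsive", {
  # baseline-only units pass both rank-sum screens at ~(1 - alpha)^2
  cfg <- sim_config(n_units = c(V4 = 30L), n_trials = 120L, seed = 81L,
                    lfp = FALSE, p_eff_pos = 0, p_eff_neg = 0,
                    rf_mix = c(focal_foveal = 0, broad_foveal = 0,
                               peripheral_localized = 0,
                               peripheral_unlocalized = 0,
                               nonresponsive = 1))
  s <- classify_units(simulate_session(cfg))
  tab <- unit_label_table(s)
  expect_gt(mean(tab$rf_class == "nonresponsive"), 0.75)
  # a truly silent unit is nonresponsive deterministically
  s2 <- s
  s2$units[[1]]$spikes <- lapply(s2$units[[1]]$spikes,
                                 function(x) numeric(0))
  rf <- classify_rf(s2, s2$units[[1]])
  expect_equal(rf$rf_class, "nonresponsive")
})

test_that("strong category tuning is detected with the correct preference", {
  s <- classify_units(tuned_foveal_session())
  gt <- s$ground_truth$units
  tab <- unit_label_table(s)
  want <- ifelse(gt$g_cat > 1, "face_selective", "house_selective")
  expect_gt(mean(tab$category_class == want), 0.9)
  expect_true(all(abs(tab$si) <= 1, na.rm = TRUE))
  # SI sign matches preference among classified units
  cls <- tab$category_class %in% c("face_selective", "house_selective")
  expect_true(all(sign(tab$si[cls]) == sign(log(gt$g_cat[cls]))))
})

test_that("significant-but-small SI yields the undefined label", {
  s <- tuned_foveal_session()
  u <- s$units[[1]]
  rf <- classify_rf(s, u)
  cfg_hi <- selection_config(si_threshold = 0.999)
  res <- select_category_selective(s, u, rf, cfg_hi)
  expect_lt(res$p, 0.05)
  expect_equal(res$category_class, "undefined")
})

test_that("attention selectivity is detected and signed correctly", {
  s <- classify_units(tuned_foveal_session())
  tab <- unit_label_table(s)
  expect_gt(mean(tab$attention_selective, na.rm = TRUE), 0.9)
  # g_att = 2 > 1: positive attentional effect (target > distractor)
  expect_gt(mean(tab$attentional_effect > 0, na.rm = TRUE), 0.9)
})

test_that("selection is invariant to unit and trial ordering", {
  s <- demo_session()
  u <- s$units[[5]]
  cfg <- selection_config()
  rf1 <- classify_rf(s, u, cfg)
  s_perm <- s
  s_perm$trials <- rev(s_perm$trials)
  s_perm$units <- rev(s_perm$units)
  rf2 <- classify_rf(s_perm, u, cfg)
  expect_identical(rf1$rf_class, rf2$rf_class)
  expect_equal(rf1$p_cue, rf2$p_cue)
  c1 <- select_category_selective(s, u, rf1, cfg)
  c2 <- select_category_selective(s_perm, u, rf2, cfg)
  expect_equal(c1$si, c2$si)
})

test_that("overlap test behaves at the extremes and under independence", {
  # perfectly nested labels: proportion 1 vs base rate, tiny p
  a <- rep(c(TRUE, FALSE), c(50, 150))
  b <- a
  res <- overlap_test(a, b)
  expect_equal(res$prop_in_a, 1)
  expect_lt(res$p, 1e-6)
  # identical proportions by construction: chi2 ~ 0
  b2 <- rep(c(TRUE, FALSE), 100)
  res2 <- overlap_test(rep(TRUE, 200), b2)
  expect_lt(res2$chi2, 1e-10)
  expect_error(overlap_test(rep(FALSE, 10), b2[1:10]), "empty")
  # independent labels: p roughly uniform
  set.seed(4)
  ps <- replicate(400, {
    overlap_test(sample(c(TRUE, FALSE), 200, replace = TRUE),
                 sample(c(TRUE, FALSE), 200, replace = TRUE))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  # Bonferroni factor scales the p-value
  res3 <- overlap_test(a, b, bonferroni = 4)
  expect_equal(res3$p, min(1, res$p * 4))
})
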