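test_that("representational distance and vector angle are exact", {
  v <- rnorm(40)
  expect_equal(representational_distance(v, v), 0)
  d <- v; d[1] <- d[1] + 3.5
  expect_equal(representational_distance(v, d), 3.5)
  set.seed(31)
  a <- rnorm(100); b <- rnorm(100)
  expect_lt(abs(representational_distance(a, b) - sqrt(sum((a - b)^2))),
            1e-12)
  expect_error(representational_distance(a, b[1:10]), "mismatch")
  # mean-pairwise context equals the brute-force double loop
  M <- matrix(rnorm(6 * 20), 6)
  brute <- mean(utils::combn(6, 2, function(ij)
    sqrt(sum((M[ij[1], ] - M[ij[2], ])^2))))
  expect_lt(abs(representational_distance(M, context = "mean_pairwise") -
                  brute), 1e-12)
  # angles
  expect_equal(vector_angle(a, a), 0)
  expect_equal(vector_angle(c(1, 0), c(0, 2)), 90)
  expect_equal(vector_angle(a, -a), 180)
  expect_error(vector_angle(a, numeric(100)), "zero vector")
  # symmetry and triangle inequality on random triples
  for (k in 1:25) {
    x <- rnorm(15); y <- rnorm(15); z <- rnorm(15)
    expect_equal(representational_distance(x, y),
                 representational_distance(y, x))
    expect_lte(representational_distance(x, z),
               representational_distance(x, y) +
                 representational_distance(y, z) + 1e-12)
  }
})

test_that("Procrustes alignment recovers a known similarity transform", {
  set.seed(32)
  ref <- matrix(rnorm(20 * 2), 20)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A <- (scale(ref, scale = FALSE) %*% t(R)) / 1.8 # rotated + shrunk copy
  res <- rpca_align(A, ref)
  expect_lt(res$residual, 1e-12)
  expect_lt(max(abs(res$scale - 1.8) / 1.8), 1e-6)
  expect_lt(max(abs(res$aligned - scale(ref, scale = FALSE) -
                      rep(colMeans(ref), each = 20))), 1e-6)
  # identity alignment
  self <- rpca_align(ref, ref)
  expect_lt(self$residual, 1e-12)
  expect_lt(max(abs(self$rotation - diag(2))), 1e-9)
  expect_equal(self$scale, 1, tolerance = 1e-9)
  # reflection required but disabled: large residual, flag set
  refl <- scale(ref, scale = FALSE); refl[, 1] <- -refl[, 1]
  res_r <- rpca_align(refl, ref)
  expect_true(res_r$reflection_needed)
  expect_gt(res_r$residual, 0.01)
  expect_lt(rpca_align(refl, ref, allow_reflection = TRUE)$residual, 1e-12)
  expect_error(rpca_align(ref[1:2, ], ref[1:2, ]), "3 shared conditions")
})

test_that("alignment matches vegan's procrustes on a rotation-only case", {
  skip_if_not_installed("vegan")
  set.seed(33)
  ref <- matrix(rnorm(15 * 2), 15)
  th <- -1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A <- scale(ref, scale = FALSE) %*% t(R) * 0.6 +
    matrix(rnorm(30, 0, 0.05), 15)
  ours <- rpca_align(A, ref)
  veg <- vegan::procrustes(ref, A, scale = TRUE, symmetric = FALSE)
  expect_equal(unname(ours$aligned), unname(veg$Yrot +
                 rep(colMeans(ref), each = 15)), tolerance = 1e-6)
})

test_that("hyperplane angle recovers planted coding geometry", {
  set.seed(34)
  N <- 25; n_fix <- 500
  w_cat <- rnorm(N); w_cat <- w_cat / sqrt(sum(w_cat^2))
  w_att <- rnorm(N)
  w_att <- w_att - sum(w_att * w_cat) * w_cat # exactly orthogonal
  w_att <- w_att / sqrt(sum(w_att^2))
  cat_lab <- sample(c("face", "house"), n_fix, TRUE)
  att_lab <- sample(c("target", "distractor"), n_fix, TRUE)
  X <- matrix(rnorm(n_fix * N, 5, 0.6), n_fix, N) +
    outer(ifelse(cat_lab == "face", 1.2, -1.2), w_cat) +
    outer(ifelse(att_lab == "target", 1.2, -1.2), w_att)
  hp <- hyperplane_angle(X, cat_lab, att_lab, n_subsamples = 40,
                         n_shuffles = 120, seed = 5)
  expect_gt(hp$angle, 80); expect_lt(hp$angle, 100)
  expect_lt(abs(mean(hp$null_angles) - 90), 6)
  # identical label schemes give a near-zero angle
  hp_same <- hyperplane_angle(X, cat_lab, cat_lab, n_subsamples = 40,
                              n_shuffles = 10, seed = 6)
  expect_lt(hp_same$angle, 10)
})

test_that("hyperplane angle is invariant to unit order and rate scale", {
  set.seed(35)
  N <- 15; n_fix <- 240
  w <- rnorm(N)
  lab_a <- sample(c("f", "h"), n_fix, TRUE)
  lab_b <- sample(c("t", "d"), n_fix, TRUE)
  X <- matrix(rnorm(n_fix * N, 3, 0.5), n_fix, N) +
    outer(ifelse(lab_a == "f", 1, -1), w)
  base <- hyperplane_angle(X, lab_a, lab_b, n_subsamples = 25,
                           n_shuffles = 10, seed = 7)
  perm <- sample(N)
  h_perm <- hyperplane_angle(X[, perm], lab_a, lab_b, n_subsamples = 25,
                             n_shuffles = 10, seed = 7)
  expect_equal(h_perm$angle, base$angle, tolerance = 1e-6)
  h_scale <- hyperplane_angle(X * 3, lab_a, lab_b, n_subsamples = 25,
                              n_shuffles = 10, seed = 7)
  expect_equal(h_scale$angle, base$angle, tolerance = 2)
  # class imbalance too severe for balanced subsampling errors out
  lab_bad <- c(rep("f", n_fix - 2), "h", "h")
  expect_error(hyperplane_angle(X, lab_bad, lab_b, n_subsamples = 5,
                                n_shuffles = 2, seed = 8), "imbalance")
})

test_that("refixation attenuation is detected; no false effect without it", {
  cfg_on <- sim_config(n_units = c(V4 = 50L), n_trials = 220L, seed = 61L,
                       lfp = FALSE, refix_gain = 0.7, refixation_prob = 0.25,
                       p_category_tuned = 0, p_attention_tuned = 0,
                       p_eff_pos = 0, p_eff_neg = 0,
                       rf_mix = c(focal_foveal = 1, broad_foveal = 0,
                                  peripheral_localized = 0,
                                  peripheral_unlocalized = 0,
                                  nonresponsive = 0))
  s_on <- simulate_session(cfg_on)
  cc_on <- context_comparison(s_on, split = "refixation")
  # groups are sorted: first, refixated; attenuation means first > refix
  expect_lt(cc_on$paired_test$p.value, 0.01)
  first_m <- mean(cc_on$per_unit[, , "first"])
  refix_m <- mean(cc_on$per_unit[, , "refixated"])
  expect_gt(first_m, refix_m)

  cfg_off <- sim_config(n_units = c(V4 = 50L), n_trials = 220L, seed = 62L,
                        lfp = FALSE, refix_gain = 1, refixation_prob = 0.25,
                        p_category_tuned = 0, p_attention_tuned = 0,
                        p_eff_pos = 0, p_eff_neg = 0,
                        rf_mix = c(focal_foveal = 1, broad_foveal = 0,
                                   peripheral_localized = 0,
                                   peripheral_unlocalized = 0,
                                   nonresponsive = 0))
  cc_off <- context_comparison(simulate_session(cfg_off),
                               split = "refixation")
  expect_gt(cc_off$paired_test$p.value, 0.05)
})

test_that("the before/after-target split produces a usable geometry", {
  s <- demo_classified()
  cc <- context_comparison(s, demo_foveal_mask(), split = "target")
  expect_setequal(cc$groups, c("before", "after"))
  expect_true(all(is.finite(cc$distance)))
  expect_true(all(cc$angle >= 0 & cc$angle <= 180))
  expect_gt(cc$n_units, 3)
})
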