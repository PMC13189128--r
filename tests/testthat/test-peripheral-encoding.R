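test_that("design rows follow the 12-indicator scheme", {
  s <- make_controlled_session()
  # RF covers locations 1 (face target), 3 (flower), 4 (hand)
  des <- build_design(s, s$units[[1]], rf_locations = c(1L, 3L, 4L))
  expect_equal(ncol(des$X), 12)
  expect_true(all(des$X %in% 0:1))
  # fixation 3 is on a target; RF holds face target + flower + hand:
  # the documented worked example (1 0 0 0 1 1 0 0 0 0 0 0)
  expect_equal(unname(des$X[3, ]), c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0))
  # fixations 1-2 are on distractors: same items in the on-distractor block
  expect_equal(unname(des$X[1, ]), c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 1))
  # only one block active per fixation
  blocks <- cbind(rowSums(des$X[, 1:6]) > 0, rowSums(des$X[, 7:12]) > 0)
  expect_true(all(rowSums(blocks) <= 1))
  # an RF away from every item: unit skipped with a message
  expect_message(res <- build_design(s, s$units[[1]],
                                     rf_locations = c(15L)),
                 "skipped")
  expect_null(res)
})

test_that("design rows reconstruct the fixation/RF condition losslessly", {
  s <- demo_session()
  gt <- s$ground_truth$units
  idx <- which(gt$rf_class == "peripheral_localized")[1]
  xy <- s$array_geometry$coordinates
  d2 <- (xy[, 1] - gt$rf_x[idx])^2 + (xy[, 2] - gt$rf_y[idx])^2
  rf_locs <- which(sqrt(d2) <= gt$rf_sigma[idx])
  des <- build_design(s, s$units[[idx]], rf_locs)
  trs <- trials_of(s)
  # trials whose array misses the RF leave all-zero rows, retained
  expect_gt(sum(rowSums(des$X) == 0), 0)
  expect_equal(nrow(des$X), nrow(des$fixtab))
  for (i in sample(nrow(des$X), 40)) {
    tr <- trs[[as.character(des$fixtab$trial_id[i])]]
    items <- tr$array_items[tr$array_items$location_index %in% rf_locs, ]
    block <- if (des$fixtab$is_target[i]) 1:6 else 7:12
    expect_equal(sum(des$X[i, block]),
                 length(unique(popdyn:::encoding_type_index(
                   items$category, items$is_target,
                   des$fixtab$is_target[i]))) *
                   (nrow(items) > 0))
    expect_equal(sum(des$X[i, setdiff(1:12, block)]), 0)
  }
})

test_that("lasso split fitting recovers planted coefficients", {
  set.seed(41)
  n <- 2000
  beta <- c(8, 4, 6, 3, 2, 2, 5, 2.5, 4, 2, 1.5, 1.5)
  X <- matrix(rbinom(n * 12, 1, 0.25), n, 12)
  y <- as.vector(X %*% beta) + rnorm(n, 10, 1.5)
  fit <- fit_lasso_splits(list(X = X, y = y), n_splits = 40, seed = 9)
  expect_equal(length(fit$coef_mean), 12)
  expect_equal(nrow(fit$coef_splits), 80)
  expect_gt(stats::cor(fit$coef_mean, beta), 0.95)
  # identical seed: bit-identical estimates
  fit2 <- fit_lasso_splits(list(X = X, y = y), n_splits = 40, seed = 9)
  expect_identical(fit$coef_splits, fit2$coef_splits)
  # all-zero responses shrink every coefficient to zero
  fit0 <- fit_lasso_splits(list(X = X, y = rep(0, n)), n_splits = 5,
                           seed = 1)
  expect_true(all(fit0$coef_mean == 0))
  expect_error(fit_lasso_splits(list(X = X[1:20, ], y = y[1:20])), ">= 40")
})

test_that("the lasso path is monotone in the penalty", {
  set.seed(42)
  X <- matrix(rbinom(3000, 1, 0.3), 250, 12)
  y <- as.vector(X %*% rnorm(12, 3, 2)) + rnorm(250)
  lams <- c(0.01, 0.1, 0.5, 1, 3, 10)
  nz <- vapply(lams, function(l) {
    f <- fit_lasso_splits(list(X = X, y = y), n_splits = 3, seed = 2,
                          lambda = l)
    sum(abs(f$coef_mean) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("split averaging reduces coefficient variance", {
  set.seed(43)
  n <- 300
  beta <- rnorm(12, 4, 2)
  X <- matrix(rbinom(n * 12, 1, 0.3), n, 12)
  y <- as.vector(X %*% beta) + rnorm(n, 0, 3)
  fit <- fit_lasso_splits(list(X = X, y = y), n_splits = 50, seed = 3)
  single_err <- mean((fit$coef_splits[1, ] - beta)^2)
  avg_err <- mean((fit$coef_mean - beta)^2)
  expect_lt(avg_err, single_err)
})

test_that("state-dependent coefficient spread is detected", {
  set.seed(44)
  n_units <- 40
  base <- matrix(rexp(n_units * 6, 1 / 5), n_units, 6)
  cm <- cbind(base * 2, base) # target-state block spread out twofold
  cm <- cm + matrix(rnorm(n_units * 12, 0, 0.3), n_units, 12)
  res <- attention_subspace_summary(cm, seed = 4)
  expect_gt(res$target_state$distance, res$distractor_state$distance)
  expect_lt(res$distance_test$p.value, 0.01)
  # identical blocks: distance ratio 1, angle difference 0
  cm_eq <- cbind(base, base)
  res_eq <- attention_subspace_summary(cm_eq, seed = 5)
  expect_equal(res_eq$target_state$distance,
               res_eq$distractor_state$distance)
  expect_equal(res_eq$target_state$angle, res_eq$distractor_state$angle)
  # module distance equals the brute-force pairwise mean
  V <- t(cm[, 1:6])
  brute <- mean(utils::combn(6, 2, function(ij)
    sqrt(sum((V[ij[1], ] - V[ij[2], ])^2))))
  expect_lt(abs(res$target_state$distance - brute), 1e-12)
  expect_error(attention_subspace_summary(cm[1:5, ]), ">= 10 units")
})

test_that("session-planted encoding coefficients are recovered", {
  s <- demo_session()
  gt <- s$ground_truth$units
  idx <- which(gt$rf_class == "peripheral_localized")
  xy <- s$array_geometry$coordinates
  cors <- vapply(idx[1:3], function(i) {
    d <- sqrt((xy[, 1] - gt$rf_x[i])^2 + (xy[, 2] - gt$rf_y[i])^2)
    des <- build_design(s, s$units[[i]], which(d <= gt$rf_sigma[i]))
    fit <- fit_lasso_splits(des, n_splits = 20, seed = i)
    stats::cor(fit$coef_mean, s$ground_truth$encoding_coefficients[i, ])
  }, numeric(1))
  expect_gt(median(cors), 0.8)
})
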