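# build a psth_matrix-shaped object directly from synthetic numbers, so
# dPCA contracts can be tested against exact constructions
make_psth <- function(vals, T_, C, conds = paste0("c", seq_len(C)),
                      obs = NULL) {
  structure(list(values = vals, T = T_, C = C, conditions = conds,
                 times = seq_len(T_), unit_ids = paste0("u", seq_len(ncol(vals))),
                 observations = obs),
            class = "psth_matrix")
}

test_that("PSTH matrix has the documented shape and equals a naive average", {
  s <- demo_session()
  ps <- build_psth_matrix(s, epoch = "cue", conditions = "category")
  expect_equal(ps$T, 50) # 500 ms / 10 ms bins
  expect_equal(ps$C, 2)
  expect_equal(dim(ps$values), c(100, length(ps$unit_ids)))
  # condition means equal brute-force per-unit trial averages
  obs <- ps$observations
  for (ci in seq_along(ps$conditions)) {
    rows <- obs$labels == ps$conditions[ci]
    naive <- colMeans(obs$resp[rows, , drop = FALSE])
    naive_mat <- matrix(naive, ps$T, length(ps$unit_ids))
    expect_lt(max(abs(ps$values[(ci - 1) * ps$T + seq_len(ps$T), ] -
                        naive_mat)), 1e-12)
  }
  expect_error(build_psth_matrix(s, epoch = "search", conditions = "nope"),
               "unknown conditions")
  expect_error(build_psth_matrix(s, epoch = "cue", conditions = "attention"),
               "category")
})

test_that("dPCA recovers a planted rank-1 condition axis", {
  set.seed(11)
  N <- 30; T_ <- 20; C <- 2
  v <- rnorm(N); v <- v / sqrt(sum(v^2))
  tpat <- sin(seq(0, pi, length.out = T_))
  vals <- matrix(0, T_ * C, N)
  for (c in 1:C) {
    cond_eff <- (c - 1.5) * 2 # -1, +1
    vals[(c - 1) * T_ + seq_len(T_), ] <-
      outer(tpat, rnorm(N, 1, 0.1)) + cond_eff * outer(rep(1, T_), v) +
      matrix(rnorm(T_ * N, 0, 0.05), T_, N)
  }
  fit <- fit_dpca(make_psth(vals, T_, C))
  ax <- fit$marginalizations$condition$encoder[, 1]
  expect_gt(abs(sum(ax * v)), 0.95)
})

test_that("single-condition dPCA reduces to PCA of the mean trajectory", {
  set.seed(12)
  N <- 25; T_ <- 40
  vals <- outer(sin(seq(0, 3, length.out = T_)), rnorm(N)) +
    outer(cos(seq(0, 5, length.out = T_)), rnorm(N)) +
    matrix(rnorm(T_ * N, 0, 0.01), T_, N)
  fit <- fit_dpca(make_psth(vals, T_, 1), marginalizations = "time")
  pca <- stats::prcomp(vals, center = TRUE)
  for (i in 1:3) {
    cosang <- abs(sum(fit$marginalizations$time$encoder[, i] *
                        pca$rotation[, i]))
    expect_gt(cosang, 0.99)
  }
})

test_that("condition variance is ~0 without condition structure", {
  set.seed(13)
  N <- 20; T_ <- 30
  shared <- outer(sin(seq(0, 2, length.out = T_)), rnorm(N, 1))
  vals <- rbind(shared, shared) + matrix(rnorm(2 * T_ * N, 0, 1e-4), 2 * T_, N)
  fit <- fit_dpca(make_psth(vals, T_, 2))
  expect_lt(sum(fit$marginalizations$condition$explained_var), 0.01)
})

test_that("explained-variance fractions are proper and projection is linear", {
  s <- demo_session()
  ps <- build_psth_matrix(s, epoch = "cue", conditions = "category")
  fit <- fit_dpca(ps, marginalizations = c("condition", "time"))
  ev <- unlist(lapply(fit$marginalizations, `[[`, "explained_var"))
  expect_true(all(ev >= 0))
  expect_lte(sum(ev), 1 + 1e-8)
  # linearity: the projection of a condition-mean equals the mean projection
  tj <- dpca_project(fit, ps)
  mean_point <- apply(tj$coords, c(2, 3), mean)
  ps_mean <- ps
  mixed <- (ps$values[seq_len(ps$T), ] +
              ps$values[ps$T + seq_len(ps$T), ]) / 2
  ps_mean$values <- rbind(mixed, mixed)
  tj_mean <- dpca_project(fit, ps_mean)
  expect_equal(tj_mean$coords[1, , ], mean_point, tolerance = 1e-10)
})

test_that("reference demixing transfers and enforces unit matching", {
  s <- demo_session()
  ps_cue <- build_psth_matrix(s, epoch = "cue", conditions = "category")
  ps_delay <- build_psth_matrix(s, epoch = "delay", conditions = "category")
  # reference = apply reproduces fit + project
  both <- demixing_from_reference(ps_cue, ps_cue)
  direct <- dpca_project(fit_dpca(ps_cue), ps_cue)
  expect_equal(both$trajectory$coords, direct$coords, tolerance = 1e-10)
  # planted maintenance: cue axes separate delay conditions too
  tr_delay <- demixing_from_reference(ps_cue, ps_delay)$trajectory
  d_sep <- sqrt(rowSums((tr_delay$coords[1, , ] - tr_delay$coords[2, , ])^2))
  lab <- rep(c(1, 2), each = ps_delay$T)
  pts <- rbind(tr_delay$coords[1, , ], tr_delay$coords[2, , ])
  acc <- mean(stats::predict(MASS::lda(pts, lab))$class == lab)
  expect_gt(acc, 0.8)
  # permuted unit order is an error
  ps_perm <- ps_delay
  ps_perm$unit_ids <- rev(ps_perm$unit_ids)
  expect_error(demixing_from_reference(ps_cue, ps_perm), "mismatch")
})

test_that("copied condition data yields zero significant bins", {
  set.seed(14)
  T_ <- 15; N <- 12; n_obs <- 60
  resp <- matrix(rnorm(n_obs * T_ * N, 5, 1), n_obs)
  half <- resp[1:30, ]
  resp <- rbind(half, half) # identical data in both conditions
  labels <- rep(c("a", "b"), each = 30)
  vals <- popdyn:::.condition_means(resp, labels, c("a", "b"), T_, N)
  ps <- make_psth(vals, T_, 2, c("a", "b"),
                  obs = list(resp = resp, labels = labels))
  res <- trajectory_separation_test(ps, n_perm = 150, seed = 3)
  expect_equal(sum(res$significant), 0)
})

test_that("a planted onset-locked difference is flagged from its onset", {
  set.seed(15)
  T_ <- 20; N <- 15; n_per <- 40
  onset_bin <- 8
  v <- rnorm(N)
  mk <- function(shift) {
    t(vapply(seq_len(n_per), function(i) {
      base <- rep(rnorm(T_, 5, 0.2), N)
      eff <- as.vector(outer(c(rep(0, onset_bin - 1),
                               rep(shift, T_ - onset_bin + 1)), v))
      base + eff + rnorm(T_ * N, 0, 0.3)
    }, numeric(T_ * N)))
  }
  resp <- rbind(mk(-1), mk(1))
  labels <- rep(c("a", "b"), each = n_per)
  vals <- popdyn:::.condition_means(resp, labels, c("a", "b"), T_, N)
  ps <- make_psth(vals, T_, 2, c("a", "b"),
                  obs = list(resp = resp, labels = labels))
  res <- trajectory_separation_test(ps, n_perm = 200, seed = 4)
  late <- res$significant[onset_bin:T_]
  expect_gte(mean(late), 0.8)
  # shuffle-null exchangeability: observed pre-onset bins stay mostly null
  expect_lte(mean(res$significant[seq_len(onset_bin - 1)]), 0.35)
})
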