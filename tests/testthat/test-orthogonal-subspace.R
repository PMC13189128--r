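test_that("average-FR axis is the vector of coefficient sums", {
  w <- diag(3) # each PC loads one unit with weight 1
  expect_equal(average_fr_axis(rbind(w, matrix(0, 2, 3))), c(1, 1, 1))
  # a uniform rate increase projects onto tau
  set.seed(21)
  W <- qr.Q(qr(matrix(rnorm(30), 10, 3))) # random orthonormal encoder
  tau <- average_fr_axis(W)
  pt <- as.vector(t(W) %*% rep(2.5, 10)) # uniform pattern in unit space
  cosang <- abs(sum(pt * tau)) / sqrt(sum(pt^2) * sum(tau^2))
  expect_gt(cosang, 0.999)
  # zero-sum columns are degenerate
  w0 <- rbind(c(1, 1, 1), c(-1, -1, -1))
  expect_error(average_fr_axis(w0), "degenerate")
})

test_that("point decomposition is exact (Pythagoras and reconstruction)", {
  set.seed(22)
  tau <- c(2, -1, 0.5)
  P <- matrix(rnorm(3000), ncol = 3)
  d <- decompose_point(P, tau)
  # Pythagoras on every point
  expect_lt(max(abs(d$parallel^2 + rowSums(d$orthogonal^2) -
                      rowSums(P^2))), 1e-9)
  # exact reconstruction from the basis
  rec <- outer(d$parallel, d$basis$tau_hat) +
    outer(d$orthogonal[, 1], d$basis$x_hat) +
    outer(d$orthogonal[, 2], d$basis$y_hat)
  expect_lt(max(abs(rec - P)), 1e-9)
  # on-axis and orthogonal special cases
  that <- tau / sqrt(sum(tau^2))
  d1 <- decompose_point(2 * that, tau)
  expect_equal(d1$parallel, 2, tolerance = 1e-12)
  expect_lt(max(abs(d1$orthogonal)), 1e-12)
  perp <- c(-tau[2], tau[1], 0)
  expect_lt(abs(decompose_point(perp, tau)$parallel), 1e-12)
  # collinear seed falls back with a message
  expect_message(dd <- decompose_point(c(0, 1, 1), c(10, 0, 0)),
                 "fallback")
  expect_lt(abs(sum(dd$basis$x_hat * c(1, 0, 0))), 1e-9)
})

test_that("basis vectors are mutually orthogonal unit vectors", {
  set.seed(23)
  for (k in 1:20) {
    tau <- rnorm(3)
    b <- decompose_point(rnorm(3), tau)$basis
    M <- rbind(b$tau_hat, b$x_hat, b$y_hat)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-12)
  }
})

test_that("classification reads gain codes from the parallel axis only", {
  set.seed(24)
  tau <- c(1, 1, 1)
  that <- tau / sqrt(3)
  n <- 40
  # pure gain code: classes differ only along tau
  gain_pts <- rbind(outer(rnorm(n, 3, 0.3), that),
                    outer(rnorm(n, 6, 0.3), that)) +
    matrix(rnorm(2 * n * 3, 0, 0.05), 2 * n, 3)
  labs <- rep(c("d", "t"), each = n)
  d <- decompose_point(gain_pts, tau)
  expect_gt(classify_component(d, labs, "parallel")$accuracy, 0.9)
  expect_lt(classify_component(d, labs, "orthogonal")$accuracy, 0.75)
  # orthogonal code: classes differ only in the plane
  b <- d$basis
  orth_pts <- rbind(outer(rep(4, n), that) + outer(rnorm(n, -2, 0.3), b$x_hat),
                    outer(rep(4, n), that) + outer(rnorm(n, 2, 0.3), b$x_hat)) +
    matrix(rnorm(2 * n * 3, 0, 0.05), 2 * n, 3)
  d2 <- decompose_point(orth_pts, tau)
  expect_gt(classify_component(d2, labs, "orthogonal")$accuracy, 0.9)
  expect_lt(classify_component(d2, labs, "parallel")$accuracy, 0.75)
  # random labels: chance
  acc_rand <- classify_component(d, sample(labs), "parallel")$accuracy
  expect_lt(acc_rand, 0.75)
  expect_error(classify_component(d, rep("x", 2 * n), "parallel"),
               "2 classes")
})

test_that("unit-space rotation leaves the projected state space unchanged", {
  # the demixed components are equivariant under orthogonal rotation of
  # unit space: encoders rotate with the data, so projected coordinates
  # (and any classification run on all three of them) are identical. The
  # average-FR axis itself is basis-dependent by construction (it is the
  # coefficient sum over the *recorded* units), so only the full-space
  # properties are compared.
  set.seed(25)
  N <- 20; T_ <- 9
  base <- matrix(rnorm(2 * T_ * N, 5, 0.3), 2 * T_, N)
  base[T_ + seq_len(T_), ] <- base[T_ + seq_len(T_), ] + 1.5
  R <- qr.Q(qr(matrix(rnorm(N * N), N)))
  run <- function(vals) {
    ps <- structure(list(values = vals, T = T_, C = 2,
                         conditions = c("d", "t"), times = 1:T_,
                         unit_ids = paste0("u", 1:N)),
                    class = "psth_matrix")
    fit <- fit_dpca(ps, marginalizations = "condition")
    dpca_project(fit, ps)$coords
  }
  c1 <- run(base)
  c2 <- run(base %*% t(R))
  expect_equal(abs(c1), abs(c2), tolerance = 1e-6)
  labs <- rep(c("d", "t"), each = T_)
  acc <- function(co) {
    pts <- rbind(co[1, , ], co[2, , ])
    mean(stats::predict(MASS::lda(pts, labs))$class == labs)
  }
  expect_equal(acc(c1), acc(c2))
})

test_that("condition points use the printed bin centers and stimulus grid", {
  s <- demo_classified()
  fov <- demo_foveal_mask()
  cp <- build_condition_points(s, fov, subspace = "attention")
  expect_equal(cp$times, c(-45, -15, 15, 45, 75, 105, 135, 165, 195))
  expect_equal(dim(cp$coords)[2], 9)
  expect_equal(dim(cp$coords)[3], 3)
  # conditions = chosen stimuli x 2 attention states
  expect_equal(dim(cp$coords)[1], 2 * length(cp$stimuli))
  expect_equal(nrow(cp$labels), dim(cp$coords)[1])
  expect_setequal(unique(cp$labels$attention), c("target", "distractor"))
  # decomposition covers every (condition, time) point
  expect_equal(length(cp$decomposed$parallel),
               dim(cp$coords)[1] * dim(cp$coords)[2])
  # parallel coordinate tracks the population-mean normalized rate
  # (exact within the 3-D space; session data add out-of-space noise)
  C <- dim(cp$coords)[1]
  pm <- matrix(rowMeans(cp$values), ncol = C) # T x C
  pm_pts <- as.vector(t(pm)) # condition-fastest, matching the points
  expect_gt(abs(stats::cor(cp$decomposed$parallel, pm_pts)), 0.99)
})

test_that("the parallel coordinate is exactly the rate axis in-space", {
  set.seed(26)
  N <- 30; n_pts <- 50
  U <- qr.Q(qr(matrix(rnorm(N * 3), N, 3)))
  pts <- matrix(rnorm(n_pts * 3), n_pts, 3)
  act <- pts %*% t(U) # activity embedded exactly in the 3-D space
  tau <- average_fr_axis(U)
  d <- decompose_point(pts, tau)
  expect_gt(abs(stats::cor(d$parallel, rowMeans(act))), 0.999)
})
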