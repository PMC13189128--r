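## Decomposition of 3-D state-space points into the population-average-
## firing-rate (parallel) coordinate and the orthogonal-plane coordinates,
## plus linear-discriminant classification from each component separately.

#' Population-average firing-rate axis from PC coefficients
#'
#' A uniform rate increase `delta * 1` in unit space projects to
#' `delta * (sum_n w_1n, sum_n w_2n, sum_n w_3n)` in component space, so
#' the rate axis is the vector of per-component coefficient sums.
#'
#' @param pc_coefficients `N x 3` matrix of unit coefficients on the three
#'   components (e.g. a [fit_dpca()] encoder).
#' @return Length-3 axis vector.
#' @export
average_fr_axis <- function(pc_coefficients) {
  stopifnot(is.matrix(pc_coefficients), ncol(pc_coefficients) == 3)
  tau <- colSums(pc_coefficients)
  if (sqrt(sum(tau^2)) < 1e-12 * sqrt(sum(pc_coefficients^2)))
    stop("degenerate average-FR axis (coefficient columns sum to zero)",
         call. = FALSE)
  tau
}

#' Decompose 3-D points into parallel and orthogonal-plane coordinates
#'
#' The parallel coordinate is the signed length of the projection onto the
#' rate axis. The orthogonal plane passes through the origin with normal
#' `tau`; its x axis comes from projecting the seed point `[10, 0, 0]` into
#' the plane (falling back to `[0, 10, 0]` when `tau` is collinear with the
#' seed), and its y axis is `tau x xhat`, normalized. Parallel and plane
#' coordinates are signed distances, and together with the basis they
#' reconstruct each point exactly (Pythagoras: `parallel^2 +
#' ||orthogonal||^2 = ||P||^2`).
#'
#' @param P Numeric length-3 vector or `n x 3` matrix of points.
#' @param tau Rate axis from [average_fr_axis()].
#' @param seed_point Seed for the plane's x axis, default `c(10, 0, 0)`.
#' @return List: `parallel` (n), `orthogonal` (n x 2), `basis` (list of
#'   unit vectors `tau_hat`, `x_hat`, `y_hat`).
#' @export
decompose_point <- function(P, tau, seed_point = c(10, 0, 0)) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  stopifnot(ncol(P) == 3, length(tau) == 3)
  nt <- sqrt(sum(tau^2))
  if (nt == 0) stop("tau must be nonzero", call. = FALSE)
  that <- tau / nt
  x <- seed_point - sum(seed_point * that) * that
  if (sqrt(sum(x^2)) < 1e-9 * sqrt(sum(seed_point^2))) {
    message("decompose_point: tau collinear with seed; using fallback seed")
    seed_point <- c(0, 10, 0)
    x <- seed_point - sum(seed_point * that) * that
  }
  xhat <- x / sqrt(sum(x^2))
  yhat <- c(that[2] * xhat[3] - that[3] * xhat[2],
            that[3] * xhat[1] - that[1] * xhat[3],
            that[1] * xhat[2] - that[2] * xhat[1])
  yhat <- yhat / sqrt(sum(yhat^2))
  list(parallel = as.vector(P %*% that),
       orthogonal = cbind(x = as.vector(P %*% xhat),
                          y = as.vector(P %*% yhat)),
       basis = list(tau_hat = that, x_hat = xhat, y_hat = yhat))
}

#' Condition points for the 16-stimulus x 2-attention-state analysis
#'
#' Per-unit PSTHs for eight face and eight house exemplars, -60 to 210 ms
#' around fixation onset in 30-ms bins (nine steps centered at -45, -15,
#' 15, ..., 195 ms), grouped by stimulus identity and attentional status
#' (32 conditions), are projected into the 3-D demixed space fitted on the
#' chosen task parameter. Exemplars are chosen greedily to maximize the
#' number of (stimulus, state) cells with data; conditions still lacking
#' data exclude the offending exemplar pair.
#'
#' @param s A [session()].
#' @param unit_mask Logical unit mask.
#' @param subspace Task parameter defining the demixing axes:
#'   `"attention"` or `"category"`.
#' @param n_per_category Exemplars per category (default 8).
#' @param min_per_cell Minimum fixations per (stimulus, state) cell.
#' @param params [kernel_params()].
#' @return List of class `"condition_points"`: `coords` (C x 9 x 3),
#'   `labels` (data frame: exemplar, category, attention), `times`, `tau`,
#'   `decomposed` (from [decompose_point()] on all C x T points), `fit`.
#' @export
build_condition_points <- function(s, unit_mask = rep(TRUE, length(s$units)),
                                   subspace = c("attention", "category"),
                                   n_per_category = 8, min_per_cell = 1,
                                   params = kernel_params()) {
  subspace <- match.arg(subspace)
  fixtab <- fixation_table(s)
  fixtab <- fixtab[fixtab$item_category %in% c("face", "house"), , drop = FALSE]
  fixtab$stim <- paste(fixtab$item_category, fixtab$item_exemplar, sep = "_")
  fixtab$state <- ifelse(fixtab$is_target, "target", "distractor")

  # greedy stimulus choice: exemplars with the most balanced state coverage
  pick <- function(cat) {
    sub <- fixtab[fixtab$item_category == cat, ]
    cnt <- table(sub$stim, sub$state)
    if (!all(c("distractor", "target") %in% colnames(cnt)))
      stop("no ", cat, " fixations in one attention state", call. = FALSE)
    score <- pmin(cnt[, "distractor"], cnt[, "target"])
    names(sort(score, decreasing = TRUE))[seq_len(min(n_per_category,
                                                      sum(score >= min_per_cell)))]
  }
  stims <- c(pick("face"), pick("house"))
  fixtab <- fixtab[fixtab$stim %in% stims, , drop = FALSE]
  cond <- paste(fixtab$stim, fixtab$state, sep = "|")

  edges <- seq(-60, 210, by = 30)
  T_ <- 9L
  units <- s$units[unit_mask]
  tr <- trials_of(s)
  base <- vapply(units, function(u) unit_baseline(u, tr, params = params),
                 numeric(1))
  ok <- is.finite(base) & base > 0
  units <- units[ok]; base <- base[ok]
  N <- length(units)
  n_obs <- nrow(fixtab)
  resp <- matrix(0, n_obs, T_ * N)
  for (n in seq_len(N)) {
    u <- units[[n]]
    col0 <- (n - 1L) * T_
    for (i in seq_len(n_obs)) {
      sp <- u$spikes[[as.character(fixtab$trial_id[i])]]
      if (length(sp)) {
        cum <- .kernel_cumint(params, outer(fixtab$onset[i] + edges, sp, "-"))
        resp[i, col0 + seq_len(T_)] <-
          rowSums(matrix(diff(cum), nrow = T_)) * 1000 / 30 / base[n]
      }
    }
  }
  conds <- sort(unique(cond))
  lab <- do.call(rbind, strsplit(conds, "|", fixed = TRUE))
  labels <- data.frame(stim = lab[, 1], attention = lab[, 2],
                       category = sub("_.*", "", lab[, 1]),
                       stringsAsFactors = FALSE)
  vals32 <- .condition_means(resp, cond, conds, T_, N)
  # demix on the chosen task parameter, then project all conditions
  par_lab <- if (subspace == "attention") fixtab$state else fixtab$item_category
  par_conds <- sort(unique(par_lab))
  vals2 <- .condition_means(resp, par_lab, par_conds, T_, N)
  uid <- vapply(units, `[[`, "", "unit_id")
  # 3-D space: ordinary PCA of the parameter-averaged condition means
  # (captures both the shared dynamics and the parameter contrast, so the
  # population-average-rate axis lives inside it)
  fit <- fit_dpca(list(values = vals2, T = T_, C = length(par_conds),
                       conditions = par_conds,
                       times = (edges[-1] + edges[-10]) / 2, unit_ids = uid),
                  marginalizations = "all", n_components = 3)
  traj <- dpca_project(fit, list(values = vals32, T = T_, C = length(conds),
                                 conditions = conds,
                                 times = (edges[-1] + edges[-10]) / 2,
                                 unit_ids = uid),
                       basis = "encoder", marginalization = "all")
  tau <- average_fr_axis(fit$marginalizations$all$encoder)
  pts <- matrix(traj$coords, ncol = 3) # (C*T) x 3, condition fastest
  structure(list(coords = traj$coords, labels = labels,
                 times = (edges[-1] + edges[-10]) / 2, tau = tau,
                 decomposed = decompose_point(pts, tau), fit = fit,
                 stimuli = stims, values = vals32),
            class = "condition_points")
}

#' Linear-discriminant classification from one subspace component
#'
#' Trains an LDA on the parallel (1-D) or orthogonal-plane (2-D)
#' coordinates and reports stratified leave-one-out cross-validated
#' accuracy together with in-sample accuracy.
#'
#' @param decomposed A [decompose_point()] result.
#' @param labels Factor/character labels, one per point.
#' @param component `"parallel"` or `"orthogonal"`.
#' @return List of class `"component_classification"`: `component`,
#'   `accuracy` (leave-one-out), `accuracy_insample`, `scheme`.
#' @export
classify_component <- function(decomposed, labels,
                               component = c("parallel", "orthogonal")) {
  component <- match.arg(component)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need >= 2 classes", call. = FALSE)
  X <- if (component == "parallel") matrix(decomposed$parallel, ncol = 1)
       else decomposed$orthogonal
  if (min(table(y)) < 2) stop("need >= 2 points per class", call. = FALSE)
  n <- length(y)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- tryCatch(MASS::lda(X[-i, , drop = FALSE], y[-i]),
                    error = function(e) NULL)
    if (!is.null(fit))
      pred[i] <- stats::predict(fit, X[i, , drop = FALSE])$class
  }
  fit_all <- MASS::lda(X, y)
  ins <- mean(stats::predict(fit_all, X)$class == y)
  structure(list(component = component,
                 accuracy = mean(pred == y, na.rm = TRUE),
                 accuracy_insample = ins,
                 scheme = "stratified leave-one-out over condition points"),
            class = "component_classification")
}
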