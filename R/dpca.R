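## Demixed PCA over condition-averaged population tensors, trajectory
## projection, and the shuffle/FDR condition-separation test.
##
## dPCA is solved in its least-squares form: for each marginalization X_phi
## of the (neuron x condition-time) matrix X, the best rank-q map is the
## reduced-rank ridge regression X_phi ~ X, giving per-marginalization
## encoder/decoder axis pairs. By default the condition x time interaction
## is pooled into the condition marginalization, so condition axes capture
## time-varying condition differences.

#' Build a condition-averaged PSTH matrix
#'
#' Trial- (or fixation-) averaged, baseline-normalized spike-density rates
#' per condition per time bin per unit, arranged as a `(T*C) x N` matrix
#' with rows grouped condition-major. Epochs: `"cue"` (0-500 ms from cue
#' onset), `"delay"` (0-500 ms from delay onset), `"search"` (0-225 ms from
#' fixation onset). Conditions: `"category"` (face vs house cue for
#' cue/delay; fixated face vs house item for search), `"attention"`
#' (fixated target vs distractor; search only), or their cross.
#'
#' Units with zero baseline (not normalizable) are excluded with a message.
#' The observation-level binned tensor is kept as an attribute so shuffle
#' tests can rebuild condition means.
#'
#' @param s A [session()].
#' @param unit_mask Logical mask over `s$units`.
#' @param epoch `"cue"`, `"delay"`, or `"search"`.
#' @param bin_ms Bin width, default 10.
#' @param conditions `"category"`, `"attention"`, or
#'   `"category_x_attention"`.
#' @param window Override the epoch's default window.
#' @param normalized Divide by per-unit baseline (default TRUE).
#' @param params [kernel_params()].
#' @return Object of class `"psth_matrix"`.
#' @export
build_psth_matrix <- function(s, unit_mask = rep(TRUE, length(s$units)),
                              epoch = c("search", "cue", "delay"),
                              bin_ms = 10, conditions = "category",
                              window = NULL, normalized = TRUE,
                              params = kernel_params()) {
  epoch <- match.arg(epoch)
  if (is.null(window))
    window <- if (epoch == "search") c(0, 225) else c(0, 500)
  units <- s$units[unit_mask]
  tr <- trials_of(s)

  if (epoch == "search") {
    fixtab <- fixation_table(s)
    labels <- switch(conditions,
      category = ifelse(fixtab$item_category %in% c("face", "house"),
                        fixtab$item_category, NA),
      attention = ifelse(fixtab$is_target, "target", "distractor"),
      category_x_attention = ifelse(
        fixtab$item_category %in% c("face", "house"),
        paste(fixtab$item_category,
              ifelse(fixtab$is_target, "target", "distractor"), sep = "_"),
        NA),
      stop("unknown conditions '", conditions, "'", call. = FALSE))
    keep <- !is.na(labels)
    fixtab <- fixtab[keep, , drop = FALSE]
    labels <- labels[keep]
    align <- fixtab$onset
    align_trial <- as.character(fixtab$trial_id)
  } else {
    ev <- if (epoch == "cue") "cue_on" else "cue_off"
    labels <- vapply(tr, `[[`, "", "cue_category")
    if (!identical(conditions, "category"))
      stop("cue/delay epochs support conditions = 'category' only",
           call. = FALSE)
    align <- vapply(tr, function(x) x$events[[ev]], numeric(1))
    align_trial <- names(tr)
  }
  if (any(table(labels) == 0) || length(unique(labels)) < 1)
    stop("empty condition", call. = FALSE)

  edges <- seq(window[1], window[2], by = bin_ms)
  T_ <- length(edges) - 1L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  n_obs <- length(align)
  N <- length(units)

  base <- if (normalized)
    vapply(units, function(u) unit_baseline(u, tr, params = params),
           numeric(1)) else rep(1, N)
  ok <- is.finite(base) & base > 0
  if (any(!ok)) {
    message("build_psth_matrix: excluding ", sum(!ok),
            " unit(s) with zero baseline")
    units <- units[ok]; base <- base[ok]; N <- sum(ok)
  }

  # obs x (T*N) binned mean rates via the exact kernel integral
  resp <- matrix(0, n_obs, T_ * N)
  for (n in seq_len(N)) {
    u <- units[[n]]
    col0 <- (n - 1L) * T_
    for (i in seq_len(n_obs)) {
      sp <- u$spikes[[align_trial[i]]]
      if (length(sp)) {
        cum <- .kernel_cumint(params, outer(align[i] + edges, sp, "-"))
        resp[i, col0 + seq_len(T_)] <-
          rowSums(matrix(diff(cum), nrow = T_)) * 1000 / bin_ms / base[n]
      }
    }
  }
  conds <- sort(unique(labels))
  vals <- .condition_means(resp, labels, conds, T_, N)
  structure(list(values = vals, T = T_, C = length(conds),
                 conditions = conds, times = centers,
                 unit_ids = vapply(units, `[[`, "", "unit_id"),
                 epoch = epoch, bin_ms = bin_ms,
                 observations = list(resp = resp, labels = labels)),
            class = "psth_matrix")
}

# average obs x (T*N) rows by label -> (T*C) x N condition-major matrix
.condition_means <- function(resp, labels, conds, T_, N) {
  g <- match(labels, conds)
  m <- rowsum(resp, g) / as.vector(table(g))
  vals <- matrix(0, T_ * length(conds), N)
  for (c in seq_along(conds))
    vals[(c - 1L) * T_ + seq_len(T_), ] <- matrix(m[c, ], T_, N)
  vals
}

# top left singular vectors; falls back to a symmetric eigendecomposition
# when LAPACK's divide-and-conquer SVD sporadically fails to converge
.left_singular <- function(M, q) {
  u <- tryCatch(svd(M, nu = q, nv = 0)$u, error = function(e) NULL)
  if (is.null(u)) {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    u <- e$vectors[, seq_len(q), drop = FALSE]
  }
  u
}

#' Fit demixed PCA
#'
#' @param psth A [build_psth_matrix()] result, or any `(T*C) x N` matrix
#'   with attributes `T`, `C` supplied via arguments.
#' @param marginalizations Which demixed axis sets to fit: any of
#'   `"condition"`, `"time"`, `"condition_x_time"`, or `"all"` (the full
#'   centered data, for which the axes reduce to ordinary PCA).
#' @param n_components Components per marginalization (default 3).
#' @param lambda Ridge strength; `"auto"` uses `1e-6 * mean(X^2)`.
#' @param pool_interaction Pool the condition x time interaction into the
#'   condition marginalization (default TRUE).
#' @return Object of class `"dpca_fit"`: per marginalization, `encoder`
#'   (N x q), `decoder` (N x q), and `explained_var` fractions; condition
#'   axes are ordered by explained variance with sign fixed so condition 1
#'   has positive mean projection on its first axis.
#' @export
fit_dpca <- function(psth, marginalizations = c("condition", "time"),
                     n_components = 3, lambda = "auto",
                     pool_interaction = TRUE) {
  vals <- psth$values; T_ <- psth$T; C <- psth$C
  N <- ncol(vals)
  if (N < n_components)
    stop("need at least ", n_components, " units, got ", N, call. = FALSE)
  X <- t(vals) # N x (T*C), columns condition-major
  mu <- rowMeans(X)
  X <- X - mu
  arr <- array(X, c(N, T_, C))
  Mt <- apply(arr, c(1, 2), mean) # N x T condition-independent dynamics
  Mc <- apply(arr, c(1, 3), mean) # N x C time-independent condition effect
  Xt <- array(rep(Mt, C), c(N, T_, C))
  Xc <- array(Mc[, rep(seq_len(C), each = T_)], c(N, T_, C))
  Xtc <- arr - Xt - Xc
  marg <- list(time = matrix(Xt, N, T_ * C),
               condition = matrix(Xc, N, T_ * C),
               condition_x_time = matrix(Xtc, N, T_ * C),
               all = X) # full centered data: axes reduce to ordinary PCA
  if (pool_interaction && "condition" %in% marginalizations) {
    marg$condition <- marg$condition + marg$condition_x_time
    if (!"condition_x_time" %in% marginalizations)
      marg$condition_x_time <- NULL
  }
  if (identical(lambda, "auto")) lambda <- 1e-6 * mean(X^2) * ncol(X)
  XXt <- tcrossprod(X) + diag(lambda, N)
  XXt_inv <- solve(XXt)
  total_var <- sum(X^2)
  fits <- list()
  for (mg in intersect(marginalizations, names(marg))) {
    B <- marg[[mg]] %*% t(X) %*% XXt_inv
    Fq <- .left_singular(B %*% X, n_components) # encoder, N x q
    Dq <- t(t(Fq) %*% B) # decoder, N x q
    comp <- crossprod(Dq, X) # q x (T*C)
    ev <- rowSums(comp^2) / total_var # encoder columns are unit norm
    # order by explained variance; fix sign: condition 1 mean positive
    o <- order(ev, decreasing = TRUE)
    Fq <- Fq[, o, drop = FALSE]; Dq <- Dq[, o, drop = FALSE]; ev <- ev[o]
    proj1 <- crossprod(Dq, X)[, seq_len(T_), drop = FALSE]
    sgn <- ifelse(rowMeans(proj1) < 0, -1, 1)
    fits[[mg]] <- list(encoder = t(t(Fq) * sgn), decoder = t(t(Dq) * sgn),
                       explained_var = ev)
  }
  structure(list(marginalizations = fits, center = mu, T = T_, C = C,
                 conditions = psth$conditions, times = psth$times,
                 unit_ids = psth$unit_ids, total_var = total_var,
                 lambda = lambda),
            class = "dpca_fit")
}

#' Project a PSTH matrix onto fitted demixing axes
#'
#' @param fit A [fit_dpca()] result.
#' @param psth A [build_psth_matrix()] result sharing the fit's unit set
#'   and ordering (error otherwise).
#' @param marginalization Axis set to project onto (default
#'   `"condition"`).
#' @param basis Project with the demixing `"decoder"` (default, the dPCA
#'   read-out) or with the orthonormal `"encoder"` axes (PCA-style
#'   coordinates, used by the parallel/orthogonal decomposition).
#' @return Object of class `"trajectory"`: array `C x T x q` of projected
#'   coordinates plus condition labels and times.
#' @export
dpca_project <- function(fit, psth, marginalization = "condition",
                         basis = c("decoder", "encoder")) {
  basis <- match.arg(basis)
  if (!identical(fit$unit_ids, psth$unit_ids))
    stop("unit set/order mismatch between fit and data", call. = FALSE)
  ax <- fit$marginalizations[[marginalization]]
  if (is.null(ax)) stop("marginalization '", marginalization,
                        "' not in fit", call. = FALSE)
  X <- t(psth$values) - fit$center
  comp <- crossprod(if (basis == "decoder") ax$decoder else ax$encoder,
                    X) # q x (T*C)
  q <- ncol(ax$decoder)
  out <- aperm(array(comp, c(q, psth$T, psth$C)), c(3, 2, 1))
  structure(list(coords = out, conditions = psth$conditions,
                 times = psth$times, marginalization = marginalization),
            class = "trajectory")
}

#' Fit demixing axes on a reference epoch and apply them to another
#'
#' The axes are computed from the reference conditions (e.g. target
#' responses, or the averaged face/house cue responses) and then applied
#' unchanged to the other epoch's data.
#'
#' @param psth_reference,psth_apply [build_psth_matrix()] results over the
#'   same units in the same order.
#' @param ... Passed to [fit_dpca()].
#' @return List: `fit` (on the reference) and `trajectory` (projection of
#'   `psth_apply`).
#' @export
demixing_from_reference <- function(psth_reference, psth_apply, ...) {
  if (!identical(psth_reference$unit_ids, psth_apply$unit_ids))
    stop("unit set/order mismatch between reference and apply sets",
         call. = FALSE)
  fit <- fit_dpca(psth_reference, ...)
  list(fit = fit, trajectory = dpca_project(fit, psth_apply))
}

#' Shuffle test for per-bin trajectory separation
#'
#' The observed statistic is the per-bin mean pairwise Euclidean distance
#' between condition points in the top-`n_components` demixed space. The
#' null shuffles condition labels at the trial/fixation level, rebuilds the
#' condition means and refits the projection per shuffle. Per-bin p-values
#' are Benjamini-Hochberg corrected.
#'
#' @param psth A [build_psth_matrix()] result (carries the observation-
#'   level data needed for shuffling).
#' @param n_perm Number of label shuffles, default 1000 (a warning is
#'   logged below 100).
#' @param alpha FDR level, default 0.05.
#' @param n_components Projection dimensionality, default 3.
#' @param seed RNG seed for the shuffles.
#' @return List: `distance` (per bin), `p_raw`, `p_fdr`, `significant`
#'   (logical per bin), `null` (n_perm x T matrix), `times`.
#' @export
trajectory_separation_test <- function(psth, n_perm = 1000, alpha = 0.05,
                                       n_components = 3, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse",
                            call. = FALSE)
  if (psth$C < 2) stop("need >= 2 conditions", call. = FALSE)
  obs <- psth$observations
  if (is.null(obs)) stop("psth carries no observation-level data", call. = FALSE)
  T_ <- psth$T; N <- length(psth$unit_ids)

  bin_dist <- function(vals) {
    fit <- fit_dpca(list(values = vals, T = T_, C = psth$C,
                         conditions = psth$conditions, times = psth$times,
                         unit_ids = psth$unit_ids),
                    marginalizations = "condition",
                    n_components = n_components)
    co <- dpca_project(fit, list(values = vals, T = T_, C = psth$C,
                                 conditions = psth$conditions,
                                 times = psth$times,
                                 unit_ids = psth$unit_ids))$coords
    vapply(seq_len(T_), function(t)
      mean(stats::dist(matrix(co[, t, ], nrow = psth$C))), numeric(1))
  }
  observed <- bin_dist(psth$values)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(k) {
      lab <- sample(obs$labels)
      bin_dist(.condition_means(obs$resp, lab, psth$conditions, T_, N))
    }, numeric(T_)))
  })
  p_raw <- vapply(seq_len(T_), function(t)
    (1 + sum(null[, t] >= observed[t])) / (n_perm + 1), numeric(1))
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  list(distance = observed, p_raw = p_raw, p_fdr = p_fdr,
       significant = p_fdr < alpha, null = null, times = psth$times)
}
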