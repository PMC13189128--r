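## Representational geometry: distances and angles between neuronal
## vectors, the angle between category and attention classifier
## hyperplanes, Procrustes ("rotated PCA") subspace alignment, and the
## first-fixation / refixation and before / after-target context
## comparisons.

#' Euclidean representational distance
#'
#' @param a,b Neuronal vectors of equal length; or, with
#'   `context = "mean_pairwise"`, `a` is a conditions-by-units matrix and
#'   the mean pairwise distance across its rows is returned (`b` ignored).
#' @param context `"pair"` or `"mean_pairwise"`.
#' @return Scalar distance.
#' @export
representational_distance <- function(a, b = NULL,
                                      context = c("pair", "mean_pairwise")) {
  context <- match.arg(context)
  if (context == "pair") {
    if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
    sqrt(sum((a - b)^2))
  } else {
    stopifnot(is.matrix(a))
    mean(stats::dist(a))
  }
}

#' Angle between neuronal vectors (degrees)
#'
#' @param a,b Nonzero vectors of equal length.
#' @return Angle in `[0, 180]` degrees.
#' @export
vector_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector has no direction", call. = FALSE)
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
}

# one linear max-margin classifier; returns (w, b) in the original feature
# space, oriented so that the first factor level scores positive. Features
# are standardized internally for optimizer stability and the weights
# back-transformed.
.linear_classifier <- function(X, y) {
  y <- factor(y)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  fit <- e1071::svm(Xs, y, kernel = "linear", scale = FALSE, cost = 1)
  ws <- as.vector(t(fit$coefs) %*% fit$SV)
  w <- ws / sd_
  b <- -fit$rho - sum(ws * mu / sd_)
  sc <- X %*% w + b
  if (mean(sc[y == levels(y)[1]]) < mean(sc[y == levels(y)[2]])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

# average classifier over balanced subsamples (min-class count per draw)
.avg_classifier <- function(X, y, n_subsamples, min_per_class = 3) {
  y <- factor(y)
  idx <- split(seq_along(y), y)
  m <- min(lengths(idx))
  if (m < min_per_class)
    stop(sprintf("class imbalance: counts %s too small for balanced subsampling",
                 paste(lengths(idx), collapse = "/")), call. = FALSE)
  ws <- matrix(0, n_subsamples, ncol(X)); bs <- numeric(n_subsamples)
  for (k in seq_len(n_subsamples)) {
    take <- unlist(lapply(idx, function(i) sample(i, m)))
    cl <- .linear_classifier(X[take, , drop = FALSE], y[take])
    ws[k, ] <- cl$w; bs[k] <- cl$b
  }
  list(w = colMeans(ws), b = mean(bs))
}

#' Angle between the category and attention classifier hyperplanes
#'
#' Two linear classifiers are trained on fixation-level population rate
#' vectors: a category classifier (faces vs houses, on the rows where
#' `labels_a` is non-NA) and an attention classifier (target vs distractor,
#' on the rows where `labels_b` is non-NA). Each classifier is the average
#' of `n_subsamples` balanced-subsample fits; the hyperplane angle is the
#' arc-cosine of the cosine similarity of the two averaged weight vectors.
#' The null distribution shuffles both label sets and retrains
#' (`n_null_subsamples` balanced fits per shuffle).
#'
#' @param rates Fixations x units matrix of mean rates (0-255 ms from
#'   fixation onset by convention).
#' @param labels_a Category labels (NA = fixation not used by scheme A).
#' @param labels_b Attention labels (NA = not used by scheme B).
#' @param n_subsamples Balanced subsamples per classifier, default 100.
#' @param n_shuffles Null shuffles, default 1000.
#' @param n_null_subsamples Subsamples per null classifier, default 5.
#' @param seed RNG seed.
#' @return List of class `"hyperplane_pair"`: `w1`, `w2`, `b1`, `b2`,
#'   `angle` (degrees), `null_angles`, `p` (two-sided exceedance of 90
#'   minus observed against the null).
#' @export
hyperplane_angle <- function(rates, labels_a, labels_b, n_subsamples = 100,
                             n_shuffles = 1000, n_null_subsamples = 5,
                             seed = 1L) {
  stopifnot(nrow(rates) == length(labels_a),
            nrow(rates) == length(labels_b))
  ia <- which(!is.na(labels_a)); ib <- which(!is.na(labels_b))
  with_seed(seed, {
    c1 <- .avg_classifier(rates[ia, , drop = FALSE], labels_a[ia], n_subsamples)
    c2 <- .avg_classifier(rates[ib, , drop = FALSE], labels_b[ib], n_subsamples)
    ang <- vector_angle(c1$w, c2$w)
    null_angles <- vapply(seq_len(n_shuffles), function(k) {
      s1 <- .avg_classifier(rates[ia, , drop = FALSE],
                            sample(labels_a[ia]), n_null_subsamples)
      s2 <- .avg_classifier(rates[ib, , drop = FALSE],
                            sample(labels_b[ib]), n_null_subsamples)
      vector_angle(s1$w, s2$w)
    }, numeric(1))
    p <- (1 + sum(abs(null_angles - 90) >= abs(ang - 90))) / (n_shuffles + 1)
    structure(list(w1 = c1$w, w2 = c2$w, b1 = c1$b, b2 = c2$b,
                   angle = ang, null_angles = null_angles, p = p),
              class = "hyperplane_pair")
  })
}

#' Procrustes alignment of condition layouts (rotated PCA)
#'
#' Each subspace (a conditions x dims coordinate matrix) is rotated and
#' isotropically scaled to best match the reference layout in the
#' least-squares sense. Reflections are disallowed unless enabled; when a
#' reflection would be required, the best proper rotation is used and the
#' result is flagged.
#'
#' @param subspace_list List of conditions x d matrices (or a single
#'   matrix).
#' @param reference Conditions x d reference layout (e.g. physical
#'   coordinates).
#' @param allow_reflection Permit improper rotations (default FALSE).
#' @param scale Fit an isotropic scale (default TRUE).
#' @return List per subspace: `aligned` coordinates, `rotation`, `scale`,
#'   `residual` (normalized sum of squares), `reflection_needed`.
#' @export
rpca_align <- function(subspace_list, reference, allow_reflection = FALSE,
                       scale = TRUE) {
  if (is.matrix(subspace_list)) subspace_list <- list(subspace_list)
  if (nrow(reference) < 3)
    stop("need >= 3 shared conditions for alignment", call. = FALSE)
  ref_c <- scale(reference, scale = FALSE)
  out <- lapply(subspace_list, function(A) {
    stopifnot(nrow(A) == nrow(reference), ncol(A) == ncol(reference))
    Ac <- scale(A, scale = FALSE)
    M <- crossprod(Ac, ref_c)
    sv <- svd(M)
    refl <- det(sv$u %*% t(sv$v)) < 0
    d_adj <- rep(1, length(sv$d))
    if (refl && !allow_reflection) d_adj[length(d_adj)] <- -1
    R <- sv$u %*% diag(d_adj, length(d_adj)) %*% t(sv$v)
    s <- if (scale) sum(sv$d * d_adj) / sum(Ac^2) else 1
    if (!is.finite(s) || s <= 0) s <- 1
    aligned <- s * Ac %*% R + rep(colMeans(reference), each = nrow(A))
    resid <- sum((s * Ac %*% R - ref_c)^2) / sum(ref_c^2)
    list(aligned = aligned, rotation = R, scale = s, residual = resid,
         reflection_needed = refl && !allow_reflection)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Context comparison of fixation responses and geometry
#'
#' Splits fixations either by novelty (`"refixation"`: first-time vs
#' return fixations) or by search stage (`"target"`: before vs after the
#' first fixation on a target), computes per-unit mean normalized rates
#' 150-250 ms after fixation onset per fixated category (face / house /
#' flower / hand) per split group, runs a two-tailed paired t-test across
#' units on the group means, and compares the 4-condition representational
#' geometry (mean pairwise distance and vector angle) between the groups.
#'
#' @param s A [session()].
#' @param unit_mask Logical unit mask.
#' @param split `"refixation"` or `"target"`.
#' @param window Response window (ms from fixation onset), default
#'   `c(150, 250)`.
#' @param params [kernel_params()].
#' @return List: `per_unit` (units x condition x group means),
#'   `paired_test` (htest), `distance` and `angle` per group, `n_units`.
#' @export
context_comparison <- function(s, unit_mask = rep(TRUE, length(s$units)),
                               split = c("refixation", "target"),
                               window = c(150, 250),
                               params = kernel_params()) {
  split <- match.arg(split)
  fixtab <- fixation_table(s)
  grp <- if (split == "refixation") {
    ifelse(fixtab$is_refixation, "refixated", "first")
  } else {
    ifelse(fixtab$after_first_target_fix, "after", "before")
  }
  groups <- sort(unique(grp))
  if (length(groups) < 2) stop("split has a single group", call. = FALSE)
  # keep only categories observed in both groups (sparse refixation /
  # post-target data can miss rare categories entirely)
  ct <- table(fixtab$item_category, grp)
  cats <- rownames(ct)[apply(ct >= 2, 1, all)]
  if (length(cats) < 2)
    stop("fewer than 2 categories observed in both groups", call. = FALSE)
  keep_fx <- fixtab$item_category %in% cats
  fixtab <- fixtab[keep_fx, , drop = FALSE]
  grp <- grp[keep_fx]
  units <- s$units[unit_mask]
  tr <- trials_of(s)
  base <- vapply(units, function(u) unit_baseline(u, tr, params = params),
                 numeric(1))
  cell <- interaction(fixtab$item_category, grp, drop = FALSE)
  per_unit <- array(NA_real_, c(length(units), length(cats), 2),
                    dimnames = list(vapply(units, `[[`, "", "unit_id"),
                                    cats, groups))
  for (n in seq_along(units)) {
    if (!is.finite(base[n]) || base[n] <= 0) next
    r <- unit_fixation_responses(units[[n]], fixtab, window, params) / base[n]
    m <- tapply(r, list(fixtab$item_category, grp), mean)
    per_unit[n, , ] <- m[cats, groups]
  }
  complete <- apply(per_unit, 1, function(x) all(is.finite(x)))
  if (sum(!complete))
    message("context_comparison: excluding ", sum(!complete),
            " unit(s) lacking data in some condition/group cell")
  if (sum(complete) < 3)
    stop("context_comparison: fewer than 3 units with complete data",
         call. = FALSE)
  pu <- per_unit[complete, , , drop = FALSE]
  g1 <- apply(pu[, , 1, drop = FALSE], 1, mean)
  g2 <- apply(pu[, , 2, drop = FALSE], 1, mean)
  tt <- stats::t.test(g1, g2, paired = TRUE)
  geom <- lapply(seq_along(groups), function(g) {
    V <- t(pu[, , g]) # conditions x units
    ang <- mean(utils::combn(nrow(V), 2, function(ij)
      vector_angle(V[ij[1], ], V[ij[2], ])))
    list(distance = representational_distance(V, context = "mean_pairwise"),
         angle = ang)
  })
  names(geom) <- groups
  list(per_unit = pu, paired_test = tt, split = split, groups = groups,
       distance = vapply(geom, `[[`, 0, "distance"),
       angle = vapply(geom, `[[`, 0, "angle"),
       n_units = sum(complete))
}
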