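## Spatial representational similarity analysis: does population activity
## preserve the physical geometry of the 20-location search array?

new_dm <- function(values, labels, metric) {
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, metric = metric),
            class = "dissimilarity_matrix")
}

#' Physical dissimilarity matrix of the array locations
#'
#' @param geometry An [array_geometry()].
#' @return `"dissimilarity_matrix"` of pairwise Euclidean distances
#'   (degrees).
#' @export
physical_dm <- function(geometry) {
  xy <- geometry$coordinates
  new_dm(as.matrix(stats::dist(xy)), as.character(seq_len(nrow(xy))),
         "euclidean")
}

#' Neural dissimilarity matrices per post-fixation time window
#'
#' Fixations are grouped by fixated location; per window the mean
#' population vector per location is computed (baseline-normalized rates)
#' and entries are `1 - Pearson r` between location vectors. Locations
#' with fewer than `min_fixations` fixations are excluded (and should be
#' dropped from the physical DM by label matching).
#'
#' @param s A [session()].
#' @param unit_mask Logical unit mask.
#' @param windows List of `c(a, b)` windows (ms from fixation onset);
#'   default the four 50-ms bins covering 0-200 ms.
#' @param min_fixations Minimum fixations per location, default 5.
#' @param params [kernel_params()].
#' @return List of `"dissimilarity_matrix"` objects (one per window), with
#'   the per-location population vectors attached as `attr(, "vectors")`.
#' @export
neural_dm <- function(s, unit_mask = rep(TRUE, length(s$units)),
                      windows = list(c(0, 50), c(50, 100), c(100, 150),
                                     c(150, 200)),
                      min_fixations = 5, params = kernel_params()) {
  fixtab <- fixation_table(s)
  counts <- table(fixtab$location_index)
  keep_loc <- as.integer(names(counts)[counts >= min_fixations])
  if (length(keep_loc) < length(counts))
    message("neural_dm: excluding ", length(counts) - length(keep_loc),
            " location(s) with < ", min_fixations, " fixations")
  fixtab <- fixtab[fixtab$location_index %in% keep_loc, , drop = FALSE]
  units <- s$units[unit_mask]
  tr <- trials_of(s)
  base <- vapply(units, function(u) unit_baseline(u, tr, params = params),
                 numeric(1))
  ok <- is.finite(base) & base > 0
  units <- units[ok]; base <- base[ok]
  lapply(windows, function(w) {
    R <- vapply(seq_along(units), function(n)
      unit_fixation_responses(units[[n]], fixtab, w, params) / base[n],
      numeric(nrow(fixtab)))
    V <- rowsum(R, fixtab$location_index) /
      as.vector(table(fixtab$location_index))
    dm <- 1 - stats::cor(t(V))
    diag(dm) <- 0
    out <- new_dm(dm, rownames(V), "one_minus_pearson")
    attr(out, "vectors") <- V
    out
  })
}

#' Spearman correlation test between neural and physical DMs
#'
#' Correlates the lower-triangle entries by Spearman's rho; the null
#' shuffles the neural DM's location labels `n_perm` times. Significance:
#' the observed rho must exceed the `1 - 0.05 / n_windows` null quantile
#' (Bonferroni over windows); the permutation p-value is also reported.
#'
#' @param ndm,pdm `"dissimilarity_matrix"` objects; `pdm` is subset to
#'   `ndm`'s labels.
#' @param n_perm Label shuffles, default 1000.
#' @param n_windows Bonferroni factor, default 4.
#' @param seed RNG seed.
#' @return List: `rho`, `p` (permutation), `significant` (Bonferroni-
#'   corrected exceedance), `null` (rho distribution).
#' @export
rsa_correlation_test <- function(ndm, pdm, n_perm = 1000, n_windows = 4,
                                 seed = 1L) {
  lab <- ndm$labels
  if (!all(lab %in% pdm$labels))
    stop("neural DM labels missing from physical DM", call. = FALSE)
  if (length(lab) < 3)
    stop("fewer than 3 shared locations; correlation undefined",
         call. = FALSE)
  P <- pdm$values[lab, lab]
  Nv <- ndm$values
  lt <- lower.tri(P)
  if (stats::sd(Nv[lt]) == 0 || stats::sd(P[lt]) == 0)
    stop("degenerate (constant) dissimilarity matrix", call. = FALSE)
  rho <- stats::cor(Nv[lt], P[lt], method = "spearman")
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    o <- sample(nrow(Nv))
    stats::cor(Nv[o, o][lt], P[lt], method = "spearman")
  }, numeric(1)))
  p <- (1 + sum(null >= rho)) / (n_perm + 1)
  crit <- stats::quantile(null, 1 - 0.05 / n_windows)
  list(rho = rho, p = p, significant = rho > crit, null = null,
       n_locations = length(lab))
}

#' Procrustes-aligned spatial state-space layouts per window
#'
#' Per window, the per-location population vectors are reduced to a 2-D
#' PCA layout and aligned (rotation + isotropic scale) to the physical x-y
#' coordinates of the locations; the normalized alignment residual
#' measures how well neural space preserves physical space.
#'
#' @param s A [session()].
#' @param geometry The session's [array_geometry()].
#' @param unit_mask Logical unit mask.
#' @param ... Passed to [neural_dm()].
#' @return List per window: `layout` (aligned 2-D coordinates),
#'   `residual`, `labels`.
#' @export
spatial_state_space <- function(s, geometry,
                                unit_mask = rep(TRUE, length(s$units)),
                                ...) {
  dms <- neural_dm(s, unit_mask, ...)
  lapply(dms, function(dm) {
    V <- attr(dm, "vectors")
    lay <- stats::prcomp(V, rank. = 2)$x
    ref <- geometry$coordinates[as.integer(dm$labels), , drop = FALSE]
    ali <- rpca_align(lay, ref)
    list(layout = ali$aligned, residual = ali$residual, labels = dm$labels,
         reflection_needed = ali$reflection_needed)
  })
}
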