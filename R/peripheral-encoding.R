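## 12-indicator lasso encoding model for peripheral units: six stimulus
## types (face/house targets and distractors, flower and hand distractors)
## crossed with the current foveal fixation type (on-target block first),
## fitted with split-half averaged lasso regression.

#' Build the 12-indicator encoding design for one unit
#'
#' For every fixation of every correct trial, indicators are set for each
#' RF-resident array item's stimulus type within the block matching the
#' current fixation type; the response is the unit's mean rate 0-250 ms
#' after fixation onset. Fixations with an empty RF keep an all-zero row.
#' A fixation on a target with a face target, a flower distractor and a
#' hand distractor in the RF codes as `(1 0 0 0 1 1 0 0 0 0 0 0)`.
#'
#' @param s A [session()].
#' @param unit A [unit_record()].
#' @param rf_locations Integer location set defining RF membership (e.g.
#'   from [classify_rf()], or ground truth in simulations).
#' @param window Response window, default `c(0, 250)` ms.
#' @param params [kernel_params()].
#' @return List: `X` (fixations x 12, 0/1), `y` (mean rates), `fixtab`.
#'   NULL (with a message) when the RF is empty on every fixation.
#' @export
build_design <- function(s, unit, rf_locations, window = c(0, 250),
                         params = kernel_params()) {
  fixtab <- fixation_table(s)
  trs <- trials_of(s)
  X <- matrix(0L, nrow(fixtab), 12,
              dimnames = list(NULL, c(paste0(ENCODING_TYPES, "_onT"),
                                      paste0(ENCODING_TYPES, "_onD"))))
  for (i in seq_len(nrow(fixtab))) {
    tr <- trs[[as.character(fixtab$trial_id[i])]]
    items <- tr$array_items[tr$array_items$location_index %in% rf_locations, ,
                            drop = FALSE]
    if (!nrow(items)) next
    idx <- encoding_type_index(items$category, items$is_target,
                               fixtab$is_target[i])
    X[i, idx] <- 1L
  }
  if (all(X == 0)) {
    message("build_design: RF empty on all fixations for unit ",
            unit$unit_id, "; skipped")
    return(NULL)
  }
  y <- unit_fixation_responses(unit, fixtab, window, params)
  list(X = X, y = y, fixtab = fixtab)
}

#' Split-half averaged lasso fit of the encoding model
#'
#' The regularization strength is selected once by 10-fold cross-validated
#' Gaussian deviance; fixations are then randomly split in half
#' `n_splits` times and the model refitted on each half at that strength,
#' giving `2 * n_splits` estimates of each coefficient whose mean is the
#' reported response strength. The intercept is unpenalized.
#'
#' @param design A [build_design()] result (or any list with `X`, `y`).
#' @param n_splits Number of random half-splits, default 100.
#' @param seed RNG seed (fit is bit-reproducible given the seed).
#' @param lambda Optional fixed regularization strength; default selects by
#'   cross-validation.
#' @return List of class `"encoding_fit"`: `coef_mean` (12),
#'   `coef_splits` (`2 n_splits` x 12), `lambda`, `n_fixations`.
#' @export
fit_lasso_splits <- function(design, n_splits = 100, seed = 1L,
                             lambda = NULL) {
  X <- design$X; y <- design$y
  n <- length(y)
  if (n < 40) stop("need >= 40 fixations, got ", n, call. = FALSE)
  if (stats::sd(y) == 0) {
    # constant response: every penalized coefficient shrinks to zero
    est <- matrix(0, 2 * n_splits, ncol(X),
                  dimnames = list(NULL, colnames(X)))
    return(structure(list(coef_mean = colMeans(est), coef_splits = est,
                          lambda = if (is.null(lambda)) Inf else lambda,
                          n_fixations = n),
                     class = "encoding_fit"))
  }
  with_seed(seed, {
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 10,
                              family = "gaussian")
      lambda <- cv$lambda.min
    }
    half <- floor(n / 2)
    est <- matrix(0, 2 * n_splits, ncol(X),
                  dimnames = list(NULL, colnames(X)))
    for (k in seq_len(n_splits)) {
      i1 <- sample.int(n, half)
      for (h in 1:2) {
        idx <- if (h == 1) i1 else setdiff(seq_len(n), i1)
        fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx], alpha = 1,
                              lambda = lambda, family = "gaussian")
        est[2 * (k - 1) + h, ] <- as.vector(stats::coef(fit))[-1]
      }
    }
    structure(list(coef_mean = colMeans(est), coef_splits = est,
                   lambda = lambda, n_fixations = n),
              class = "encoding_fit")
  })
}

#' Geometry of the encoded stimulus types per foveal attentional state
#'
#' The six stimulus-type coefficient vectors across units form neuronal
#' vectors separately for the on-target and on-distractor fixation blocks.
#' Representational distance (mean pairwise over the six conditions) and
#' mean pairwise vector angle are computed per state and compared by a
#' two-tailed paired t-test across resampled unit subsets. The
#' distractor-state PCA layout is Procrustes-aligned to the target-state
#' layout.
#'
#' @param coef_matrix Units x 12 matrix of mean encoding coefficients
#'   (rows = units with an [fit_lasso_splits()] fit).
#' @param n_subsets Resampled unit subsets for the paired test, default 15.
#' @param subset_frac Fraction of units per subset, default 0.8.
#' @param seed RNG seed.
#' @return List: per-state `distance` and `angle`, paired tests
#'   (`distance_test`, `angle_test`), aligned 2-D layouts, `n_units`.
#' @export
attention_subspace_summary <- function(coef_matrix, n_subsets = 15,
                                       subset_frac = 0.8, seed = 1L) {
  stopifnot(ncol(coef_matrix) == 12)
  n_units <- nrow(coef_matrix)
  if (n_units < 10) stop("need >= 10 units with encoding fits", call. = FALSE)
  vt <- t(coef_matrix[, 1:6]) # 6 stimulus types x units, on-target state
  vd <- t(coef_matrix[, 7:12]) # on-distractor state
  if (nrow(vt) < 3) stop("need >= 3 stimulus types", call. = FALSE)
  geom <- function(V) {
    list(distance = representational_distance(V, context = "mean_pairwise"),
         angle = mean(utils::combn(nrow(V), 2, function(ij)
           vector_angle(V[ij[1], ], V[ij[2], ]))))
  }
  gt <- geom(vt); gd <- geom(vd)
  m <- max(3, round(subset_frac * n_units))
  sub <- with_seed(seed, lapply(seq_len(n_subsets), function(k)
    sample.int(n_units, m)))
  dsub <- t(vapply(sub, function(i)
    c(representational_distance(t(coef_matrix[i, 1:6]), context = "mean_pairwise"),
      representational_distance(t(coef_matrix[i, 7:12]), context = "mean_pairwise")),
    numeric(2)))
  asub <- t(vapply(sub, function(i)
    c(geom(t(coef_matrix[i, 1:6]))$angle, geom(t(coef_matrix[i, 7:12]))$angle),
    numeric(2)))
  pca2 <- function(V) stats::prcomp(V, rank. = 2)$x
  lay_t <- pca2(vt); lay_d <- pca2(vd)
  ali <- rpca_align(lay_d, lay_t)
  list(target_state = gt, distractor_state = gd,
       distance_test = stats::t.test(dsub[, 1], dsub[, 2], paired = TRUE),
       angle_test = stats::t.test(asub[, 1], asub[, 2], paired = TRUE),
       layout_target = lay_t, layout_distractor_aligned = ali$aligned,
       alignment_residual = ali$residual, n_units = n_units,
       n_subsets = n_subsets)
}
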