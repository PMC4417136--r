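#' Ordination fit by permutation matrix regression
#'
#' Assesses how much of the community distance structure an ordination
#' represents.  Both matrices' lower triangles are unfolded and the
#' community distances are regressed by OLS on the Euclidean distances among
#' ordination scores (all axes jointly); the R-squared is reported as the
#' percentage of community structure represented.  Significance comes from a
#' permutation test: sample labels of the response matrix are shuffled
#' (simultaneous row/column permutation) `n_perm` times and
#' `p = (1 + #\{R2_perm >= R2_obs\}) / (1 + n_perm)`.
#'
#' This is a matrix regression in the Mantel family; with a single predictor
#' matrix it reduces to the squared Mantel correlation, and additional
#' predictor matrices can be supplied for the partial/multiple variant.
#'
#' @param ord an `nmds_ord` (or any object with `scores` and `labels`), or a
#'   predictor distance matrix.
#' @param D_community labelled community distance matrix (the response).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param extra_predictors optional list of additional labelled distance
#'   matrices entered as covariates.
#' @return list with `r_squared`, `r_squared_pct`, `p_value`, `n_perm`.
#' @export
ordination_fit <- function(ord, D_community, n_perm = 1000, seed = 1L,
                           extra_predictors = list()) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(ord, "nmds_ord") ||
      (is.list(ord) && !is.matrix(ord) && !is.null(ord$scores))) {
    D_pred <- euclidean_distances(ord$scores, labels = ord$labels)
  } else {
    D_pred <- as.matrix(ord)
  }
  validate_distance_matrix(D_pred, tol = 1e-8)
  validate_distance_matrix(D_community, tol = 1e-8)
  if (!setequal(rownames(D_pred), rownames(D_community)))
    stop("ordination and community matrices carry different labels")
  D_pred <- D_pred[rownames(D_community), rownames(D_community)]
  preds <- c(list(D_pred), lapply(extra_predictors, function(M)
    as.matrix(M)[rownames(D_community), rownames(D_community)]))

  X <- cbind(1, do.call(cbind, lapply(preds, lower_triangle)))
  n <- nrow(D_community)
  r2_of <- function(Dresp) {
    yv <- lower_triangle(Dresp)
    fit <- stats::lm.fit(X, yv)
    1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  }
  r2_obs <- r2_of(D_community)
  set.seed(stage_seed(seed, "mantel"))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    if (r2_of(D_community[idx, idx]) >= r2_obs) exceed <- exceed + 1L
  }
  list(r_squared = r2_obs, r_squared_pct = 100 * r2_obs,
       p_value = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm))
}
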