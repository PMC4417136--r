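#' Ordinary least squares fit for eigenvector-regression models
#'
#' Fits `y ~ 1 + design` by OLS and records everything the modelling layer
#' needs: coefficients with t-tests, Gaussian log-likelihood, R-squared,
#' adjusted R-squared (`1 - (1 - R2) * (n - 1) / (n - p - 1)`), residual
#' degrees of freedom and per-predictor variance inflation factors.  The
#' design may mix numeric columns and factors; a rank-deficient design is an
#' error naming the aliased columns.
#'
#' @param y numeric response (e.g. an ordination axis).
#' @param design data frame (or numeric matrix) of predictors; `NULL` or
#'   zero columns fits the intercept-only model.
#' @param class_label tag naming the predictor class (`"species"`,
#'   `"chemistry"`, ...).
#' @return an object of class `pvr_ols`.
#' @export
fit_ols <- function(y, design = NULL, class_label = "model") {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(design) || NCOL(design) == 0L) {
    df <- data.frame(.y = y)
    fml <- .y ~ 1
  } else {
    design <- as.data.frame(design, check.names = FALSE)
    if (nrow(design) != n) stop("design and response lengths differ")
    df <- data.frame(.y = y, design, check.names = FALSE)
    fml <- stats::as.formula(paste(".y ~",
      paste(sprintf("`%s`", names(design)), collapse = " + ")))
  }
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  p <- length(stats::coef(fit)) - 1L
  if (n <= p + 1L) stop("need n > p + 1 observations")
  sm <- summary(fit)
  r2 <- sm$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f_p <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
              lower.tail = FALSE)
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]
  vifs <- if (ncol(X) >= 2) vif(X) else
    stats::setNames(rep(1, ncol(X)), colnames(X))
  structure(list(fit = fit, class_label = class_label,
                 design_labels = if (is.null(design)) character(0)
                                 else names(design),
                 coefficients = stats::coef(fit),
                 coef_table = sm$coefficients,
                 n = n, p = p, df_residual = fit$df.residual,
                 rss = sum(stats::residuals(fit)^2),
                 log_lik = as.numeric(stats::logLik(fit)),
                 r_squared = r2, adj_r_squared = adj,
                 f_p_value = unname(f_p),
                 sigma = sm$sigma, vif = vifs),
            class = "pvr_ols")
}

#' @export
print.pvr_ols <- function(x, ...) {
  cat(sprintf("pvr_ols [%s]: n = %d, p = %d, R2 = %.3f, adj R2 = %.3f, logLik = %.2f\n",
              x$class_label, x$n, x$p, x$r_squared, x$adj_r_squared,
              x$log_lik))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing column `j` on
#' all other columns (with intercept).  Perfect collinearity yields `Inf`
#' rather than an error.
#'
#' @param X numeric matrix with at least two columns.
#' @return named numeric vector of VIFs (all `>= 1`, possibly `Inf`).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least two columns")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(pmax(out, 1), colnames(X))
}

#' Likelihood-ratio test between nested OLS fits
#'
#' The statistic `2 * (logLik(full) - logLik(reduced))` is referred, by
#' default, to a chi-squared distribution with degrees of freedom equal to
#' the difference in regression-parameter count.  With `exact = TRUE` the
#' same likelihood-ratio statistic is referred to its exact null
#' distribution under the Gaussian linear model — a monotone transform of
#' the partial F statistic — which keeps the test at its nominal level in
#' finite samples (the chi-squared asymptote over-rejects slightly when the
#' dropped class is large relative to n).  The reduced design must be a
#' subset of the full design's columns (non-nested pairs are an error).
#'
#' @param full,reduced `pvr_ols` fits on the same response.
#' @param exact use the exact partial-F reference instead of the
#'   chi-squared asymptote.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt_drop_class <- function(full, reduced, exact = FALSE) {
  stopifnot(inherits(full, "pvr_ols"), inherits(reduced, "pvr_ols"))
  if (full$n != reduced$n)
    stop("fits use different numbers of observations")
  if (!all(reduced$design_labels %in% full$design_labels))
    stop("designs are not nested: reduced columns ",
         paste(setdiff(reduced$design_labels, full$design_labels),
               collapse = ", "), " absent from full design")
  df <- full$p - reduced$p
  if (df < 0) stop("designs are not nested: reduced has more parameters")
  stat <- max(0, 2 * (full$log_lik - reduced$log_lik))
  p <- if (df == 0) 1
  else if (exact) {
    fstat <- ((reduced$rss - full$rss) / df) / (full$rss / full$df_residual)
    stats::pf(fstat, df, full$df_residual, lower.tail = FALSE)
  } else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}
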