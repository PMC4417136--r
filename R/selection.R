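#' Retain significant phylogenetic eigenvectors
#'
#' Fits the joint model of the response on all screened phylogenetic
#' eigenvectors (default: first seven) plus the spatial eigenvectors, and
#' keeps the phylogenetic columns whose coefficient t-test satisfies
#' `p < alpha`.  An empty retained set is legal: it means no evidence of
#' phylogenetic structure, and downstream the phylogeny class then gets
#' adjusted R-squared 0 and p-value 1 by convention.
#'
#' @param y numeric response.
#' @param phylo_evs sample-level phylogenetic `eigenvector_set` (or matrix).
#' @param spatial_evs sample-level spatial `eigenvector_set` (or matrix).
#' @param alpha retention significance level.
#' @return integer vector of retained phylogenetic column indices (possibly
#'   empty), with the per-coefficient p-values as the `p_values` attribute.
#' @export
retain_significant_phylo <- function(y, phylo_evs, spatial_evs,
                                     alpha = 0.05) {
  P <- ev_matrix(phylo_evs, "phy")
  S <- ev_matrix(spatial_evs, "spa")
  design <- as.data.frame(cbind(P, S), check.names = FALSE)
  fit <- fit_ols(y, design, class_label = "phylo+space screen")
  pv <- fit$coef_table[-1, "Pr(>|t|)"]
  phylo_p <- pv[seq_len(ncol(P))]
  retained <- which(phylo_p < alpha)
  names(retained) <- NULL
  attr(retained, "p_values") <- unname(phylo_p)
  retained
}

ev_matrix <- function(evs, prefix) {
  M <- if (inherits(evs, "eigenvector_set")) evs$vectors else as.matrix(evs)
  colnames(M) <- paste0(prefix, "_", seq_len(ncol(M)))
  M
}

#' AIC-stepwise selection of soil-chemistry predictors
#'
#' Starting from the model with all ten standardised chemistry variables,
#' runs bidirectional stepwise search minimising AIC, then applies the
#' second filter: repeatedly drop the term with the largest coefficient
#' p-value at or above `alpha`, refitting after each drop, until every
#' remaining term is significant.  Deterministic; ties in the search are
#' broken by fixed column order.
#'
#' @param y numeric response.
#' @param chemistry numeric matrix/data frame of standardised (z-score)
#'   chemistry columns.
#' @param alpha significance level of the post-AIC pruning.
#' @return character vector of selected column names (possibly empty).
#' @export
step_aic_chemistry <- function(y, chemistry, alpha = 0.05) {
  chem <- as.data.frame(chemistry, check.names = FALSE)
  sds <- vapply(chem, stats::sd, numeric(1))
  means <- vapply(chem, mean, numeric(1))
  if (any(abs(means) > 1e-6) || any(abs(sds - 1) > 1e-6))
    stop("chemistry must be standardised to z-scores before selection")
  df <- data.frame(.y = y, chem, check.names = FALSE)
  full <- stats::lm(stats::as.formula(paste(".y ~",
    paste(sprintf("`%s`", names(chem)), collapse = " + "))), data = df)
  if (anyNA(stats::coef(full)))
    stop("rank-deficient chemistry design; aliased: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  stepped <- MASS::stepAIC(full, direction = "both", trace = 0,
                           scope = list(lower = .y ~ 1, upper = full))
  selected <- attr(stats::terms(stepped), "term.labels")
  selected <- gsub("`", "", selected)
  ## second filter: prune terms with p >= alpha, worst first, refit each time
  repeat {
    if (!length(selected)) break
    fit <- fit_ols(y, chem[, selected, drop = FALSE], "chemistry")
    pv <- fit$coef_table[-1, "Pr(>|t|)"]
    if (all(pv < alpha)) break
    selected <- selected[-which.max(pv)]
  }
  selected
}
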