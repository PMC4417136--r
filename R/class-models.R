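#' Per-class linear models for one ordination axis
#'
#' For a single ordination axis, each predictor class is handled by exactly
#' one model at a time, so that phylogeny and chemistry (strongly collinear
#' in field data) never share a tested model.
#'
#' Two quantities are reported per class, computed the way each is best
#' defined:
#'
#' *Class significance* is assessed on the screened, pre-selection predictor
#' sets, mirroring the order of operations of fitting a full joint model
#' first and dropping whole classes from it:
#'
#' * `species` / `genus`: categorical factor, overall F-test;
#' * `chemistry`: all ten standardised soil variables against the
#'   intercept-only model;
#' * `space` and `phylogeny`: whole-class drops from the joint model of all
#'   screened phylogenetic eigenvectors plus the spatial eigenvectors.
#'
#' Class drops use the likelihood-ratio statistic with its exact
#' finite-sample reference ([lrt_drop_class()] with `exact = TRUE`);
#' testing *after* subset selection would be anti-conservative, so the
#' selected subsets are never themselves the basis of the class p-value.
#'
#' *Explanatory power* (adjusted R-squared) is reported from the
#' parsimonious single-class models: the AIC-selected,
#' significance-pruned chemistry subset ([step_aic_chemistry()]), the
#' retained phylogenetic eigenvectors ([retain_significant_phylo()]), the
#' spatial eigenvectors, and the species/genus factors.  An empty
#' selected/retained set contributes adjusted R-squared 0 (no evidence for
#' the class).
#'
#' @param y numeric response (one ordination axis, in `frame` sample order).
#' @param frame a [sample_frame].
#' @param phylo_evs,spatial_evs sample-level eigenvector sets.
#' @param alpha significance level used inside the selection steps.
#' @param axis_label tag recorded in the output.
#' @return data frame with one row per class: `axis`, `class`, `adj_r2`,
#'   `p_value`, `n_predictors`, `max_vif`; the selected chemistry names and
#'   retained phylogenetic indices are attached as attributes
#'   `chemistry_selected` and `phylo_retained`.
#' @export
class_models <- function(y, frame, phylo_evs, spatial_evs, alpha = 0.05,
                         axis_label = "axis1") {
  null_fit <- fit_ols(y, NULL, "null")
  chem_z <- standardize_chemistry(frame)
  P <- ev_matrix(phylo_evs, "phy")
  S <- ev_matrix(spatial_evs, "spa")
  joint <- fit_ols(y, as.data.frame(cbind(P, S), check.names = FALSE),
                   "phylo+space")
  phylo_only <- fit_ols(y, as.data.frame(P, check.names = FALSE),
                        "phylo screen")
  space_fit <- fit_ols(y, as.data.frame(S, check.names = FALSE), "space")
  chem_full <- fit_ols(y, as.data.frame(chem_z, check.names = FALSE),
                       "chemistry screen")

  row_of <- function(class, fit, p) {
    data.frame(axis = axis_label, class = class,
               adj_r2 = if (is.null(fit)) 0 else fit$adj_r_squared,
               p_value = p,
               n_predictors = if (is.null(fit)) 0L else fit$p,
               max_vif = if (is.null(fit) || !length(fit$vif)) NA_real_
                         else max(fit$vif),
               stringsAsFactors = FALSE)
  }

  ## (a) species factor: overall F-test
  sp_fit <- fit_ols(y, data.frame(species = factor(frame$species)), "species")
  out <- row_of("species", sp_fit, sp_fit$f_p_value)

  ## (b) chemistry: screened test, AIC-selected subset for adjusted R2
  chem_p <- lrt_drop_class(chem_full, null_fit, exact = TRUE)$p_value
  chem_sel <- step_aic_chemistry(y, chem_z, alpha = alpha)
  chem_fit <- if (length(chem_sel))
    fit_ols(y, as.data.frame(chem_z[, chem_sel, drop = FALSE],
                             check.names = FALSE), "chemistry") else NULL
  out <- rbind(out, row_of("chemistry", chem_fit, chem_p))

  ## (c) space: whole-class drop from the joint phylo+space model
  space_p <- lrt_drop_class(joint, phylo_only, exact = TRUE)$p_value
  out <- rbind(out, row_of("space", space_fit, space_p))

  ## (d) phylogeny: whole-class drop from the joint model; retained subset
  ##     for adjusted R2
  phylo_p <- lrt_drop_class(joint, space_fit, exact = TRUE)$p_value
  retained <- retain_significant_phylo(y, phylo_evs, spatial_evs, alpha)
  phy_fit <- if (length(retained))
    fit_ols(y, as.data.frame(P[, retained, drop = FALSE],
                             check.names = FALSE), "phylogeny") else NULL
  out <- rbind(out, row_of("phylogeny", phy_fit, phylo_p))

  ## (e) genus factor (congener-design variant)
  gen_fit <- fit_ols(y, data.frame(genus = factor(frame$genus)), "genus")
  out <- rbind(out, row_of("genus", gen_fit, gen_fit$f_p_value))

  rownames(out) <- NULL
  attr(out, "chemistry_selected") <- chem_sel
  attr(out, "phylo_retained") <- as.integer(retained)
  out
}

#' Format a per-axis results grid for display
#'
#' Renders the (axis x class) grid with the display conventions of the
#' field: adjusted R-squared below 0.01 is shown as `<0.01`, and classes
#' significant at `alpha` are marked with an asterisk.
#'
#' @param results data frame as stacked by [class_models()] over axes.
#' @param alpha significance marking level.
#' @return character matrix (classes x axes) of formatted cells.
#' @export
format_results_table <- function(results, alpha = 0.05) {
  axes <- unique(results$axis)
  classes <- unique(results$class)
  out <- matrix("", nrow = length(classes), ncol = length(axes),
                dimnames = list(classes, axes))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    r2txt <- if (r$adj_r2 < 0.01) "<0.01" else sprintf("%.2f", r$adj_r2)
    ptxt <- if (r$p_value < 0.001) "<0.001"
            else if (r$p_value < 0.01) "<0.01"
            else sprintf("%.2f", r$p_value)
    star <- if (r$p_value < alpha) "*" else ""
    out[r$class, r$axis] <- sprintf("%s (P=%s)%s", r2txt, ptxt, star)
  }
  out
}

#' @rdname format_results_table
#' @param path output TSV path.
#' @export
write_results_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
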