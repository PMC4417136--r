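#' Principal coordinates analysis by Gower double-centering
#'
#' Computes `G = -1/2 * C %*% (D*D) %*% C` with `C = I - 11'/n`, takes the
#' eigendecomposition of `G`, and returns the eigenvectors scaled by the
#' square roots of their (positive) eigenvalues.  Negative eigenvalues —
#' legal for non-Euclidean dissimilarities such as Bray-Curtis — are reported
#' in `all_eigenvalues` but their axes are discarded without Lingoes/Cailliez
#' correction, following eigenvector-regression practice of using leading
#' positive axes only.
#'
#' Column signs are pinned (largest-magnitude element positive) so the
#' decomposition is reproducible.
#'
#' @param D labelled symmetric distance matrix.
#' @param source label recorded on the result (`"phylogenetic"`, `"spatial"`,
#'   or any other provenance tag).
#' @param zero_tol eigenvalues below `zero_tol * max(eigenvalue)` are treated
#'   as null and dropped.
#' @return an object of class `eigenvector_set`: list with `labels`,
#'   `vectors` (columns ordered by descending eigenvalue, scaled by
#'   `sqrt(eigenvalue)`), `eigenvalues` (the retained, positive ones),
#'   `all_eigenvalues`, `source`.
#' @export
pcoa <- function(D, source = "generic", zero_tol = 1e-8) {
  validate_distance_matrix(D, tol = 1e-8)
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  lambda <- e$values
  keep <- lambda > zero_tol * max(abs(lambda))
  vectors <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda[keep]), sum(keep))
  vectors <- pin_column_signs(vectors)
  dimnames(vectors) <- list(rownames(D), paste0("EV", seq_len(sum(keep))))
  structure(list(labels = rownames(D), vectors = vectors,
                 eigenvalues = lambda[keep], all_eigenvalues = lambda,
                 source = source),
            class = "eigenvector_set")
}

gower_center <- function(D) {
  n <- nrow(D)
  D2 <- D * D
  rm_ <- rowMeans(D2)
  gm <- mean(D2)
  -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
}

#' @export
print.eigenvector_set <- function(x, ...) {
  cat(sprintf("eigenvector_set (%s): %d labels x %d axes; leading eigenvalues: %s\n",
              x$source, length(x$labels), ncol(x$vectors),
              paste(signif(utils::head(x$eigenvalues, 4), 3), collapse = ", ")))
  invisible(x)
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the tree path between every pair of tips.
#'
#' @param tree a `phylo` object with branch lengths on all edges.
#' @return labelled symmetric distance matrix over the tip labels.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  D <- ape::cophenetic.phylo(tree)
  D <- D[tree$tip.label, tree$tip.label]
  validate_distance_matrix(D, tol = 1e-8)
  D
}

#' Automated scree break in an eigenvalue sequence
#'
#' Returns the index after the largest successive drop ratio
#' `lambda[i] / lambda[i + 1]` among the positive eigenvalues — an automated
#' stand-in for choosing the number of axes by eye from a scree plot.  If all
#' positive eigenvalues are equal (no break) the full count is returned.
#'
#' @param eigenvalues numeric vector sorted in descending order.
#' @return integer: number of eigenvalues before the break.
#' @export
scree_break <- function(eigenvalues) {
  if (length(eigenvalues) < 2)
    stop("need at least two eigenvalues")
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be sorted in descending order")
  pos <- eigenvalues[eigenvalues > 0]
  if (length(pos) < 2) return(length(pos))
  ratios <- pos[-length(pos)] / pos[-1]
  if (max(ratios) <= 1 + 1e-12) return(length(pos))
  which.max(ratios)
}
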