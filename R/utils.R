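#' @keywords internal
"_PACKAGE"

## Stage-seed fan-out: one master seed, fixed offsets per stage, so that
## replaying a single stage (or switching one signal weight off) leaves every
## other random stream untouched.  Offsets are part of the package contract.
.stage_seed_offsets <- c(
  tree = 101L, sites = 211L, chemistry = 307L,
  species_effects = 401L, chem_loadings = 409L, space_fields = 419L,
  phylo_traits = 421L, noise = 431L, subsample = 433L,
  nmds = 503L, mantel = 509L, benchmark = 601L
)

stage_seed <- function(seed, stage) {
  offset <- .stage_seed_offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 2048L + offset
}

#' Validate a labelled distance matrix
#'
#' Checks that `D` is a square numeric matrix with matching row/column labels,
#' symmetric to `tol`, zero on the diagonal and non-negative off it.  Used as
#' the common currency between the ordination, eigenvector and modelling
#' stages.
#'
#' @param D square numeric matrix with dimnames.
#' @param tol symmetry tolerance.
#' @param max_one if `TRUE` additionally require all entries `<= 1 + tol`
#'   (Bray-Curtis range).
#' @return `D`, invisibly, after validation.
#' @export
validate_distance_matrix <- function(D, tol = 1e-12, max_one = FALSE) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("distance matrix must be a square numeric matrix")
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D)))
    stop("distance matrix must carry identical row and column labels")
  if (max(abs(D - t(D))) > tol)
    stop("distance matrix is not symmetric (tolerance ", tol, ")")
  if (any(abs(diag(D)) > tol))
    stop("distance matrix diagonal must be zero")
  if (any(D < -tol))
    stop("distance matrix entries must be non-negative")
  if (max_one && any(D > 1 + tol))
    stop("distance entries exceed 1")
  invisible(D)
}

## Lower-triangle unfold in a fixed (column-major) order.
lower_triangle <- function(D) D[lower.tri(D)]

## Euclidean distance matrix of the rows of a coordinate matrix.
euclidean_distances <- function(X, labels = rownames(X)) {
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- list(labels, labels)
  D
}

## Pin eigenvector/score column signs: largest-magnitude element positive.
pin_column_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
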