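#' Three-set variance partitioning on adjusted R-squared
#'
#' Partitions the variance of a response (an ordination axis) among three
#' predictor sets — phylogenetic eigenvectors, selected soil-chemistry
#' variables and spatial eigenvectors — into unique, pairwise-shared and
#' three-way-shared fractions plus a residual.  With `A_S` the adjusted
#' R-squared of the OLS model on the union of the sets in `S`:
#'
#' * unique fractions: `a = A_123 - A_23`, `b = A_123 - A_13`,
#'   `c = A_123 - A_12`;
#' * pairwise shared: `ab = A_123 - A_3 - a - b` (likewise `ac`, `bc`);
#' * three-way shared: `abc = A_123 - a - b - c - ab - ac - bc`;
#' * residual: `1 - A_123`.
#'
#' The eight fractions sum to 1 by construction.  Shared fractions may be
#' negative (a well-known property of adjusted-R-squared partitioning) and
#' are reported, not clipped.  An empty predictor set is treated as
#' contributing no columns, so every fraction unique to it is 0.
#'
#' @param y numeric response.
#' @param X_phylo,X_chem,X_space predictor matrices/data frames (possibly
#'   zero-column) for the phylogeny, chemistry and space sets.
#' @param set_names names used in the report.
#' @param use_adjusted partition adjusted R-squared (default) or raw
#'   R-squared; the raw version satisfies the inclusion-exclusion identity
#'   exactly for nested designs and is kept for checking.
#' @return object of class `varpart3`: list with `fractions` (named numeric,
#'   `a`, `b`, `c`, `ab`, `ac`, `bc`, `abc`, `residual`), `adj_r2` of the
#'   seven subset models, and `set_names`.
#' @export
partition3 <- function(y, X_phylo, X_chem, X_space,
                       set_names = c("phylogeny", "chemistry", "space"),
                       use_adjusted = TRUE) {
  sets <- list(as_design(X_phylo), as_design(X_chem), as_design(X_space))
  subsets <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  labels <- vapply(subsets, function(s)
    paste(set_names[s], collapse = "+"), "")
  A <- vapply(seq_along(subsets), function(i) {
    cols <- do.call(cbind, sets[subsets[[i]]])
    if (is.null(cols) || ncol(cols) == 0) return(0)
    fit <- tryCatch(
      fit_ols(y, as.data.frame(cols, check.names = FALSE), labels[i]),
      error = function(e) stop("subset model '", labels[i], "' failed: ",
                               conditionMessage(e)))
    if (use_adjusted) fit$adj_r_squared else fit$r_squared
  }, numeric(1))
  names(A) <- c("1", "2", "3", "12", "13", "23", "123")

  a <- A[["123"]] - A[["23"]]
  b <- A[["123"]] - A[["13"]]
  c_ <- A[["123"]] - A[["12"]]
  ab <- A[["123"]] - A[["3"]] - a - b
  ac <- A[["123"]] - A[["2"]] - a - c_
  bc <- A[["123"]] - A[["1"]] - b - c_
  abc <- A[["123"]] - a - b - c_ - ab - ac - bc
  fractions <- c(a = a, b = b, c = c_, ab = ab, ac = ac, bc = bc, abc = abc,
                 residual = 1 - A[["123"]])
  stopifnot(abs(sum(fractions) - 1) < 1e-10)
  structure(list(fractions = fractions, adj_r2 = A, set_names = set_names),
            class = "varpart3")
}

as_design <- function(X) {
  if (is.null(X)) return(NULL)
  X <- as.matrix(X)
  if (ncol(X) == 0) return(NULL)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' @export
print.varpart3 <- function(x, ...) {
  f <- x$fractions
  s <- x$set_names
  cat("Three-set variance partition (adjusted R-squared fractions)\n")
  cat(sprintf("  [%s] unique:            %7.4f\n", s[1], f["a"]))
  cat(sprintf("  [%s] unique:            %7.4f\n", s[2], f["b"]))
  cat(sprintf("  [%s] unique:            %7.4f\n", s[3], f["c"]))
  cat(sprintf("  shared %s & %s:     %7.4f\n", s[1], s[2], f["ab"]))
  cat(sprintf("  shared %s & %s:         %7.4f\n", s[1], s[3], f["ac"]))
  cat(sprintf("  shared %s & %s:         %7.4f\n", s[2], s[3], f["bc"]))
  cat(sprintf("  shared all three:            %7.4f\n", f["abc"]))
  cat(sprintf("  residual:                    %7.4f\n", f["residual"]))
  neg <- names(f)[f < 0]
  if (length(neg))
    cat("  note: negative shared/unique fraction(s): ",
        paste(neg, collapse = ", "),
        " (legal for adjusted R-squared)\n", sep = "")
  invisible(x)
}

#' Summarise variance partitions across axes
#'
#' @param partitions named list of `varpart3` objects (one per axis).
#' @return data frame with one row per axis and one column per fraction,
#'   plus a `sum` column (always 1 up to rounding).
#' @export
partition_report <- function(partitions) {
  if (!length(partitions)) stop("need at least one partition")
  rows <- lapply(names(partitions), function(nm) {
    f <- partitions[[nm]]$fractions
    data.frame(axis = nm, t(f), sum = sum(f), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
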