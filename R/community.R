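#' Community-matrix preprocessing
#'
#' `filter_rare()` removes rare OTUs at the technical-subsample level: an OTU
#' is retained iff the fraction of subsamples in which it is present
#' (abundance > 0) is strictly greater than `threshold`, so with the default
#' 0.07 an OTU present in at most 7% of subsamples is removed.
#' `average_subsamples()` then collapses technical subsamples to one row per
#' soil sample by the cellwise arithmetic mean.  The order matters and is
#' fixed: filtering is defined on subsamples and happens first.
#'
#' @param table an [otu_table].
#' @param threshold presence proportion in `[0, 1]`.
#' @return an [otu_table].
#' @export
filter_rare <- function(table, threshold = 0.07) {
  stopifnot(inherits(table, "otu_table"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  presence <- colMeans(table$values > 0)
  keep <- presence > threshold
  if (!any(keep))
    stop("rare-taxon filter removed every OTU (threshold ", threshold, ")")
  otu_table(table$values[, keep, drop = FALSE],
            table$sample_id, table$subsample_id)
}

#' @rdname filter_rare
#' @export
average_subsamples <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  samples <- unique(table$sample_id)
  vals <- rowsum(table$values, group = table$sample_id, reorder = FALSE)
  counts <- as.vector(table(factor(table$sample_id, levels = samples)))
  vals <- vals[samples, , drop = FALSE] / counts
  otu_table(vals, samples, samples)
}

#' Bray-Curtis dissimilarity matrix
#'
#' For abundance rows x and y, the dissimilarity is
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`, bounded in `[0, 1]`.
#' Expects one row per sample (apply [average_subsamples()] first); any
#' all-zero row makes the distance undefined and is an error.
#'
#' @param table an [otu_table] with one row per sample.
#' @return a labelled symmetric distance matrix.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  X <- table$values
  if (anyDuplicated(table$sample_id))
    stop("bray_curtis expects one row per sample; average subsamples first")
  rs <- rowSums(X)
  if (any(rs == 0))
    stop("all-zero abundance row(s): ",
         paste(table$sample_id[rs == 0], collapse = ", "),
         " (Bray-Curtis undefined)")
  n <- nrow(X)
  ## sum of pairwise minima via the identity min(a,b) = (a + b - |a - b|)/2
  abs_diff_sum <- as.matrix(stats::dist(X, method = "manhattan"))
  sum_pairs <- outer(rs, rs, `+`)
  min_sum <- (sum_pairs - abs_diff_sum) / 2
  D <- 1 - 2 * min_sum / sum_pairs
  diag(D) <- 0
  dimnames(D) <- list(table$sample_id, table$sample_id)
  validate_distance_matrix(D, tol = 1e-9, max_one = TRUE)
  D
}
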