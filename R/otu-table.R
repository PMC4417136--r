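#' OTU abundance tables
#'
#' An `otu_table` holds a subsamples-by-OTU matrix of non-negative abundances
#' (TRFLP peak-area style), together with the mapping of technical subsamples
#' to soil samples.  Each soil sample has one or more subsamples; OTU
#' identifiers are the fragment-size classes.
#'
#' @param values numeric matrix, rows = subsamples, columns = OTUs;
#'   non-negative, no missing cells.
#' @param sample_id character vector, one entry per row of `values`.
#' @param subsample_id character vector, one entry per row; the pair
#'   (`sample_id`, `subsample_id`) must be unique.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(values, sample_id, subsample_id) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("OTU table requires OTU identifiers as column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (length(sample_id) != nrow(values) || length(subsample_id) != nrow(values))
    stop("sample_id and subsample_id must have one entry per row")
  if (anyNA(values))
    stop("OTU table contains missing cells")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at subsample '%s', OTU '%s'",
                 subsample_id[idx[1L]], colnames(values)[idx[2L]]))
  }
  key <- paste(sample_id, subsample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (sample, subsample) pair: ('%s', '%s')",
                 sample_id[d], subsample_id[d]))
  }
  rownames(values) <- NULL
  structure(
    list(values = values,
         sample_id = as.character(sample_id),
         subsample_id = as.character(subsample_id)),
    class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d subsamples (%d samples) x %d OTUs\n",
              nrow(x$values), length(unique(x$sample_id)), ncol(x$values)))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
n_samples <- function(x) length(unique(x$sample_id))

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x$values)

#' Read / write an OTU table
#'
#' The file format is tab-separated with a header row: the first two columns
#' are `sample_id` and `subsample_id`, the remaining columns are OTU
#' abundances named by OTU identifier.  Malformed input (negative values,
#' duplicated subsample keys, missing cells) is rejected, never coerced.
#'
#' @param path file path.
#' @return `read_otu_table()` returns an [otu_table]; `write_otu_table()`
#'   returns `path` invisibly.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 3L ||
      !identical(names(df)[1:2], c("sample_id", "subsample_id")))
    stop("OTU table must start with columns 'sample_id' and 'subsample_id'")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing abundance at row %d, OTU '%s' in %s",
                 idx[1L], colnames(vals)[idx[2L]], path))
  }
  otu_table(vals, df$sample_id, df$subsample_id)
}

#' @rdname read_otu_table
#' @param table an [otu_table].
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_id,
                   subsample_id = table$subsample_id,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
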