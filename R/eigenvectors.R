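#' Phylogenetic eigenvector predictors (PVR front end)
#'
#' Decomposes the species-level patristic distance matrix with [pcoa()],
#' keeps the first `n_screen` axes (the screened candidate set; default 7),
#' and broadcasts each species' eigenvector values to all of its samples, so
#' that two samples of the same species carry identical rows.
#'
#' @param tree species phylogeny (`phylo`), tips covering all species in
#'   `frame`.
#' @param frame a [sample_frame] (only `sample_id` and `species` are used).
#' @param n_screen number of leading eigenvectors screened; must be at most
#'   `n_tips - 1`.
#' @return sample-level `eigenvector_set` (source `"phylogenetic"`), rows in
#'   the order of `frame`.
#' @export
phylo_eigenvectors <- function(tree, frame, n_screen = 7) {
  missing_sp <- setdiff(unique(frame$species), tree$tip.label)
  if (length(missing_sp))
    stop("species absent from tree: ", paste(missing_sp, collapse = ", "))
  if (n_screen > length(tree$tip.label) - 1)
    stop("n_screen must be <= n_tips - 1")
  dec <- pcoa(patristic_distances(tree), source = "phylogenetic")
  if (ncol(dec$vectors) < n_screen)
    stop("only ", ncol(dec$vectors), " positive axes available")
  sp_vectors <- dec$vectors[, seq_len(n_screen), drop = FALSE]
  vectors <- sp_vectors[match(frame$species, rownames(sp_vectors)), ,
                        drop = FALSE]
  rownames(vectors) <- frame$sample_id
  structure(list(labels = frame$sample_id, vectors = vectors,
                 eigenvalues = dec$eigenvalues[seq_len(n_screen)],
                 all_eigenvalues = dec$all_eigenvalues,
                 source = "phylogenetic"),
            class = "eigenvector_set")
}

#' Spatial eigenvector predictors
#'
#' Principal coordinates of the pairwise Euclidean distance matrix of the
#' sample coordinates; the first `n_keep` axes (default 2) serve as spatial
#' predictors.  For planar coordinates these axes span the same plane as the
#' centred coordinates themselves.
#'
#' @param frame a [sample_frame] with `x`, `y` in metres.
#' @param n_keep number of leading axes kept.
#' @return sample-level `eigenvector_set` (source `"spatial"`).
#' @export
spatial_eigenvectors <- function(frame, n_keep = 2) {
  if (n_keep < 1) stop("n_keep must be >= 1")
  if (!all(c("x", "y") %in% names(frame)))
    stop("frame must carry planar coordinates x, y")
  D <- euclidean_distances(cbind(frame$x, frame$y), labels = frame$sample_id)
  dec <- pcoa(D, source = "spatial")
  if (ncol(dec$vectors) < n_keep)
    stop("only ", ncol(dec$vectors),
         " positive spatial eigenvalues; cannot keep ", n_keep,
         " (are the sites collinear?)")
  vectors <- dec$vectors[, seq_len(n_keep), drop = FALSE]
  structure(list(labels = frame$sample_id, vectors = vectors,
                 eigenvalues = dec$eigenvalues[seq_len(n_keep)],
                 all_eigenvalues = dec$all_eigenvalues, source = "spatial"),
            class = "eigenvector_set")
}

#' Write an eigenvector set as TSV
#'
#' Eigenvalues go into `#`-prefixed header comment lines, followed by a
#' labelled table of the eigenvector scores.
#'
#' @param evs an `eigenvector_set`.
#' @param path output path.
#' @export
write_eigenvector_set <- function(evs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", evs$source), con)
  writeLines(sprintf("# eigenvalues: %s",
                     paste(format(evs$eigenvalues, digits = 15),
                           collapse = "\t")), con)
  df <- data.frame(label = evs$labels, evs$vectors, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
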