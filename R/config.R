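#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline with its default.  Defaults encode
#' the package's reference analysis settings: rare taxa are OTUs present in at most 7% of
#' subsamples; ordination dimensionality is the smallest k with Kruskal
#' stress below 0.20; NMDS uses 20 random starts; the ordination-fit
#' permutation test uses 1000 permutations; seven phylogenetic eigenvectors
#' are screened and two spatial eigenvectors used; eigenvectors are retained
#' at P < 0.05.
#'
#' @param rare_threshold presence-proportion threshold; OTUs present in a
#'   fraction of subsamples less than or equal to this are removed.
#' @param k_max largest ordination dimensionality scanned.
#' @param stress_ceiling acceptance ceiling for Kruskal stress-1.
#' @param n_starts number of NMDS starts (one PCoA start plus random starts).
#' @param n_perm permutations for the ordination-fit test.
#' @param n_phylo_screen phylogenetic eigenvectors entered into retention.
#' @param n_spatial spatial eigenvectors used.
#' @param alpha significance level for eigenvector retention and for the
#'   post-AIC pruning of chemistry terms.
#' @param seed master random seed; all stage seeds are derived from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(rare_threshold = 0.07, k_max = 6, stress_ceiling = 0.20,
                       n_starts = 20, n_perm = 1000, n_phylo_screen = 7,
                       n_spatial = 2, alpha = 0.05, seed = 1L) {
  cfg <- list(rare_threshold = rare_threshold, k_max = as.integer(k_max),
              stress_ceiling = stress_ceiling, n_starts = as.integer(n_starts),
              n_perm = as.integer(n_perm),
              n_phylo_screen = as.integer(n_phylo_screen),
              n_spatial = as.integer(n_spatial), alpha = alpha,
              seed = as.integer(seed))
  counts <- c("k_max", "n_starts", "n_perm", "n_phylo_screen", "n_spatial")
  if (any(vapply(cfg[counts], function(v) is.na(v) || v < 1L, logical(1))))
    stop("all count parameters must be positive integers")
  if (rare_threshold < 0 || rare_threshold > 1)
    stop("rare_threshold must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (stress_ceiling <= 0)
    stop("stress_ceiling must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path key-value file (`key: value` or `key=value`, one per line,
#'   `#` comments allowed).  Keys mirror the arguments of `run_config()`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, as.list(stats::setNames(vals, keys)))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(unclass(config)),
                     vapply(unclass(config), format, "")), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(unclass(x))) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
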