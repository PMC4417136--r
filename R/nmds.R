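#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimises Kruskal's stress-1,
#' `sqrt(sum((dhat - d)^2) / sum(d^2))`, where `d` are configuration
#' distances and `dhat` are fitted by monotone (isotonic) regression of `d`
#' on the rank order of the input dissimilarities.  Ties are handled by the
#' primary approach: tied dissimilarities may take unequal fitted values.
#' The optimisation alternates a Guttman (SMACOF-style majorisation) update
#' of the configuration with the isotonic re-fit, to convergence (relative
#' stress change below `tol`) or `max_iter` iterations.  One start is the
#' principal-coordinates configuration of `D`; the remaining `n_starts - 1`
#' are random Gaussian configurations.  The best (lowest-stress) solution is
#' kept.
#'
#' The returned scores are identified up to similarity transforms, so they
#' are pinned for reproducibility: centred, rotated to principal axes,
#' scaled to unit root-mean-square, and column signs fixed so each column's
#' largest-magnitude score is positive.
#'
#' @param D labelled symmetric dissimilarity matrix (zero diagonal).
#' @param k number of ordination axes.
#' @param n_starts total number of starts (PCoA start plus random).
#' @param seed integer seed controlling the random starts.
#' @param max_iter,tol convergence controls.
#' @return an object of class `nmds_ord`: list with `labels`, `scores`
#'   (n x k), `k`, `stress`, `n_starts`, `converged`, `best_start`.
#' @export
nmds <- function(D, k, n_starts = 20, seed = 1L, max_iter = 500, tol = 1e-6) {
  validate_distance_matrix(D, tol = 1e-8)
  if (k < 1) stop("k must be >= 1")
  if (n_starts < 1) stop("n_starts must be >= 1")
  n <- nrow(D)
  lt <- lower.tri(D)
  delta <- D[lt]
  denom_pairs <- which(lt, arr.ind = TRUE)

  starts <- vector("list", n_starts)
  starts[[1L]] <- pcoa_start(D, k)
  if (n_starts > 1L) {
    set.seed(stage_seed(seed, "nmds"))
    for (s in 2:n_starts)
      starts[[s]] <- matrix(stats::rnorm(n * k), n, k)
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- nmds_one_start(starts[[s]], delta, lt, n, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best$start <- s
    }
  }

  scores <- align_scores(best$X)
  dimnames(scores) <- list(rownames(D), paste0("MDS", seq_len(k)))
  structure(list(labels = rownames(D), scores = scores, k = as.integer(k),
                 stress = best$stress, n_starts = as.integer(n_starts),
                 converged = best$converged, best_start = best$start),
            class = "nmds_ord")
}

## One SMACOF/isotonic run from a given configuration; returns the best
## configuration seen (majorisation is monotone in the normalised stress but
## we guard by tracking the minimum explicitly).
nmds_one_start <- function(X, delta, lt, n, max_iter, tol) {
  eval_config <- function(X) {
    d <- as.matrix(stats::dist(X))[lt]
    ord <- order(delta, d)           # primary tie approach
    dhat <- numeric(length(d))
    dhat[ord] <- stats::isoreg(d[ord])$yf
    stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
    list(d = d, dhat = dhat, stress = stress)
  }
  ev <- eval_config(X)
  best_X <- X
  best_stress <- ev$stress
  converged <- FALSE
  prev <- ev$stress
  for (it in seq_len(max_iter)) {
    ## Guttman transform toward the current disparities
    ratio <- matrix(0, n, n)
    r <- ifelse(ev$d > 0, ev$dhat / ev$d, 0)
    ratio[lt] <- r
    ratio <- ratio + t(ratio)
    B <- -ratio
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    ev <- eval_config(X)
    if (ev$stress < best_stress) {
      best_stress <- ev$stress
      best_X <- X
    }
    if (abs(prev - ev$stress) < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- ev$stress
  }
  list(X = best_X, stress = best_stress, converged = converged)
}

## Principal-coordinates configuration used as the deterministic start.
pcoa_start <- function(D, k) {
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  pos <- pmax(e$values[seq_len(k)], 0)
  X <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos), k)
  ## guard against zero columns (rank < k): jitter deterministically
  zero <- colSums(X^2) == 0
  if (any(zero))
    X[, zero] <- matrix(sin(seq_len(nrow(X) * sum(zero))),
                        nrow(X), sum(zero)) * 1e-4
  X
}

## Centre, rotate to principal axes, unit RMS, pin signs.
align_scores <- function(X) {
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- X %*% sv$v
  X <- X / sqrt(mean(X^2))
  pin_column_signs(X)
}

#' @export
print.nmds_ord <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, k = %d, stress-1 = %.4f (%s, best start %d of %d)\n",
              length(x$labels), x$k, x$stress,
              if (x$converged) "converged" else "iteration cap reached",
              x$best_start, x$n_starts))
  invisible(x)
}

#' Stress against number of dimensions, and dimension choice
#'
#' `stress_profile()` runs [nmds()] at each `k = 1, ..., k_max` and returns
#' the stress at each dimensionality.  `choose_k()` applies the acceptance
#' rule: the smallest `k` whose stress falls strictly below `ceiling`
#' (default 0.20).  If no scanned `k` achieves the ceiling an error reports
#' the whole profile.
#'
#' @inheritParams nmds
#' @param k_max largest dimensionality scanned (>= 2).
#' @return `stress_profile()`: data frame with columns `k`, `stress`;
#'   `choose_k()`: an integer.
#' @export
stress_profile <- function(D, k_max, n_starts = 20, seed = 1L,
                           max_iter = 500, tol = 1e-6) {
  if (k_max < 2) stop("k_max must be >= 2")
  stress <- vapply(seq_len(k_max), function(k)
    nmds(D, k, n_starts = n_starts, seed = seed + k,
         max_iter = max_iter, tol = tol)$stress, numeric(1))
  data.frame(k = seq_len(k_max), stress = stress)
}

#' @rdname stress_profile
#' @param profile data frame from `stress_profile()`.
#' @param ceiling stress acceptance ceiling.
#' @export
choose_k <- function(profile, ceiling = 0.20) {
  ok <- profile$stress < ceiling
  if (!any(ok))
    stop("no dimensionality reaches stress < ", ceiling, "; profile: ",
         paste(sprintf("k=%d: %.3f", profile$k, profile$stress),
               collapse = ", "))
  profile$k[which(ok)[1L]]
}
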