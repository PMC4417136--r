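#' Signal weights for the synthetic community generator
#'
#' The generator builds per-OTU log-affinities as a weighted sum of four
#' channels — species identity, soil chemistry, spatial location and
#' phylogenetically conserved traits — plus noise.  Each channel is scaled
#' to roughly unit variance, so the weights are comparable: a weight of 1
#' injects about as much log-affinity variance as the iid noise at
#' `noise_sd = 1`.
#'
#' @param w_species,w_chem,w_space,w_phylo non-negative channel weights.
#' @param noise_sd standard deviation of the iid per-sample noise (> 0).
#' @param subsample_sd standard deviation of the technical-subsample noise.
#' @return list of class `signal_weights`.
#' @export
signal_weights <- function(w_species = 1, w_chem = 1, w_space = 1,
                           w_phylo = 1, noise_sd = 1, subsample_sd = 0.5) {
  w <- list(w_species = w_species, w_chem = w_chem, w_space = w_space,
            w_phylo = w_phylo, noise_sd = noise_sd,
            subsample_sd = subsample_sd)
  if (any(unlist(w) < 0)) stop("all weights must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  class(w) <- "signal_weights"
  w
}

#' Synthetic study design specification
#'
#' Defaults mirror the field design: 7 genera x 2 congeneric species x 6
#' collection locations (84 soil samples), 2 technical subsamples per
#' sample, sites of one species at least 100 m apart within a ~5 km extent.
#'
#' @param n_genera,species_per_genus,sites_per_species,subsamples_per_sample
#'   design counts.
#' @param n_otus number of OTUs (TRFLP fragment classes) generated.
#' @param extent side of the square study area, metres.
#' @param min_spacing minimum within-species distance between collection
#'   locations, metres.
#' @param patch_rule `"random"` (species patches placed independently) or
#'   `"phylogenetic"` (congeners share a genus patch centre, making related
#'   species spatially close).
#' @param weights a [signal_weights] object.
#' @param seed master seed; every generator stage derives its own stream
#'   from it, so changing one channel's weight leaves all other draws
#'   unchanged.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_genera = 7, species_per_genus = 2,
                          sites_per_species = 6, subsamples_per_sample = 2,
                          n_otus = 150, extent = 5000, min_spacing = 100,
                          patch_rule = c("random", "phylogenetic"),
                          weights = signal_weights(), seed = 1L) {
  patch_rule <- match.arg(patch_rule)
  spec <- list(n_genera = as.integer(n_genera),
               species_per_genus = as.integer(species_per_genus),
               sites_per_species = as.integer(sites_per_species),
               subsamples_per_sample = as.integer(subsamples_per_sample),
               n_otus = as.integer(n_otus), extent = extent,
               min_spacing = min_spacing, patch_rule = patch_rule,
               weights = weights, seed = as.integer(seed))
  counts <- c("n_genera", "species_per_genus", "sites_per_species",
              "subsamples_per_sample", "n_otus")
  if (any(vapply(spec[counts], function(v) is.na(v) || v < 1L, logical(1))))
    stop("all design counts must be positive integers")
  if (min_spacing <= 0) stop("min_spacing must be > 0")
  if (extent <= 0) stop("extent must be > 0")
  if (!inherits(weights, "signal_weights")) stop("weights must be a signal_weights object")
  spec$n_species <- spec$n_genera * spec$species_per_genus
  spec$n_samples <- spec$n_species * spec$sites_per_species
  class(spec) <- "scenario_spec"
  spec
}

species_names <- function(spec) {
  genera <- sprintf("Genus%02d", seq_len(spec$n_genera))
  list(genera = genera,
       species = as.vector(t(outer(genera, seq_len(spec$species_per_genus),
                                   function(g, i) sprintf("%s_sp%d", g, i)))))
}

#' Simulate an ultrametric species phylogeny
#'
#' Genera attach by a random-coalescent backbone topology (join heights
#' increasing, deepest join at height 1); congeneric species split at a
#' recent depth drawn uniformly in `[0.05, 0.2]` of tree height.  The tree
#' is ultrametric by construction and deterministic under the spec's seed.
#'
#' @param spec a [scenario_spec].
#' @return an \pkg{ape} `phylo` with `n_genera * species_per_genus` tips.
#' @export
simulate_tree <- function(spec) {
  set.seed(stage_seed(spec$seed, "tree"))
  nm <- species_names(spec)
  ## genus subtrees: all congeners join at a shallow depth u
  lineages <- lapply(seq_len(spec$n_genera), function(g) {
    sp <- sprintf("%s_sp%d", nm$genera[g], seq_len(spec$species_per_genus))
    if (length(sp) == 1L) return(list(str = sp, h = 0))
    u <- stats::runif(1, 0.05, 0.2)
    list(str = sprintf("(%s)", paste(sprintf("%s:%.12f", sp, u),
                                     collapse = ",")), h = u)
  })
  if (spec$n_genera == 1L) {
    txt <- paste0(lineages[[1L]]$str, ";")
  } else {
    heights <- sort(stats::runif(spec$n_genera - 1L, 0.3, 1))
    heights[spec$n_genera - 1L] <- 1
    for (h in heights) {
      pick <- sample.int(length(lineages), 2L)
      l1 <- lineages[[pick[1L]]]; l2 <- lineages[[pick[2L]]]
      merged <- list(str = sprintf("(%s:%.12f,%s:%.12f)", l1$str, h - l1$h,
                                   l2$str, h - l2$h), h = h)
      lineages <- c(lineages[-pick], list(merged))
    }
    txt <- paste0(lineages[[1L]]$str, ";")
  }
  tree <- ape::read.tree(text = txt)
  validate_phylogeny(tree)
  tree
}

#' Simulate collection locations
#'
#' Each species gets a Gaussian patch around a patch centre.  Under the
#' default `"random"` rule the patches are wide (sd = extent/3) and placed
#' independently, so they overlap heavily and species identity carries
#' essentially no spatial information; under the `"phylogenetic"` rule
#' congeners share a genus centre (jittered by extent/20) and patches are
#' tight (sd = extent/10), making related species spatially close -- the
#' switch for injecting space-phylogeny confounding.
#' Within a species, locations are rejection-sampled to be pairwise at least
#' `min_spacing` apart and inside the study square.
#'
#' @param spec a [scenario_spec].
#' @return a sample frame (no chemistry yet) with columns `sample_id`,
#'   `species`, `genus`, `x`, `y`.
#' @export
simulate_sites <- function(spec) {
  set.seed(stage_seed(spec$seed, "sites"))
  nm <- species_names(spec)
  ext <- spec$extent
  centers <- matrix(NA_real_, spec$n_species, 2)
  if (spec$patch_rule == "phylogenetic") {
    gc <- matrix(stats::runif(spec$n_genera * 2, 0.15 * ext, 0.85 * ext),
                 spec$n_genera, 2)
    for (s in seq_len(spec$n_species)) {
      g <- ceiling(s / spec$species_per_genus)
      centers[s, ] <- pmin(pmax(gc[g, ] + stats::rnorm(2, 0, ext / 20),
                                0.05 * ext), 0.95 * ext)
    }
  } else {
    centers[] <- stats::runif(spec$n_species * 2, 0.15 * ext, 0.85 * ext)
  }
  patch_sd <- if (spec$patch_rule == "phylogenetic") ext / 10 else ext / 3
  rows <- vector("list", spec$n_species)
  for (s in seq_len(spec$n_species)) {
    pts <- matrix(NA_real_, spec$sites_per_species, 2)
    placed <- 0L
    tries <- 0L
    while (placed < spec$sites_per_species) {
      if (tries >= 10000L)
        stop("site placement failed after 10000 rejections for ",
             nm$species[s], "; increase the extent or reduce min_spacing")
      cand <- centers[s, ] + stats::rnorm(2, 0, patch_sd)
      tries <- tries + 1L
      if (any(cand < 0) || any(cand > ext)) next
      if (placed > 0L) {
        d <- sqrt(rowSums((pts[seq_len(placed), , drop = FALSE] -
                             matrix(cand, placed, 2, byrow = TRUE))^2))
        if (any(d < spec$min_spacing)) next
      }
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
    rows[[s]] <- data.frame(
      sample_id = sprintf("%s_loc%d", nm$species[s],
                          seq_len(spec$sites_per_species)),
      species = nm$species[s],
      genus = nm$genera[ceiling(s / spec$species_per_genus)],
      x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Cholesky factor of an exponential-covariance spatial field over coords.
grf_chol <- function(coords, range, nugget = 1e-8) {
  D <- as.matrix(stats::dist(coords))
  chol(exp(-D / range) + diag(nugget, nrow(D)))
}

#' Simulate soil chemistry
#'
#' Each of the ten chemistry variables is a spatially autocorrelated
#' Gaussian field (exponential covariance, range = extent/5) plus
#' independent noise, affinely rescaled so the defaults match realistic
#' marginals for a coastal loamy-sand site: pH centred at 6.07 (sd 0.46,
#' clipped to 5.01-8.03), organic matter 4.2% (sd 1.9, clipped to
#' 0.6-15.5%), Na 91.8 ppm (sd 61, clipped to 12-390 ppm), with the
#' remaining variables given field-plausible means and spreads.
#'
#' @param frame frame from [simulate_sites()].
#' @param spec a [scenario_spec].
#' @return the frame with the ten chemistry columns filled in.
#' @export
simulate_chemistry <- function(frame, spec) {
  set.seed(stage_seed(spec$seed, "chemistry"))
  n <- nrow(frame)
  targets <- list(
    no3_ppm     = c(mean = 8,    sd = 5,    lo = 0.5,  hi = Inf),
    p_olsen_ppm = c(mean = 25,   sd = 12,   lo = 1,    hi = Inf),
    k_ppm       = c(mean = 150,  sd = 60,   lo = 10,   hi = Inf),
    k_meq       = c(mean = 0.38, sd = 0.15, lo = 0.03, hi = Inf),
    na_ppm      = c(mean = 91.8, sd = 61,   lo = 12,   hi = 390),
    ca_meq      = c(mean = 5,    sd = 2.5,  lo = 0.3,  hi = Inf),
    mg_meq      = c(mean = 2.5,  sd = 1.2,  lo = 0.2,  hi = Inf),
    cec         = c(mean = 10,   sd = 3.5,  lo = 1,    hi = Inf),
    om_pct      = c(mean = 4.2,  sd = 1.9,  lo = 0.6,  hi = 15.5),
    ph          = c(mean = 6.07, sd = 0.46, lo = 5.01, hi = 8.03))
  L <- grf_chol(cbind(frame$x, frame$y), spec$extent / 5)
  for (v in chemistry_vars()) {
    smooth <- as.vector(t(L) %*% stats::rnorm(n))
    raw <- smooth + stats::rnorm(n, 0, 0.5)     # independent nugget
    z <- as.vector(scale(raw))
    tg <- targets[[v]]
    frame[[v]] <- pmin(pmax(tg["mean"] + tg["sd"] * z, tg["lo"]), tg["hi"])
  }
  validate_sample_frame(frame)
  frame
}

#' Simulate an OTU community table
#'
#' For OTU j and sample i the log-affinity is
#' `eta_ij = w_species * a[sp(i), j] + w_chem * <b_j, z_i> +
#'  w_space * g_j(x_i, y_i) + w_phylo * t_j(sp(i)) + eps_ij`, where
#'
#' * `a` are species offsets, iid over species but projected onto the
#'   orthogonal complement of the leading phylogenetic eigenvectors, so the
#'   species channel carries the *non-phylogenetic* component of species
#'   identity and the two channels are injectable independently;
#' * `b_j` are chemistry loadings on the standardised chemistry `z_i`;
#' * `g_j` is an exponential-covariance Gaussian random field (range =
#'   extent/3: broad-scale structure, the kind the leading spatial
#'   eigenvectors of the analysis are designed to capture);
#' * `t_j` is a Brownian-motion trait evolved on the tree (tip covariance
#'   equals the tree's variance-covariance matrix), so congeners get
#'   similar values;
#' * `eps ~ N(0, noise_sd)` iid.
#'
#' Technical subsample rows add iid `N(0, subsample_sd)` and abundances are
#' `exp(eta)` row-normalised to relative abundance.  Fully deterministic
#' under the spec's seed, with one independent stream per channel.
#'
#' @param frame complete sample frame (coordinates + chemistry).
#' @param tree species phylogeny covering `frame$species`.
#' @param spec a [scenario_spec].
#' @return an [otu_table] of relative abundances (rows sum to 1).
#' @export
simulate_community <- function(frame, tree, spec) {
  w <- spec$weights
  n <- nrow(frame)
  m <- spec$n_otus
  sp <- tree$tip.label
  S <- length(sp)
  sp_idx <- match(frame$species, sp)
  if (anyNA(sp_idx)) stop("tree tips do not cover frame species")
  eta <- matrix(0, n, m)

  if (w$w_species > 0) {
    set.seed(stage_seed(spec$seed, "species_effects"))
    A <- matrix(stats::rnorm(S * m), S, m)
    ## remove the phylogenetically structured component of the offsets
    n_ev <- min(7L, S - 1L)
    EV <- pcoa(patristic_distances(tree), "phylogenetic")$vectors
    B <- cbind(1, EV[sp, seq_len(min(n_ev, ncol(EV))), drop = FALSE])
    Q <- qr.Q(qr(B))
    A <- A - Q %*% (t(Q) %*% A)
    A <- scale(A)                        # unit variance across species
    eta <- eta + w$w_species * A[sp_idx, , drop = FALSE]
  }
  if (w$w_chem > 0) {
    set.seed(stage_seed(spec$seed, "chem_loadings"))
    Bld <- matrix(stats::rnorm(10 * m, sd = sqrt(1 / 10)), 10, m)
    eta <- eta + w$w_chem * (standardize_chemistry(frame) %*% Bld)
  }
  if (w$w_space > 0) {
    set.seed(stage_seed(spec$seed, "space_fields"))
    Ls <- grf_chol(cbind(frame$x, frame$y), spec$extent / 3)
    eta <- eta + w$w_space * (t(Ls) %*% matrix(stats::rnorm(n * m), n, m))
  }
  if (w$w_phylo > 0) {
    set.seed(stage_seed(spec$seed, "phylo_traits"))
    V <- ape::vcv.phylo(tree)[sp, sp]
    Lp <- chol(V + diag(1e-10, S))
    Tt <- t(Lp) %*% matrix(stats::rnorm(S * m), S, m)
    eta <- eta + w$w_phylo * Tt[sp_idx, , drop = FALSE]
  }
  set.seed(stage_seed(spec$seed, "noise"))
  eta <- eta + matrix(stats::rnorm(n * m, 0, w$noise_sd), n, m)

  set.seed(stage_seed(spec$seed, "subsample"))
  reps <- spec$subsamples_per_sample
  row_idx <- rep(seq_len(n), each = reps)
  eta_sub <- eta[row_idx, , drop = FALSE] +
    matrix(stats::rnorm(n * reps * m, 0, w$subsample_sd), n * reps, m)
  ab <- exp(eta_sub)
  ab <- ab / rowSums(ab)
  colnames(ab) <- sprintf("OTU%04d", seq_len(m))
  otu_table(ab,
            sample_id = frame$sample_id[row_idx],
            subsample_id = rep(sprintf("s%d", seq_len(reps)), times = n))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_sites()],
#' [simulate_chemistry()] and [simulate_community()].
#'
#' @param spec a [scenario_spec].
#' @return list with `tree`, `frame`, `otu`, `spec`.
#' @export
simulate_dataset <- function(spec) {
  tree <- simulate_tree(spec)
  frame <- simulate_sites(spec)
  frame <- simulate_chemistry(frame, spec)
  otu <- simulate_community(frame, tree, spec)
  list(tree = tree, frame = frame, otu = otu, spec = spec)
}

#' Write a synthetic dataset in the pipeline's external file formats
#'
#' Emits exactly the formats the readers consume (OTU TSV, metadata TSV,
#' chemistry TSV, Newick), so the pipeline cannot distinguish synthetic from
#' field input.
#'
#' @param data list from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_scenario <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             chemistry = file.path(dir, "chemistry.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_otu_table(data$otu, paths["otu"])
  write_sample_frame(data$frame, paths["metadata"], paths["chemistry"])
  write_newick(data$tree, paths["tree"])
  paths
}
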