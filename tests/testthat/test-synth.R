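test_that("simulated trees have the congener-pair structure and are ultrametric", {
  spec <- scenario_spec(seed = 31)
  tree <- simulate_tree(spec)
  expect_equal(length(tree$tip.label), 14L)
  # seven cherries: each species' closest relative is its congener
  D <- patristic_distances(tree)
  diag(D) <- Inf
  nearest <- rownames(D)[apply(D, 1, which.min)]
  genus_of <- function(x) sub("_sp[0-9]+$", "", x)
  expect_true(all(genus_of(nearest) == genus_of(rownames(D))))
  # ultrametric: all root-to-tip depths equal
  depths <- ape::node.depth.edgelength(tree)[seq_len(14)]
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_equal(max(depths), 1, tolerance = 1e-9)
  # congener splits at 5-20% of tree height
  cherries <- D[cbind(paste0(genus_of(rownames(D)), "_sp1"),
                      paste0(genus_of(rownames(D)), "_sp2"))] / 2
  expect_true(all(cherries >= 0.05 & cherries <= 0.2))
  # determinism
  expect_identical(ape::write.tree(simulate_tree(spec)),
                   ape::write.tree(tree))
})

test_that("site placement respects spacing and is deterministic", {
  spec <- scenario_spec(seed = 13)
  frame <- simulate_sites(spec)
  expect_equal(nrow(frame), 84L)
  for (sp in unique(frame$species)) {
    pts <- frame[frame$species == sp, c("x", "y")]
    d <- dist(pts)
    expect_gte(min(d), spec$min_spacing)
  }
  expect_true(all(frame$x >= 0 & frame$x <= spec$extent))
  expect_identical(simulate_sites(spec), frame)
  # impossible spacing fails with advice
  tight <- scenario_spec(extent = 150, min_spacing = 140, seed = 1)
  expect_error(simulate_sites(tight), "extent")
})

test_that("the phylogenetic patch rule places congeners closer together", {
  congener_vs_other <- function(seed) {
    spec <- scenario_spec(patch_rule = "phylogenetic", seed = seed)
    frame <- simulate_sites(spec)
    sp_means <- aggregate(frame[, c("x", "y")], list(sp = frame$species),
                          mean)
    gen <- sub("_sp[0-9]+$", "", sp_means$sp)
    D <- as.matrix(dist(sp_means[, c("x", "y")]))
    same <- outer(gen, gen, "==") & upper.tri(D)
    diff_g <- outer(gen, gen, "!=") & upper.tri(D)
    mean(D[same]) - mean(D[diff_g])
  }
  gaps <- vapply(1:20, congener_vs_other, numeric(1))
  expect_lt(median(gaps), 0)
  expect_gt(mean(gaps < 0), 0.8)
})

test_that("chemistry marginals match the calibrated field site", {
  ph_means <- vapply(1:20, function(seed) {
    spec <- scenario_spec(seed = seed)
    frame <- simulate_chemistry(simulate_sites(spec), spec)
    mean(frame$ph)
  }, numeric(1))
  expect_gte(mean(ph_means >= 5.8 & ph_means <= 6.4), 0.95)
  spec <- scenario_spec(seed = 4)
  frame <- simulate_chemistry(simulate_sites(spec), spec)
  expect_true(all(frame$ph >= 5.01 & frame$ph <= 8.03))
  expect_true(all(frame$om_pct >= 0.6 & frame$om_pct <= 15.5))
  expect_true(all(frame$na_ppm >= 12 & frame$na_ppm <= 390))
  expect_identical(simulate_chemistry(simulate_sites(spec), spec), frame)
})

test_that("chemistry fields are spatially autocorrelated, degrading to flat at infinite range", {
  spec <- scenario_spec(seed = 6)
  frame <- simulate_chemistry(simulate_sites(spec), spec)
  D <- as.matrix(dist(cbind(frame$x, frame$y)))
  near <- D < quantile(D[upper.tri(D)], 0.1) & upper.tri(D)
  far <- D > quantile(D[upper.tri(D)], 0.9) & upper.tri(D)
  # near pairs more similar than far pairs, pooled over variables
  gaps <- vapply(chemistry_vars(), function(v) {
    z <- as.vector(scale(frame[[v]]))
    gap <- abs(outer(z, z, "-"))
    mean(gap[far]) - mean(gap[near])
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  # infinite-range limit: smooth component collapses to a constant, so the
  # field is nugget noise around a flat surface and near/far gaps vanish
  spec_inf <- spec
  spec_inf$extent <- Inf
  frame_inf <- frame
  frame_inf[chemistry_vars()] <- NULL
  frame_inf <- simulate_chemistry(frame_inf, spec_inf)
  gaps_inf <- vapply(chemistry_vars(), function(v) {
    z <- as.vector(scale(frame_inf[[v]]))
    gap <- abs(outer(z, z, "-"))
    mean(gap[far]) - mean(gap[near])
  }, numeric(1))
  expect_lt(mean(abs(gaps_inf)), mean(gaps))
})

test_that("community tables are valid compositions, deterministic under seed", {
  spec <- tiny_spec(seed = 17)
  data <- simulate_dataset(spec)
  expect_equal(rowSums(data$otu$values), rep(1, nrow(data$otu$values)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(data$otu$values > 0))
  data2 <- simulate_dataset(spec)
  expect_identical(data$otu$values, data2$otu$values)
})

test_that("a phylogeny-only signal makes congeners compositionally closer", {
  genus_gap <- function(seed) {
    spec <- tiny_spec(seed = seed, n_otus = 60,
                      weights = signal_weights(w_species = 0, w_chem = 0,
                                               w_space = 0, w_phylo = 3))
    data <- simulate_dataset(spec)
    D <- bray_curtis(average_subsamples(data$otu))
    sp <- data$frame$species[match(rownames(D), data$frame$sample_id)]
    gen <- data$frame$genus[match(rownames(D), data$frame$sample_id)]
    congener <- outer(gen, gen, "==") & outer(sp, sp, "!=") & upper.tri(D)
    other <- outer(gen, gen, "!=") & upper.tri(D)
    mean(D[congener]) - mean(D[other])
  }
  gaps <- vapply(1:10, genus_gap, numeric(1))
  expect_lt(median(gaps), 0)
  expect_gt(mean(gaps < 0), 0.8)
})

test_that("with all weights zero, group labels carry no compositional signal", {
  gap <- vapply(23:42, function(seed) {
    spec <- tiny_spec(seed = seed, weights = signal_weights(
      w_species = 0, w_chem = 0, w_space = 0, w_phylo = 0))
    data <- simulate_dataset(spec)
    D <- bray_curtis(average_subsamples(data$otu))
    sp <- data$frame$species[match(rownames(D), data$frame$sample_id)]
    within <- outer(sp, sp, "==") & upper.tri(D)
    between <- outer(sp, sp, "!=") & upper.tri(D)
    mean(D[within]) - mean(D[between])
  }, numeric(1))
  # 20-seed Monte-Carlo mean; bound is ~4 standard errors of that mean
  expect_lt(abs(mean(gap)), 0.01)
})

test_that("Brownian traits have tip covariance matching the tree", {
  spec <- scenario_spec(n_otus = 500, seed = 19,
                        weights = signal_weights(w_species = 0, w_chem = 0,
                                                 w_space = 0, w_phylo = 1))
  # nearly noise-free generation isolates the Brownian trait channel in the
  # log relative abundances (row-normalisation only shifts whole samples,
  # which cancels in covariances taken across OTUs)
  spec$weights$noise_sd <- 0.05
  spec$weights$subsample_sd <- 0.01
  data <- simulate_dataset(spec)
  sp <- data$tree$tip.label
  V <- ape::vcv.phylo(data$tree)[sp, sp]
  first_rows <- match(paste0(sp, "_loc1"), data$otu$sample_id)
  logv <- log(data$otu$values[first_rows, ])
  logv <- logv - rowMeans(logv)
  emp <- tcrossprod(sweep(logv, 2, colMeans(logv))) / ncol(logv)
  expect_gt(cor(emp[upper.tri(emp)], V[upper.tri(V)]), 0.9)
})

test_that("emitted file formats round-trip through the io readers", {
  spec <- tiny_spec(seed = 29)
  data <- simulate_dataset(spec)
  dir <- withr::local_tempdir()
  paths <- write_scenario(data, dir)
  otu <- read_otu_table(paths[["otu"]])
  expect_equal(otu$values, data$otu$values, tolerance = 1e-10)
  frame <- read_sample_frame(paths[["metadata"]], paths[["chemistry"]])
  expect_identical(frame$sample_id, data$frame$sample_id)
  # planar geometry survives the GPS round trip
  d_orig <- dist(cbind(data$frame$x, data$frame$y))
  d_back <- dist(cbind(frame$x, frame$y))
  expect_equal(as.vector(d_back), as.vector(d_orig), tolerance = 1e-3)
  tree <- read_newick(paths[["tree"]])
  expect_setequal(tree$tip.label, data$tree$tip.label)
})
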