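test_that("patristic distances sum branch lengths along tip paths", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_distances(tree)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["B", "C"], 4)
  # star tree: every off-diagonal distance is 2
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  Ds <- patristic_distances(star)
  expect_true(all(Ds[upper.tri(Ds)] == 2))
  # ultrametric tree: max distance = 2 * height
  ut <- simulate_tree(scenario_spec(seed = 3))
  expect_equal(max(patristic_distances(ut)), 2 * tree_height(ut),
               tolerance = 1e-9)
  noBL <- ape::read.tree(text = "((A,B),C);")
  expect_error(patristic_distances(noBL), "branch length")
})

test_that("PCoA reconstructs Euclidean configurations", {
  # three points on a line at 0, 1, 3: one positive axis, exact distances
  pts <- c(0, 1, 3)
  D <- abs(outer(pts, pts, "-"))
  dimnames(D) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  dec <- pcoa(D)
  expect_equal(length(dec$eigenvalues), 1L)
  expect_equal(abs(outer(dec$vectors[, 1], dec$vectors[, 1], "-")), D,
               tolerance = 1e-10, ignore_attr = TRUE)

  # random planar points: exactly two positive eigenvalues, axes that
  # reproduce all pairwise distances, centred columns
  set.seed(8)
  XY <- matrix(rnorm(30), 15, 2)
  D2 <- as.matrix(dist(XY))
  dimnames(D2) <- list(sprintf("s%d", 1:15), sprintf("s%d", 1:15))
  dec2 <- pcoa(D2)
  expect_equal(ncol(dec2$vectors), 2L)
  expect_equal(as.matrix(dist(dec2$vectors)), D2,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(colSums(dec2$vectors), c(EV1 = 0, EV2 = 0), tolerance = 1e-8)
  # trace identity for Euclidean D: sum(lambda) = sum(D^2_ij)/n over i<j
  expect_equal(sum(dec2$eigenvalues),
               sum(D2[lower.tri(D2)]^2) / nrow(D2), tolerance = 1e-8)
  # agreement with classical scaling as independent route
  ref <- pcoa_brute(D2, k = 2)
  expect_lt(procrustes_residual(ref$points, dec2$vectors), 1e-8)
})

test_that("negative eigenvalues are reported but their axes discarded", {
  X <- random_table(10, 12, seed = 2)
  D <- bc_brute(X)
  dec <- pcoa(D)
  expect_true(any(dec$all_eigenvalues < 0))
  expect_true(all(dec$eigenvalues > 0))
  G <- crossprod(dec$vectors)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)   # orthogonal columns
})

test_that("phylogenetic eigenvectors broadcast species values to samples", {
  spec <- scenario_spec(seed = 5)
  tree <- simulate_tree(spec)
  frame <- simulate_sites(spec)
  evs <- phylo_eigenvectors(tree, frame, n_screen = 7)
  expect_equal(dim(evs$vectors), c(84L, 7L))
  same_sp <- which(frame$species == frame$species[1])
  expect_equal(evs$vectors[same_sp[1], ], evs$vectors[same_sp[2], ])
  expect_error(phylo_eigenvectors(tree, frame, n_screen = 14), "n_screen")
  frame_bad <- frame
  frame_bad$species[1] <- "NotInTree"
  expect_error(phylo_eigenvectors(tree, frame_bad, 7), "NotInTree")
})

test_that("a deep-split eigenvector separates genera before congeners", {
  # two genera of two congeners each, deep split between genera
  tree <- ape::read.tree(
    text = "((A1:0.1,A2:0.1):0.9,(B1:0.1,B2:0.1):0.9);")
  dec <- pcoa(patristic_distances(tree))
  ev1 <- dec$vectors[, 1]
  expect_true(sign(ev1[["A1"]]) == sign(ev1[["A2"]]))
  expect_true(sign(ev1[["B1"]]) == sign(ev1[["B2"]]))
  expect_true(sign(ev1[["A1"]]) != sign(ev1[["B1"]]))
  # shallow eigenvectors separate within genus
  ev23 <- dec$vectors[, 2:3]
  expect_true(any(abs(ev23["A1", ] - ev23["A2", ]) > 0.1) &&
              any(abs(ev23["B1", ] - ev23["B2", ]) > 0.1))
})

test_that("phylo eigenvectors are invariant to tip ordering up to sign", {
  spec <- tiny_spec(seed = 11)
  tree <- simulate_tree(spec)
  frame <- simulate_sites(spec)
  a <- phylo_eigenvectors(tree, frame, 5)$vectors
  tree2 <- ape::rotateConstr(tree, rev(tree$tip.label))
  b <- phylo_eigenvectors(tree2, frame, 5)$vectors
  agree <- vapply(seq_len(5), function(j)
    min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j]))), numeric(1))
  expect_lt(max(agree), 1e-8)
})

test_that("scree break finds the largest successive eigenvalue drop", {
  expect_equal(scree_break(c(10, 9, 8, 1, 0.9)), 3)
  expect_equal(scree_break(c(5, 5, 5)), 3)
  expect_equal(scree_break(c(4, 2)), 1)
  expect_error(scree_break(c(1)), "two")
  expect_error(scree_break(c(1, 5)), "descending")
})

test_that("spatial eigenvectors span the centred coordinate plane", {
  spec <- tiny_spec(seed = 21)
  frame <- simulate_sites(spec)
  evs <- spatial_eigenvectors(frame, n_keep = 2)
  centred <- scale(cbind(frame$x, frame$y), scale = FALSE)
  expect_lt(procrustes_residual(centred, evs$vectors), 1e-8)
  # translation invariance
  frame2 <- frame
  frame2$x <- frame2$x + 5000
  frame2$y <- frame2$y - 1234
  evs2 <- spatial_eigenvectors(frame2, n_keep = 2)
  expect_equal(evs$vectors, evs2$vectors, tolerance = 1e-6)
  # collinear sites are rank-1: the second axis does not exist
  frame3 <- frame[1:6, ]
  frame3$x <- seq_len(6) * 200
  frame3$y <- 0
  expect_error(spatial_eigenvectors(frame3, n_keep = 2), "positive spatial")
  expect_silent(evs1 <- spatial_eigenvectors(frame3, n_keep = 1))
})
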