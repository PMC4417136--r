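# A fixed 14-species design shared by the selection tests.
models_fixture <- local({
  spec <- scenario_spec(seed = 99)
  tree <- simulate_tree(spec)
  frame <- simulate_chemistry(simulate_sites(spec), spec)
  list(tree = tree, frame = frame,
       phylo = phylo_eigenvectors(tree, frame, 7),
       spatial = spatial_eigenvectors(frame, 2),
       chem_z = standardize_chemistry(frame))
})

test_that("fit_ols matches a pseudo-inverse normal-equations oracle", {
  set.seed(1)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    fit <- fit_ols(y, as.data.frame(X))
    ref <- ols_brute(y, X)
    expect_equal(unname(fit$coefficients), ref$beta, tolerance = 1e-8)
    expect_equal(fit$r_squared, ref$r2, tolerance = 1e-10)
    expect_equal(fit$adj_r_squared, ref$adj_r2, tolerance = 1e-10)
    expect_equal(fit$log_lik, ref$log_lik, tolerance = 1e-8)
  }
})

test_that("fit_ols handles exact fits, rank deficiency and intercept-only", {
  x <- 1:20
  fit <- suppressWarnings(fit_ols(2 * x + 1, data.frame(x = x)))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$adj_r_squared, 1)
  expect_error(fit_ols(rnorm(20), data.frame(a = x, b = 2 * x)),
               "aliased.*b")
  null_fit <- fit_ols(rnorm(20), NULL)
  expect_equal(null_fit$p, 0L)
  expect_equal(null_fit$r_squared, 0)
})

test_that("single binary predictor: overall F-test equals the two-sample t-test", {
  set.seed(7)
  g <- rep(0:1, each = 15)
  y <- rnorm(30) + 0.5 * g
  fit <- fit_ols(y, data.frame(g = g))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(fit$f_p_value, tt$p.value, tolerance = 1e-10)
})

test_that("adjusted R-squared of pure-noise designs is centred on zero", {
  set.seed(42)
  adj <- replicate(200, fit_ols(rnorm(60),
    as.data.frame(matrix(rnorm(60 * 4), 60, 4)))$adj_r_squared)
  expect_lt(abs(mean(adj)), 0.02)
})

test_that("VIF has its closed forms and infinite collinearity limit", {
  # orthonormal design
  Q <- qr.Q(qr(scale(matrix(rnorm(100 * 3), 100, 3), scale = FALSE)))
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  # exact correlation r -> VIF = 1/(1-r^2)
  for (r in c(0.3, 0.6, 0.9)) {
    set.seed(5)
    z1 <- rnorm(500); z2 <- rnorm(500)
    z1 <- as.vector(scale(z1)); z2 <- as.vector(scale(resid(lm(z2 ~ z1))))
    X <- cbind(a = z1, b = r * z1 + sqrt(1 - r^2) * z2)
    expect_equal(unname(vif(X)), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  }
  expect_equal(unname(vif(cbind(a = 1:10, b = 1:10))), c(Inf, Inf))
  expect_error(vif(matrix(1:5)), "two columns")
})

test_that("likelihood-ratio test is calibrated and detects dropped effects", {
  set.seed(31)
  # null distribution ~ chi-squared with df = 2 (asymptotic, so large n)
  stats <- replicate(1000, {
    y <- rnorm(200)
    X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
    full <- fit_ols(y, as.data.frame(X))
    red <- fit_ols(y, as.data.frame(X[, 1, drop = FALSE]))
    lrt_drop_class(full, red)$statistic
  })
  ks <- suppressWarnings(ks.test(stats, pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
  # identical designs give statistic 0, p 1
  y <- rnorm(40); X <- data.frame(a = rnorm(40))
  f <- fit_ols(y, X)
  expect_equal(lrt_drop_class(f, f)$p_value, 1)
  # a strong dropped effect is detected
  x <- rnorm(80); y2 <- x + rnorm(80, sd = 0.5)
  full <- fit_ols(y2, data.frame(x = x, z = rnorm(80)))
  red <- fit_ols(y2, data.frame(z = full$fit$model$z))
  expect_lt(lrt_drop_class(full, red)$p_value, 0.001)
  # non-nested designs are refused
  g <- fit_ols(y, data.frame(w = rnorm(40)))
  expect_error(lrt_drop_class(f, g), "not nested")
})

test_that("phylogenetic eigenvector retention recovers a planted predictor", {
  fx <- models_fixture
  P <- fx$phylo$vectors
  set.seed(2)
  kept_sets <- lapply(1:100, function(rep) {
    y <- P[, 2] + rnorm(84, sd = 0.3 * sd(P[, 2]))
    as.integer(retain_significant_phylo(y, fx$phylo, fx$spatial))
  })
  # the planted eigenvector is recovered; false inclusions of the other six
  # columns happen at the nominal ~5% each, so the typical set is exactly {2}
  expect_gte(sum(vapply(kept_sets, function(k) 2L %in% k, logical(1))), 90)
  expect_equal(median(lengths(kept_sets)), 1)
  # exact predictor: retained with overwhelming evidence
  kept <- retain_significant_phylo(P[, 3] + rnorm(84, sd = 1e-8),
                                   fx$phylo, fx$spatial)
  expect_true(3L %in% kept)
  expect_lt(attr(kept, "p_values")[3], 1e-10)
})

test_that("retention under pure noise is a binomial at the nominal level", {
  fx <- models_fixture
  set.seed(3)
  counts <- replicate(500,
    length(retain_significant_phylo(rnorm(84), fx$phylo, fx$spatial)))
  # expected mean = 7 * 0.05 = 0.35; 500-seed Monte-Carlo band ~ +/-3 SE
  expect_gt(mean(counts), 0.35 - 0.1)
  expect_lt(mean(counts), 0.35 + 0.1)
})

test_that("stepwise AIC chemistry selection recovers a single-driver model", {
  fx <- models_fixture
  Z <- fx$chem_z
  set.seed(4)
  sels <- lapply(1:100, function(i) {
    y <- 0.8 * Z[, "ph"] + rnorm(84, sd = 1)
    step_aic_chemistry(y, Z)
  })
  # the planted driver is recovered; the other nine null variables slip in
  # at roughly the nominal rate each, so the typical model is just {ph}
  expect_gte(sum(vapply(sels, function(s) "ph" %in% s, logical(1))), 90)
  expect_equal(median(lengths(sels)), 1)
})

test_that("chemistry selection on noise stays small, and guards its input", {
  fx <- models_fixture
  set.seed(6)
  sizes <- replicate(200, length(step_aic_chemistry(rnorm(84), fx$chem_z)))
  expect_lte(median(sizes), 1)
  expect_error(step_aic_chemistry(rnorm(84), fx$frame[, chemistry_vars()]),
               "standardised")
  Zdup <- fx$chem_z
  Zdup[, 2] <- Zdup[, 1]
  expect_error(step_aic_chemistry(rnorm(84), Zdup), "aliased|deficien")
})

test_that("class models attribute a planted species effect to species identity", {
  fx <- models_fixture
  set.seed(8)
  sp <- factor(fx$frame$species)
  effects <- rnorm(nlevels(sp), sd = 2)
  # remove the phylogenetically structured part so the planted signal is
  # purely species identity
  P <- fx$phylo$vectors[match(levels(sp), fx$frame$species), ]
  Q <- qr.Q(qr(cbind(1, P)))
  effects <- as.vector(effects - Q %*% (t(Q) %*% effects))
  y <- effects[as.integer(sp)] + rnorm(84, sd = 1)
  res <- class_models(y, fx$frame, fx$phylo, fx$spatial)
  expect_setequal(res$class,
                  c("species", "chemistry", "space", "phylogeny", "genus"))
  sp_row <- res[res$class == "species", ]
  expect_lt(sp_row$p_value, 0.001)
  expect_gt(sp_row$adj_r2, res[res$class == "phylogeny", "adj_r2"])
  # chemistry and phylogeny never co-occur in a single tested model
  expect_true(all(res$class %in%
    c("species", "chemistry", "space", "phylogeny", "genus")))
})

test_that("empty retained sets give the no-evidence convention", {
  fx <- models_fixture
  # a response orthogonal to everything measurable: plain noise with a seed
  # chosen arbitrarily; conventions, not significance, are under test
  set.seed(12)
  y <- rnorm(84)
  res <- class_models(y, fx$frame, fx$phylo, fx$spatial)
  # an empty selected/retained set contributes zero explanatory power; the
  # class p-value still comes from the calibrated pre-selection test
  phy <- res[res$class == "phylogeny", ]
  if (phy$n_predictors == 0) {
    expect_equal(phy$adj_r2, 0)
    expect_gt(phy$p_value, 0.05)
  }
  chem <- res[res$class == "chemistry", ]
  if (chem$n_predictors == 0) {
    expect_equal(chem$adj_r2, 0)
    expect_true(chem$p_value > 0 && chem$p_value <= 1)
  }
  # results render with the display conventions
  txt <- format_results_table(res)
  expect_true(any(grepl("<0.01", txt)) || all(res$adj_r2 >= 0.01))
})
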