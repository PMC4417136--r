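# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders.  Oracles deliberately use
# naive loops / closed forms, never the code paths they check.

# Bray-Curtis by explicit double loop over sample pairs.
bc_brute <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0
    for (k in seq_len(ncol(X))) num <- num + min(X[i, k], X[j, k])
    D[i, j] <- 1 - 2 * num / (sum(X[i, ]) + sum(X[j, ]))
  }
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

# OLS by pseudo-inverse normal equations, with closed-form R2/adjR2/logLik.
ols_brute <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  beta <- MASS::ginv(t(Xd) %*% Xd) %*% t(Xd) %*% y
  res <- y - Xd %*% beta
  n <- length(y)
  p <- ncol(Xd) - 1
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(beta = as.vector(beta), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       log_lik = -n / 2 * (log(2 * pi) + log(rss / n) + 1))
}

# Gower-centred PCoA via an independent route: cmdscale on the distance
# matrix (classical MDS is the same decomposition).
pcoa_brute <- function(D, k) {
  stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
}

# Three-set partition by independently enumerating every subset fit with lm.
partition3_brute <- function(y, Xs) {
  adj <- function(cols) {
    if (is.null(cols) || ncol(cols) == 0) return(0)
    summary(stats::lm(y ~ ., data = as.data.frame(cols)))$adj.r.squared
  }
  u <- function(s) do.call(cbind, Xs[s])
  A123 <- adj(u(1:3)); A12 <- adj(u(1:2)); A13 <- adj(u(c(1, 3)))
  A23 <- adj(u(2:3)); A1 <- adj(u(1)); A2 <- adj(u(2)); A3 <- adj(u(3))
  a <- A123 - A23; b <- A123 - A13; c_ <- A123 - A12
  ab <- A123 - A3 - a - b; ac <- A123 - A2 - a - c_
  bc <- A123 - A1 - b - c_
  abc <- A123 - a - b - c_ - ab - ac - bc
  c(a = a, b = b, c = c_, ab = ab, ac = ac, bc = bc, abc = abc,
    residual = 1 - A123)
}

# Procrustes residual after optimal translation/rotation/scaling of
# configuration B onto A (both n x k).
procrustes_residual <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  sv <- svd(t(A) %*% B)
  R <- sv$v %*% t(sv$u)
  s <- sum(sv$d) / sum(B^2)
  sum((A - s * B %*% R)^2)
}

# A small complete synthetic scenario for pipeline-level tests.
tiny_spec <- function(seed = 1, weights = signal_weights(), n_otus = 40,
                      n_genera = 4, sites_per_species = 3) {
  scenario_spec(n_genera = n_genera, species_per_genus = 2,
                sites_per_species = sites_per_species,
                subsamples_per_sample = 2, n_otus = n_otus,
                extent = 5000, min_spacing = 100,
                weights = weights, seed = seed)
}

# Random small OTU matrix with labels.
random_table <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(stats::rexp(n * m), n, m)
  rownames(X) <- sprintf("s%02d", seq_len(n))
  colnames(X) <- sprintf("OTU%03d", seq_len(m))
  X
}
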