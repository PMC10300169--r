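# Independent oracles and small fixture builders shared across tests.

# Brute-force conditional log-likelihood: for each stratum, enumerate the
# within-stratum case choices that form the denominator directly.
enum_clogit_loglik <- function(beta, x, y, strata) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (ix in split(seq_along(y), strata)) {
    ll <- ll + eta[ix][y[ix] == 1] - log(sum(exp(eta[ix])))
  }
  ll
}

# Coarse-to-fine grid search maximizer of the enumerated likelihood (1-D).
grid_clogit_max <- function(x, y, strata, lo = -4, hi = 4) {
  for (step in c(0.01, 1e-3, 1e-4, 1e-5)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, function(b) enum_clogit_loglik(b, x, y, strata), 0)
    best <- grid[which.max(ll)]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# 1:1 matched pairs with a binary exposure: a case-exposed-only discordant
# pairs, b control-exposed-only, plus concordant padding.
make_discordant_pairs <- function(a, b, conc_exposed = 2, conc_unexposed = 2) {
  pair_types <- c(rep("case_exp", a), rep("ctrl_exp", b),
                  rep("both", conc_exposed), rep("neither", conc_unexposed))
  n <- length(pair_types)
  x <- unlist(lapply(pair_types, function(t)
    switch(t, case_exp = c(1, 0), ctrl_exp = c(0, 1),
           both = c(1, 1), neither = c(0, 0))))
  list(x = matrix(x, ncol = 1, dimnames = list(NULL, "exposure")),
       y = rep(c(1, 0), n), strata = rep(seq_len(n), each = 2))
}

# Random sparse lower-triangular Gaussian DAG; returns data and the true
# skeleton adjacency (the moral-free undirected version of the edge set).
sim_dag <- function(p, n, edge_prob = 0.2, seed = 1) {
  set.seed(seed)
  B <- matrix(0, p, p)
  for (j in 2:p) for (i in seq_len(j - 1)) {
    if (runif(1) < edge_prob)
      B[j, i] <- sample(c(-1, 1), 1) * runif(1, 0.5, 1)
  }
  X <- matrix(0, n, p)
  for (j in seq_len(p)) {
    X[, j] <- X %*% B[j, ] + rnorm(n)
  }
  colnames(X) <- paste0("V", seq_len(p))
  skel <- (B != 0) | t(B != 0)
  list(data = X, skeleton = skel, B = B)
}

structural_hamming <- function(adj_a, adj_b) {
  sum((adj_a != adj_b)[upper.tri(adj_a)])
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum(choose(tab, 2))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Cached small cohorts so independent tests reuse fixtures without
# regenerating them.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_cohort <- function() cached("small_cohort", {
  generate_cohort(cohort_spec(n_strata = 120, n_lipids = 20, n_clusters = 4,
                              within_cluster_rho = 0.5, seed = 3))
})

signal_cohort <- function() cached("signal_cohort", {
  generate_cohort(cohort_spec(
    n_strata = 400, n_lipids = 30, n_clusters = 10, within_cluster_rho = 0.5,
    true_effects = stats::setNames(rep(0.6, 3), c("1", "2", "3")),
    missing_rate = 0, seed = 21))
})

blom_of <- function(cohort) blom_transform(impute_half_min(cohort$lipids))

unclass_helper <- function(x) {
  class(x) <- c("matrix", "array")
  attr(x, "transform_tag") <- NULL
  attr(x, "provenance") <- NULL
  x
}
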