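make_block_data <- function(n = 400, blocks = 3, per_block = 10, rho = 0.7,
                            seed = 5) {
  set.seed(seed)
  p <- blocks * per_block
  sig <- matrix(0, p, p)
  for (b in seq_len(blocks)) {
    ix <- ((b - 1) * per_block + 1):(b * per_block)
    sig[ix, ix] <- rho
  }
  diag(sig) <- 1
  m <- matrix(rnorm(n * p), n, p) %*% chol(sig)
  colnames(m) <- sprintf("lipid_%03d", seq_len(p))
  m
}

test_that("independent features retain no factor at the eigenvalue cutoff", {
  set.seed(6)
  m <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  expect_warning(fm <- fit_pca_controls(m, rep(TRUE, 500)), "empty factor")
  expect_equal(fm$retained, 0)
  expect_true(all(abs(fm$eigenvalues - 1) < 0.5))
  expect_error(project_scores(fm, m), "no retained factors")
})

test_that("three correlation blocks yield three factors matching the blocks", {
  m <- make_block_data()
  fm <- fit_pca_controls(m, rep(TRUE, nrow(m)))
  expect_equal(fm$retained, 3)
  expect_equal(fm$retained, sum(fm$eigenvalues > 2))
  blocks <- split(colnames(m), rep(1:3, each = 10))
  found <- lapply(fm$relevant_loadings, sort)
  for (b in blocks) {
    expect_true(any(vapply(found, identical, TRUE, y = sort(b))))
  }
  expect_equal(fm$variance_explained,
               sum(fm$eigenvalues[fm$eigenvalues > 2]) / ncol(m))
})

test_that("varimax preserves communalities and orthogonality", {
  m <- make_block_data(seed = 8)
  fm <- fit_pca_controls(m, rep(TRUE, nrow(m)))
  C <- cor(m)
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors[, 1:fm$retained] %*% diag(sqrt(ev$values[1:fm$retained]))
  # rotation leaves per-feature sums of squared loadings unchanged
  expect_equal(rowSums(fm$loadings^2), unname(rowSums(L^2)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # the rotation matrix is orthonormal
  expect_equal(crossprod(fm$rotation), diag(fm$retained), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("projection centers on controls and responds linearly to features", {
  m <- make_block_data(n = 300, seed = 9)
  ctrl <- rep(c(TRUE, FALSE), length.out = 300)
  fm <- fit_pca_controls(m, ctrl)
  fs <- project_scores(fm, m)
  # a subject exactly at the controls' feature means scores 0 on every factor
  probe <- matrix(fm$center, 1, ncol(m), dimnames = list(NULL, colnames(m)))
  expect_equal(as.numeric(project_scores(fm, probe)), rep(0, fm$retained))
  # linear response: shifting feature j moves factor f by delta/sd_j * loading
  j <- 4
  m2 <- m
  m2[1, j] <- m2[1, j] + 2
  fs2 <- project_scores(fm, m2)
  expect_equal(fs2[1, ] - fs[1, ], 2 / fm$scale[j] * fm$loadings[j, ],
               tolerance = 1e-10, ignore_attr = TRUE)
  # controls' factor-score SD tracks the analytic variance of the weighted
  # sum, L_f' Sigma L_f under the generating block correlation
  sig_pop <- matrix(0, 30, 30)
  for (b in 1:3) {
    ix <- ((b - 1) * 10 + 1):(b * 10)
    sig_pop[ix, ix] <- 0.7
  }
  diag(sig_pop) <- 1
  expected_sd <- sqrt(diag(t(fm$loadings) %*% sig_pop %*% fm$loadings))
  sds <- apply(fs[ctrl, ], 2, sd)
  expect_true(all(sds >= 0.9 * expected_sd & sds <= 1.1 * expected_sd))
  expect_error(project_scores(fm, m[, -1]), "feature set")
})

test_that("quartile cut points depend only on the controls", {
  co <- small_cohort()
  blom <- blom_of(co)
  fm <- fit_pca_controls(blom, co$subjects$is_case == 0, eigen_cutoff = 1.5)
  fs <- project_scores(fm, blom)
  qa1 <- quartile_association(co, fs[, 1, drop = FALSE])
  # perturb every case's score: controls-only cut points leave the quartile
  # assignment of controls (hence the cuts) untouched
  fs2 <- fs
  case <- co$subjects$is_case == 1
  ctrl <- !case
  cuts1 <- quantile(fs[ctrl, 1], c(0.25, 0.5, 0.75))
  fs2[case, 1] <- fs2[case, 1] + 100
  cuts2 <- quantile(fs2[ctrl, 1], c(0.25, 0.5, 0.75))
  expect_identical(cuts1, cuts2)
  expect_named(qa1, c("factor", "or_q2", "ci_low_q2", "ci_high_q2",
                      "or_q3", "ci_low_q3", "ci_high_q3",
                      "or_q4", "ci_low_q4", "ci_high_q4",
                      "or_trend", "p_trend", "p_interaction"))
})

test_that("a factor carrying planted signal shows the expected quartile gradient", {
  co <- generate_cohort(cohort_spec(
    n_strata = 500, n_lipids = 30, n_clusters = 3, within_cluster_rho = 0.7,
    true_effects = setNames(rep(0.4, 10), as.character(1:10)),
    missing_rate = 0, seed = 23))
  blom <- blom_of(co)
  fm <- fit_pca_controls(blom, co$subjects$is_case == 0)
  fs <- project_scores(fm, blom)
  # the factor loading on the signal block
  sig_feats <- names(co$truth$effects)
  onto <- which.max(colSums(abs(fm$loadings[sig_feats, , drop = FALSE])))
  # orient so the factor increases with the signal features
  orient <- sign(sum(fm$loadings[sig_feats, onto]))
  qa <- quartile_association(co, fs[, onto, drop = FALSE] * orient)
  expect_gt(qa$or_q4, 1)
  expect_lt(qa$p_trend, 0.05)
  # null factor: a block without effects stays near OR 1
  null_f <- which.min(colSums(abs(fm$loadings[sig_feats, , drop = FALSE])))
  qa0 <- quartile_association(co, fs[, null_f, drop = FALSE])
  expect_gt(qa0$p_trend, 0.01)
})
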