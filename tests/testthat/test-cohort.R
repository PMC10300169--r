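test_that("generated cohorts satisfy the matched-design invariants across seeds", {
  for (seed in 1:40) {
    co <- generate_cohort(cohort_spec(n_strata = 15, n_lipids = 6,
                                      n_clusters = 2, missing_rate = 0.1,
                                      seed = seed))
    expect_silent(validate_cohort(co))
    sizes <- table(co$subjects$stratum_id)
    expect_true(all(sizes >= 2 & sizes <= 4))
    expect_equal(sum(co$subjects$is_case), 15)
    # truth partitions all features
    expect_setequal(names(co$truth$clusters), co$feature_names)
  }
})

test_that("fixed 1:1 matching yields exactly the requested strata", {
  co <- generate_cohort(cohort_spec(n_strata = 100, controls_per_case = 1,
                                    n_lipids = 5, n_clusters = 1, seed = 2))
  expect_equal(nrow(co$subjects), 200)
  expect_equal(length(unique(co$subjects$stratum_id)), 100)
  expect_equal(sum(co$subjects$is_case), 100)
  expect_true(all(table(co$subjects$stratum_id) == 2))
})

test_that("empirical within-block correlation matches the requested rho", {
  co <- generate_cohort(cohort_spec(n_strata = 1000, controls_per_case = 1,
                                    n_lipids = 30, n_clusters = 5,
                                    within_cluster_rho = 0.6,
                                    missing_rate = 0, seed = 7))
  z <- log(co$lipids)  # latent normal up to a per-feature shift
  cl <- co$truth$clusters
  rhos <- c()
  for (b in unique(cl)) {
    C <- cor(z[, names(cl)[cl == b]])
    rhos <- c(rhos, C[upper.tri(C)])
  }
  expect_lt(abs(mean(rhos) - 0.6), 0.05)
})

test_that("block correlation matrix is positive definite by construction", {
  spec <- cohort_spec(n_lipids = 20, n_clusters = 4, within_cluster_rho = 0.7,
                      between_cluster_rho = 0.1, seed = 1)
  sig <- lipanet:::block_sigma(spec)
  expect_silent(chol(sig))
})

test_that("a non-positive-definite correlation spec is rejected with a diagnostic", {
  expect_error(
    cohort_spec(n_lipids = 10, n_clusters = 2, within_cluster_rho = 0.1,
                between_cluster_rho = 0.9),
    "positive definite")
})

test_that("invalid effect maps and parameters are rejected", {
  expect_error(cohort_spec(true_effects = c("999" = 0.5), n_lipids = 10,
                           n_clusters = 2), "indices")
  expect_error(cohort_spec(missing_rate = 0.5), "missing_rate")
  expect_error(cohort_spec(covariate_effects = c(nonsense = 1)),
               "unsupported")
})

test_that("write/read round-trips a cohort including the missingness mask", {
  co <- generate_cohort(cohort_spec(n_strata = 30, n_lipids = 8,
                                    n_clusters = 2, missing_rate = 0.1,
                                    seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("subjects.csv", "lipids.csv",
                                               "truth.json", "manifest.json")))))
  back <- read_cohort(dir)
  expect_equal(back$subjects, co$subjects)
  expect_identical(is.na(back$lipids), is.na(co$lipids))
  expect_equal(unname(back$lipids), unname(co$lipids))
  expect_equal(back$truth$clusters, co$truth$clusters)
})

test_that("a stratum with two cases is rejected naming the stratum", {
  co <- generate_cohort(cohort_spec(n_strata = 10, n_lipids = 4,
                                    n_clusters = 1, controls_per_case = 2,
                                    seed = 5))
  bad <- which(co$subjects$stratum_id == 7 & co$subjects$is_case == 0)[1]
  co$subjects$is_case[bad] <- 1L
  expect_error(validate_cohort(co), "stratum 7")
})

test_that("empty-cell and NA missing-value tokens parse to the same mask", {
  co <- generate_cohort(cohort_spec(n_strata = 20, n_lipids = 6,
                                    n_clusters = 2, missing_rate = 0.15,
                                    seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)  # writes missing as empty cell
  a <- read_cohort(dir)
  txt <- readLines(file.path(dir, "lipids.csv"))
  txt <- gsub(",(?=(,|$))", ",NA", txt, perl = TRUE)  # empty cells -> NA token
  writeLines(txt, file.path(dir, "lipids.csv"))
  b <- read_cohort(dir)
  expect_identical(is.na(a$lipids), is.na(b$lipids))
  expect_equal(a$lipids, b$lipids)
})

test_that("control reuse flag duplicates compatible control profiles", {
  co <- generate_cohort(cohort_spec(n_strata = 150, n_lipids = 5,
                                    n_clusters = 1, reuse_controls = TRUE,
                                    reuse_rate = 0.5, seed = 11))
  expect_silent(validate_cohort(co))
  expect_gt(co$truth$n_reused_controls, 0)
})

test_that("null cohorts give calibrated per-lipid screens", {
  # pooled fraction of raw p < 0.05 over replicates stays in binomial noise
  frac <- c()
  for (seed in 1:25) {
    co <- generate_cohort(cohort_spec(n_strata = 120, n_lipids = 16,
                                      n_clusters = 4, missing_rate = 0,
                                      seed = 100 + seed))
    blom <- blom_of(co)
    scr <- screen_lipids(co, blom)
    frac <- c(frac, mean(scr$p_raw < 0.05, na.rm = TRUE))
  }
  m <- length(frac) * 16
  band <- 3 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(mean(frac) - 0.05), band + 0.005)
})
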