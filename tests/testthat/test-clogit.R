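test_that("1:1 binary exposure recovers the discordant-pair closed form", {
  set.seed(10)
  for (rep in 1:50) {
    a <- sample(1:12, 1); b <- sample(1:12, 1)
    d <- make_discordant_pairs(a, b, conc_exposed = sample(0:3, 1),
                               conc_unexposed = sample(0:3, 1))
    fit <- clogit_fit(d$x, d$y, d$strata)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients["exposure"]), log(a / b),
                 tolerance = 1e-6)
  }
  # the worked 6-vs-3 configuration
  d <- make_discordant_pairs(6, 3)
  expect_equal(unname(clogit_fit(d$x, d$y, d$strata)$coefficients),
               log(2), tolerance = 1e-8)
})

test_that("maximizer agrees with grid search over the enumerated likelihood", {
  set.seed(22)
  for (rep in 1:5) {
    sizes <- sample(2:4, 5, replace = TRUE)
    strata <- rep(seq_along(sizes), sizes)
    n <- length(strata)
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "z"))
    y <- unlist(lapply(sizes, function(s) sample(c(1, rep(0, s - 1)))))
    fit <- clogit_fit(x, y, strata)
    if (!fit$converged) next
    b_grid <- grid_clogit_max(x, y, strata)
    expect_equal(unname(fit$coefficients), b_grid, tolerance = 1e-4)
    # log-likelihood at the maximizer is at least the null value
    expect_gte(fit$loglik, fit$loglik_null - 1e-12)
  }
})

test_that("within-stratum constant predictors are dropped and reported", {
  strata <- rep(1:10, each = 2)
  set.seed(3)
  x <- cbind(match_var = rep(rnorm(10), each = 2), z = rnorm(20))
  y <- rep(c(1, 0), 10)
  fit <- clogit_fit(x, y, strata)
  expect_true("match_var" %in% fit$dropped)
  expect_false("match_var" %in% names(fit$coefficients))
  # all terms constant -> empty fit flagged, never an error
  fit0 <- clogit_fit(x[, "match_var", drop = FALSE], y, strata)
  expect_equal(length(fit0$coefficients), 0)
  expect_equal(fit0$flag, "all_terms_dropped")
})

test_that("coefficients match survival::clogit on a random matched design", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(14)
  sizes <- sample(2:4, 60, replace = TRUE)
  strata <- rep(seq_along(sizes), sizes)
  n <- length(strata)
  x <- cbind(z1 = rnorm(n), z2 = rnorm(n))
  eta <- 0.5 * x[, 1] - 0.3 * x[, 2]
  y <- rep(0, n)
  for (ix in split(seq_len(n), strata))
    y[ix[sample(length(ix), 1, prob = exp(eta[ix] - max(eta[ix])))]] <- 1
  ours <- clogit_fit(x, y, strata)
  ref <- survival::clogit(y ~ z1 + z2 + strata(st),
                          data = data.frame(x, y = y, st = strata))
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
})

test_that("separation is flagged, never returned silently", {
  # exposure perfectly predicts the case in every pair
  d <- make_discordant_pairs(8, 0, conc_exposed = 0, conc_unexposed = 0)
  d$x <- d$x[1:16, , drop = FALSE]; d$y <- d$y[1:16]; d$strata <- d$strata[1:16]
  fit <- clogit_fit(d$x, d$y, d$strata)
  expect_false(fit$converged)
  expect_match(fit$flag, "separation|max_iter")
})

test_that("parameter recovery: a 0.5 log-OR lipid effect is estimated within 0.1", {
  co <- generate_cohort(cohort_spec(n_strata = 1000, n_lipids = 10,
                                    n_clusters = 2,
                                    true_effects = c("5" = 0.5),
                                    missing_rate = 0, seed = 11))
  blom <- blom_of(co)
  fit <- clogit_fit(unclass_helper(blom)[, "lipid_005", drop = FALSE],
                    co$subjects$is_case, co$subjects$stratum_id)
  expect_lt(abs(fit$coefficients[["lipid_005"]] - 0.5), 0.1)
})

test_that("Wald test matches the df-1 identity and sums over orthogonal terms", {
  fit <- structure(list(
    coefficients = c(a = 0.8, b = -0.5, c = 0),
    se = c(a = 0.2, b = 0.25, c = 0.1),
    vcov = diag(c(0.04, 0.0625, 0.01)),
    converged = TRUE), class = "clogit_fit")
  dimnames(fit$vcov) <- list(c("a", "b", "c"), c("a", "b", "c"))
  wa <- wald_test(fit, "a")
  expect_equal(wa$statistic, (0.8 / 0.2)^2, tolerance = 1e-10)
  expect_equal(wa$df, 1)
  wc <- wald_test(fit, "c")
  expect_equal(wc$statistic, 0)
  expect_equal(wc$p, 1)
  # orthogonal (diagonal-covariance) terms: joint statistic is the sum
  wab <- wald_test(fit, c("a", "b"))
  expect_equal(wab$statistic,
               wa$statistic + wald_test(fit, "b")$statistic,
               tolerance = 1e-10)
  expect_equal(wab$df, 2)
  # singular sub-covariance errors
  fit$vcov["b", "b"] <- 0
  expect_error(wald_test(fit, "b"), "singular")
  expect_error(wald_test(fit, "nope"), "not in model")
})
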