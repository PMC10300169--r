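stratified_folds <- function(y, nfolds, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    foldid[ix] <- sample(rep_len(seq_len(nfolds), length(ix)))
  }
  foldid
}

enet_select <- function(x, y, alphas, nfolds, seed) {
  x <- as.matrix(x)
  single <- ncol(x) == 1
  pf <- rep(1, ncol(x))
  if (single) {  # glmnet needs >= 2 columns; pad with an excluded duplicate
    x <- cbind(x, .pad = x[, 1])
    pf <- c(1, Inf)
  }
  foldid <- stratified_folds(y, nfolds, seed)
  best <- NULL
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = a,
                            foldid = foldid, penalty.factor = pf,
                            type.measure = "deviance", standardize = TRUE)
    cvm <- cv$cvm[cv$index["min", 1]]
    if (is.null(best) || cvm < best$cvm)
      best <- list(cv = cv, alpha = a, cvm = cvm)
  }
  beta <- as.numeric(stats::coef(best$cv, s = "lambda.min"))[-1]
  names(beta) <- colnames(x)
  if (single) beta <- beta[1]
  list(coefficients = beta[beta != 0], alpha = best$alpha,
       lambda = best$cv$lambda.min)
}

#' Within-cluster elastic-net selection of case-control predictors
#'
#' For each of the top-ranked clusters, fits a penalized (elastic-net)
#' logistic regression of the case indicator on that cluster's
#' strata-deviation features, with the penalty chosen by tenfold
#' cross-validated deviance over a small mixing-parameter grid; the features
#' with nonzero coefficients at the selected penalty are the cluster's
#' robust predictors. An empty selection is allowed.
#'
#' @param deviations Strata-deviation subjects x features matrix.
#' @param outcome Case indicator per row.
#' @param partition Named feature -> cluster id vector.
#' @param clusters Cluster ids to process (e.g. [top_clusters()]).
#' @param alphas Elastic-net mixing grid (default `c(0.1, 0.5, 0.9)`).
#' @param nfolds CV folds (default 10), stratified by outcome.
#' @param seed Seed for fold assignment.
#' @return Named list cluster id -> character vector of selected features.
#' @export
enet_within_clusters <- function(deviations, outcome, partition, clusters,
                                 alphas = c(0.1, 0.5, 0.9), nfolds = 10,
                                 seed = 1L) {
  m <- unclass_matrix(deviations)
  y <- as.integer(as.logical(outcome))
  part <- partition[colnames(m)]
  out <- list()
  for (cl in clusters) {
    feats <- colnames(m)[which(part == cl)]
    if (!length(feats)) stop("cluster ", cl, " has no features")
    sel <- enet_select(m[, feats, drop = FALSE], y, alphas, nfolds,
                       seed + as.integer(cl))
    out[[as.character(cl)]] <- names(sel$coefficients)
  }
  out
}

#' Across-cluster elastic-net selection
#'
#' Pools all within-cluster selected features and repeats the
#' cross-validated elastic-net step over the pooled candidate list, yielding
#' the mutually independent network-wide predictors.
#'
#' @param deviations Strata-deviation subjects x features matrix.
#' @param outcome Case indicator per row.
#' @param candidates Character vector of candidate features (union of the
#'   within-cluster selections).
#' @param within_cluster_selected The per-cluster selections, carried into
#'   the result.
#' @inheritParams enet_within_clusters
#' @return A `selection_result`: `within_cluster_selected`,
#'   `across_cluster_selected`, `enet_coefficients`, `cv_params`.
#' @export
enet_across_clusters <- function(deviations, outcome, candidates,
                                 within_cluster_selected = NULL,
                                 alphas = c(0.1, 0.5, 0.9), nfolds = 10,
                                 seed = 1L) {
  cv_params <- list(folds = nfolds, alphas = alphas, seed = seed)
  if (!length(candidates)) {
    warning("no candidate features; empty selection")
    return(structure(list(within_cluster_selected = within_cluster_selected,
                          across_cluster_selected = character(0),
                          enet_coefficients = numeric(0),
                          cv_params = cv_params),
                     class = "selection_result"))
  }
  m <- unclass_matrix(deviations)
  y <- as.integer(as.logical(outcome))
  sel <- enet_select(m[, candidates, drop = FALSE], y, alphas, nfolds, seed)
  structure(list(within_cluster_selected = within_cluster_selected,
                 across_cluster_selected = names(sel$coefficients),
                 enet_coefficients = sel$coefficients,
                 cv_params = c(cv_params, list(alpha = sel$alpha,
                                               lambda = sel$lambda))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$across_cluster_selected),
      "network-wide predictors\n")
  if (length(x$enet_coefficients)) print(round(x$enet_coefficients, 4))
  invisible(x)
}

#' Leave-one-stratum-out cross-validated weighted multilipid score
#'
#' For each matched stratum s, a conditional logistic model (selected
#' features + adjustment covariates) is fitted on all strata except s, and
#' the subjects of s are scored as the dot product of their selected-feature
#' values with that fold's feature coefficients -- so no subject's score
#' uses weights estimated from its own stratum. The final association is a
#' conditional logistic model of the outcome on the SD-standardized score
#' plus covariates; effect modification by the 3-arm intervention is
#' assessed by adding score x intervention product terms and Wald-testing
#' them jointly (2 df).
#'
#' @param cohort A `matched_cohort`.
#' @param transformed Blom-scaled subjects x features matrix.
#' @param selected Character vector of score features (nonempty).
#' @param covariates Adjustment covariates, default [default_covariates()].
#' @return A `score_model`: `weights_per_fold` (strata x features matrix),
#'   `weight_medians`, `subject_scores` (raw and standardized), `or_per_sd`,
#'   `ci95`, `p`, `interaction_wald`, `failed_strata`.
#' @export
build_loocv_score <- function(cohort, transformed, selected,
                              covariates = default_covariates()) {
  if (!length(selected)) stop("selected features must be nonempty")
  m <- unclass_matrix(transformed)
  miss <- setdiff(selected, colnames(m))
  if (length(miss)) stop("selected feature(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  s <- cohort$subjects
  cov_x <- covariate_design(s, covariates)
  X <- cbind(m[, selected, drop = FALSE], cov_x)
  y <- s$is_case
  strata <- s$stratum_id
  ids <- unique(strata)

  full <- clogit_fit(X, y, strata)
  warm <- full$coefficients

  W <- matrix(NA_real_, length(ids), length(selected),
              dimnames = list(as.character(ids), selected))
  scores <- rep(NA_real_, nrow(s))
  failed <- character(0)
  for (k in seq_along(ids)) {
    hold <- strata == ids[k]
    fit <- tryCatch(
      clogit_fit(X[!hold, , drop = FALSE], y[!hold], strata[!hold],
                 init = warm),
      error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      failed <- c(failed, as.character(ids[k]))
      next
    }
    wk <- fit$coefficients[selected]
    wk[is.na(wk)] <- 0  # feature dropped in this fold
    W[k, ] <- wk
    scores[hold] <- drop(m[hold, selected, drop = FALSE] %*% wk)
  }
  if (all(is.na(scores))) stop("every leave-one-out fold failed")
  weight_medians <- apply(W, 2, stats::median, na.rm = TRUE)

  ok <- !is.na(scores)
  sd_score <- stats::sd(scores[ok])
  score_std <- (scores - mean(scores[ok])) / sd_score
  Xf <- cbind(score = score_std[ok], cov_x[ok, , drop = FALSE])
  fitf <- clogit_fit(Xf, y[ok], strata[ok])
  b <- fitf$coefficients[["score"]]
  se <- fitf$se[["score"]]

  inter <- s$intervention[ok]
  lev <- sort(unique(inter))
  iw <- NULL
  if (length(lev) == 3) {
    prods <- sapply(lev[-1], function(l) score_std[ok] * (inter == l))
    colnames(prods) <- paste0("score_x_", lev[-1])
    Xi <- cbind(Xf, prods)
    fiti <- clogit_fit(Xi, y[ok], strata[ok])
    if (fiti$converged)
      iw <- wald_test(fiti, colnames(prods))
  }

  structure(list(
    weights_per_fold = W,
    weight_medians = weight_medians,
    subject_scores = data.frame(subject_id = s$subject_id,
                                score = scores, score_std = score_std,
                                stringsAsFactors = FALSE),
    sd_score = sd_score,
    or_per_sd = exp(b),
    ci95 = c(exp(b - stats::qnorm(0.975) * se),
             exp(b + stats::qnorm(0.975) * se)),
    p = 2 * stats::pnorm(-abs(b / se)),
    interaction_wald = iw,
    failed_strata = failed,
    fit = fitf), class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("score_model:", ncol(x$weights_per_fold), "lipids; OR per SD",
      format(x$or_per_sd, digits = 3), "(95% CI",
      format(x$ci95[1], digits = 3), "-", format(x$ci95[2], digits = 3),
      "), p =", format(x$p, digits = 3), "\n")
  if (!is.null(x$interaction_wald))
    cat("  intervention interaction Wald p =",
        format(x$interaction_wald$p, digits = 3), "\n")
  if (length(x$failed_strata))
    cat("  ", length(x$failed_strata), "fold(s) failed and were excluded\n")
  invisible(x)
}
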