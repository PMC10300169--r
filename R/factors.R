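#' Varimax-rotated PCA of the lipid panel among controls
#'
#' Eigen-decomposes the controls' correlation matrix, retains the components
#' with eigenvalue above `eigen_cutoff` (default 2), and varimax-rotates the
#' retained loading block. Rotation preserves per-feature communalities and
#' the orthogonality of the block. Control means and SDs are stored so cases
#' can later be projected into the controls' coordinate system.
#'
#' @param transformed Subjects x features matrix (Blom-scaled).
#' @param control_mask Logical vector, `TRUE` for control rows.
#' @param eigen_cutoff Retention threshold on the eigenvalues (default 2).
#' @param loading_cutoff Absolute loading above which a feature is a
#'   relevant component of a factor (default 0.40).
#' @return A `factor_model`: `loadings` (rotated), `eigenvalues`, `retained`,
#'   `variance_explained`, `relevant_loadings`, `center`, `scale`,
#'   `rotation`. `retained = 0` gives an empty model with a warning.
#' @export
fit_pca_controls <- function(transformed, control_mask, eigen_cutoff = 2,
                             loading_cutoff = 0.40) {
  m <- unclass_matrix(transformed)
  stopifnot(length(control_mask) == nrow(m))
  ctrl <- m[control_mask, , drop = FALSE]
  if (nrow(ctrl) < 3) stop("need at least 3 controls")
  mu <- colMeans(ctrl)
  sdev <- apply(ctrl, 2, stats::sd)
  if (any(sdev == 0)) stop("constant feature among controls")
  C <- stats::cor(ctrl)
  ev <- eigen(C, symmetric = TRUE)
  retained <- sum(ev$values > eigen_cutoff)
  model <- structure(list(eigenvalues = ev$values, retained = retained,
                          variance_explained = sum(ev$values[ev$values > eigen_cutoff]) / ncol(m),
                          center = mu, scale = sdev,
                          loading_cutoff = loading_cutoff),
                     class = "factor_model")
  if (retained == 0) {
    warning("no component has eigenvalue > ", eigen_cutoff,
            "; empty factor model")
    model$loadings <- matrix(0, ncol(m), 0,
                             dimnames = list(colnames(m), NULL))
    model$relevant_loadings <- list()
    return(model)
  }
  L <- ev$vectors[, seq_len(retained), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(retained)]), retained)
  rot <- if (retained > 1) stats::varimax(L) else
    list(loadings = L, rotmat = diag(1))
  Lr <- matrix(as.numeric(rot$loadings), ncol(m), retained,
               dimnames = list(colnames(m),
                               paste0("factor_", seq_len(retained))))
  model$loadings <- Lr
  model$rotation <- rot$rotmat
  model$relevant_loadings <- apply(Lr, 2, function(l)
    colnames(m)[abs(l) > loading_cutoff], simplify = FALSE)
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat("factor_model:", x$retained, "retained factors explaining",
      sprintf("%.1f%%", 100 * x$variance_explained), "of total variance\n")
  invisible(x)
}

#' Project subjects onto the control-derived factors
#'
#' Standardizes each feature with the control means/SDs stored in the model
#' and forms loading-weighted sums -- the rotated loadings obtained among
#' controls applied identically to cases and controls.
#'
#' @param model A `factor_model` with `retained >= 1`.
#' @param transformed Subjects x features matrix on the same features.
#' @return Subjects x factors score matrix.
#' @export
project_scores <- function(model, transformed) {
  if (model$retained < 1) stop("model has no retained factors")
  m <- unclass_matrix(transformed)
  if (!identical(colnames(m), rownames(model$loadings)))
    stop("feature set does not match the factor model")
  z <- sweep(sweep(m, 2, model$center), 2, model$scale, "/")
  z %*% model$loadings
}

#' Quartile-based association of factor scores with the matched outcome
#'
#' Per factor: quartile cut points are computed from the controls only;
#' conditional logistic models with quartile indicators (plus covariates)
#' give ORs for quartiles 2-4 vs 1; the trend model replaces the indicators
#' with each quartile's median control score treated as a single continuous
#' term; effect modification is tested by adding trend x intervention
#' product terms (joint 2-df Wald).
#'
#' @param cohort A `matched_cohort`.
#' @param factor_scores Subjects x factors matrix from [project_scores()].
#' @param covariates Adjustment covariates, default [default_covariates()].
#' @return A data frame with one row per factor: ORs and CIs for Q2-Q4 vs
#'   Q1 (NA when non-estimable), trend OR and p, interaction p.
#' @export
quartile_association <- function(cohort, factor_scores,
                                 covariates = default_covariates()) {
  s <- cohort$subjects
  fs <- as.matrix(factor_scores)
  stopifnot(nrow(fs) == nrow(s))
  ctrl <- s$is_case == 0
  cov_x <- covariate_design(s, covariates)
  y <- s$is_case
  strata <- s$stratum_id
  lev <- sort(unique(s$intervention))

  res <- lapply(seq_len(ncol(fs)), function(f) {
    v <- fs[, f]
    cuts <- stats::quantile(v[ctrl], c(0.25, 0.5, 0.75))
    q <- findInterval(v, cuts) + 1L  # 1..4, cut points from controls only
    row <- list(factor = colnames(fs)[f] %||% paste0("factor_", f))
    ind <- sapply(2:4, function(k) as.numeric(q == k))
    colnames(ind) <- paste0("Q", 2:4)
    fit <- tryCatch(clogit_fit(cbind(ind, cov_x), y, strata),
                    error = function(e) NULL)
    for (k in 2:4) {
      term <- paste0("Q", k)
      if (!is.null(fit) && fit$converged &&
          term %in% names(fit$coefficients)) {
        b <- fit$coefficients[[term]]; se <- fit$se[[term]]
        row[[paste0("or_q", k)]] <- exp(b)
        row[[paste0("ci_low_q", k)]] <- exp(b - stats::qnorm(0.975) * se)
        row[[paste0("ci_high_q", k)]] <- exp(b + stats::qnorm(0.975) * se)
      } else {
        row[[paste0("or_q", k)]] <- NA_real_
        row[[paste0("ci_low_q", k)]] <- NA_real_
        row[[paste0("ci_high_q", k)]] <- NA_real_
      }
    }
    med <- vapply(1:4, function(k) stats::median(v[ctrl & q == k]), 0)
    trend <- med[q]
    tfit <- tryCatch(clogit_fit(cbind(trend = trend, cov_x), y, strata),
                     error = function(e) NULL)
    if (!is.null(tfit) && tfit$converged &&
        "trend" %in% names(tfit$coefficients)) {
      bt <- tfit$coefficients[["trend"]]; set <- tfit$se[["trend"]]
      row$or_trend <- exp(bt)
      row$p_trend <- 2 * stats::pnorm(-abs(bt / set))
    } else {
      row$or_trend <- NA_real_; row$p_trend <- NA_real_
    }
    row$p_interaction <- NA_real_
    if (length(lev) == 3 && !is.null(tfit) && tfit$converged) {
      prods <- sapply(lev[-1], function(l) trend * (s$intervention == l))
      colnames(prods) <- paste0("trend_x_", lev[-1])
      ifit <- tryCatch(clogit_fit(cbind(trend = trend, prods, cov_x),
                                  y, strata), error = function(e) NULL)
      if (!is.null(ifit) && ifit$converged &&
          all(colnames(prods) %in% names(ifit$coefficients))) {
        row$p_interaction <- wald_test(ifit, colnames(prods))$p
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
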