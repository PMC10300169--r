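#' Per-lipid conditional-logistic association screen
#'
#' Fits one conditional logistic model per lipid feature (the Blom-scaled
#' feature plus the adjustment covariates) over the matched strata, and
#' adjusts the per-feature Wald p-values for multiple testing with the
#' Benjamini-Yekutieli procedure, which controls the FDR under arbitrary
#' dependence between the lipid tests. Because features are on the SD scale,
#' `exp(coef)` is the odds ratio per SD.
#'
#' Features whose fit fails to converge are reported with missing p-values
#' and flagged; by default they still count toward the BY family size (the
#' conservative choice), controlled by `failed_in_family`.
#'
#' @param cohort A `matched_cohort` (supplies outcome, strata, covariates).
#' @param transformed Blom-scaled subjects x features matrix.
#' @param covariates Covariate names, default [default_covariates()].
#' @param failed_in_family Count failed fits toward the BY family size
#'   (default `TRUE`).
#' @return A `screen_result` data frame: feature, or, ci_low, ci_high,
#'   p_raw, p_by, n_informative_strata, flag. Attributes record dropped
#'   covariate terms and the family size.
#' @export
screen_lipids <- function(cohort, transformed,
                          covariates = default_covariates(),
                          failed_in_family = TRUE) {
  m <- unclass_matrix(transformed)
  stopifnot(nrow(m) == nrow(cohort$subjects))
  cov_x <- covariate_design(cohort$subjects, covariates)
  y <- cohort$subjects$is_case
  strata <- cohort$subjects$stratum_id

  # warm start every per-feature fit from the covariate-only solution
  base_fit <- clogit_fit(cov_x, y, strata)
  warm <- c(feature = 0, base_fit$coefficients)

  p <- ncol(m)
  out <- data.frame(feature = colnames(m), or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_raw = NA_real_, p_by = NA_real_,
                    n_informative_strata = NA_integer_, flag = "ok",
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    xj <- cbind(feature = m[, j], cov_x)
    fit <- tryCatch(clogit_fit(xj, y, strata, init = warm),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out$flag[j] <- conditionMessage(fit)
      next
    }
    out$n_informative_strata[j] <- fit$n_informative_strata
    if (!fit$converged || !"feature" %in% names(fit$coefficients)) {
      out$flag[j] <- if (!fit$converged) fit$flag else "feature_dropped"
      next
    }
    b <- fit$coefficients[["feature"]]
    se <- fit$se[["feature"]]
    out$or[j] <- exp(b)
    out$ci_low[j] <- exp(b - stats::qnorm(0.975) * se)
    out$ci_high[j] <- exp(b + stats::qnorm(0.975) * se)
    out$p_raw[j] <- 2 * stats::pnorm(-abs(b / se))
  }
  ok <- !is.na(out$p_raw)
  fam <- if (failed_in_family) p else sum(ok)
  out$p_by[ok] <- by_adjust(out$p_raw[ok], m_total = fam)
  structure(out, class = c("screen_result", "data.frame"),
            dropped_terms = base_fit$dropped, family_size = fam)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values inflated by
#' `c(m) = sum_{i<=m} 1/i`, valid under arbitrary dependence; capped at 1.
#' `m_total` lets the family size exceed the number of p-values supplied
#' (e.g. when failed fits count toward the family).
#'
#' @param p Numeric vector of raw p-values.
#' @param m_total Family size (default `length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
by_adjust <- function(p, m_total = length(p)) {
  if (!length(p)) return(numeric(0))
  if (m_total < length(p)) stop("m_total must be >= length(p)")
  if (m_total == length(p)) return(stats::p.adjust(p, method = "BY"))
  # p.adjust with an explicit family size n > length(p)
  stats::p.adjust(p, method = "BY", n = m_total)
}
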