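#' Conditional logistic regression for 1:m matched sets
#'
#' Maximizes the stratum-conditional likelihood
#' `prod_s exp(b'x_case_s) / sum_{j in s} exp(b'x_j_s)` by Newton-Raphson
#' with step-halving. Terms that are constant within every stratum (the
#' matching variables) carry no information and are dropped and reported.
#' Standard errors come from the inverse observed information.
#'
#' Separation (the likelihood maximized at infinite coefficients) is
#' flagged, never silent: on SD-scaled predictors a coefficient norm above
#' 15 signals a diverging path, and the fit is returned with
#' `converged = FALSE` and `flag = "separation"`.
#'
#' @param x Numeric design matrix (one row per subject) with column names.
#' @param y Case indicator (0/1 or logical), exactly one case per stratum.
#' @param strata Stratum label per row; each stratum needs >= 1 control.
#' @param init Optional warm-start coefficient vector (named or in column
#'   order of the retained terms).
#' @param tol Convergence tolerance on `|delta loglik|` (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return An object of class `clogit_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `loglik_null`, `converged`, `flag`, `dropped` (within-stratum
#'   constant terms), `n_strata`, `n_informative_strata`, `iterations`.
#' @export
clogit_fit <- function(x, y, strata, init = NULL, tol = 1e-10, max_iter = 50) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.integer(as.logical(y))
  if (length(y) != nrow(x) || length(strata) != nrow(x))
    stop("x, y and strata must have matching lengths")
  if (any(!is.finite(x))) stop("design matrix has non-finite entries")

  g <- match(strata, unique(strata))
  G <- max(g)
  sizes <- tabulate(g, G)
  ncase <- as.vector(rowsum(y, g))
  if (any(ncase != 1L))
    stop("each stratum must contain exactly 1 case; offending strata: ",
         paste(utils::head(unique(strata)[ncase != 1L], 5), collapse = ", "))
  if (any(sizes < 2L))
    stop("each stratum needs at least 1 control")

  # drop terms constant within every stratum (matching variables);
  # within-stratum variance via rowsum keeps this O(n k) and vectorized
  gm <- rowsum(x, g) / sizes
  wvar <- rowsum(x * x, g) - sizes * gm * gm
  wvar[wvar < 0] <- 0
  within_var <- apply(wvar, 2, max)
  dropped <- colnames(x)[within_var <= 1e-12]
  keep <- within_var > 1e-12
  xk <- x[, keep, drop = FALSE]
  k <- ncol(xk)
  case_rows <- which(y == 1L)
  n_inf <- if (k > 0) sum(rowSums(wvar[, keep, drop = FALSE] > 1e-12) > 0) else 0L

  ll_at <- function(beta) {
    eta <- drop(xk %*% beta)
    ctr <- as.vector(rowsum(eta, g)) / sizes  # stabilizing center
    w <- exp(eta - ctr[g])
    denom <- as.vector(rowsum(w, g))
    list(eta = eta, w = w, denom = denom,
         ll = sum(eta[case_rows]) - sum(log(denom) + ctr))
  }

  if (k == 0) {
    ll0 <- -sum(log(sizes))
    return(structure(list(coefficients = stats::setNames(numeric(0), character(0)),
                          se = numeric(0), vcov = matrix(0, 0, 0),
                          loglik = ll0, loglik_null = ll0, converged = TRUE,
                          flag = "all_terms_dropped", dropped = dropped,
                          n_strata = G, n_informative_strata = 0L,
                          iterations = 0L), class = "clogit_fit"))
  }

  beta <- numeric(k)
  if (!is.null(init)) {
    if (!is.null(names(init))) {
      hit <- intersect(names(init), colnames(xk))
      beta[match(hit, colnames(xk))] <- init[hit]
    } else if (length(init) == k) beta <- as.numeric(init)
  }
  ll0 <- ll_at(numeric(k))$ll
  st <- ll_at(beta)
  converged <- FALSE
  flag <- "ok"
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    p <- st$w / st$denom[g]
    mu <- rowsum(p * xk, g)
    grad <- colSums(xk[case_rows, , drop = FALSE]) - colSums(mu)
    H <- crossprod(xk, p * xk) - crossprod(mu)
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) { flag <- "singular_information"; break }
    step <- 1
    repeat {
      cand <- beta + step * delta
      st2 <- ll_at(cand)
      if (st2$ll >= st$ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    moved <- st2$ll - st$ll
    beta <- cand
    st <- st2
    if (sqrt(sum(beta^2)) > 15) {
      # on SD-scaled predictors a coefficient this large means the
      # likelihood is maximized at infinity (separation)
      flag <- "separation"; break
    }
    if (abs(moved) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged && flag == "ok") flag <- "max_iter"
  if (converged) {
    # perfect within-stratum prediction of every case: the conditional
    # likelihood approaches its supremum of 0 only under separation
    p_case <- st$w[case_rows] / st$denom[g[case_rows]]
    if (min(p_case) > 1 - 1e-6) {
      converged <- FALSE
      flag <- "separation"
    }
  }

  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  dimnames(vcov) <- list(colnames(xk), colnames(xk))
  se <- sqrt(pmax(diag(vcov), 0))
  structure(list(coefficients = stats::setNames(as.numeric(beta), colnames(xk)),
                 se = stats::setNames(se, colnames(xk)), vcov = vcov,
                 loglik = st$ll, loglik_null = ll0, converged = converged,
                 flag = flag, dropped = dropped, n_strata = G,
                 n_informative_strata = n_inf, iterations = iter),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat("clogit_fit:", length(x$coefficients), "terms,", x$n_strata, "strata (",
      x$n_informative_strata, "informative ), loglik", format(x$loglik),
      if (!x$converged) paste0("[", x$flag, "]") else "", "\n")
  if (length(x$coefficients)) {
    z <- x$coefficients / x$se
    print(data.frame(coef = x$coefficients, se = x$se, z = z,
                     p = 2 * stats::pnorm(-abs(z))))
  }
  if (length(x$dropped))
    cat("dropped (constant within strata):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Wald test of a set of model terms
#'
#' Computes `b' V^-1 b` over the selected coefficient sub-vector and
#' sub-covariance, with df = number of terms.
#'
#' @param fit A converged [clogit_fit()].
#' @param terms Character vector of coefficient names to test jointly.
#' @return List with `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, terms) {
  stopifnot(inherits(fit, "clogit_fit"))
  if (!fit$converged) stop("Wald test requires a converged fit")
  bad <- setdiff(terms, names(fit$coefficients))
  if (length(bad)) stop("terms not in model: ", paste(bad, collapse = ", "))
  b <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular sub-covariance for terms: ", paste(terms, collapse = ", ")))
  stat <- drop(t(b) %*% Vi %*% b)
  list(statistic = stat, df = length(terms),
       p = stats::pchisq(stat, df = length(terms), lower.tail = FALSE))
}
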