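new_transformed <- function(values, tag, provenance) {
  structure(values, transform_tag = tag, provenance = provenance,
            class = c("transformed_matrix", "matrix", "array"))
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat("transformed_matrix:", nrow(x), "subjects x", ncol(x), "features;",
      "tag =", attr(x, "transform_tag"), "\n  provenance:",
      paste(attr(x, "provenance"), collapse = " -> "), "\n")
  invisible(x)
}

provenance_of <- function(x) attr(x, "provenance") %||% "raw"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-minimum imputation of missing abundances
#'
#' Every missing entry of feature j is replaced by half of feature j's
#' minimum observed value -- the standard treatment when missingness reflects
#' values below the detection limit. Observed entries are unchanged.
#'
#' @param matrix Subjects x features numeric matrix, `NA` = missing.
#' @return A `transformed_matrix` with no missing entries.
#' @export
impute_half_min <- function(matrix) {
  m <- unclass_matrix(matrix)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing))
    stop("feature(s) entirely missing: ",
         paste(colnames(m)[all_missing], collapse = ", "))
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) m[na, j] <- min(m[!na, j]) / 2
  }
  new_transformed(m, "half_min_imputed",
                  c(provenance_of(matrix), "half_min_imputed"))
}

#' Blom rank-based inverse normal transformation
#'
#' Per feature, maps value i to `qnorm((r_i - 3/8) / (n + 1/4))` where `r_i`
#' is its tie-averaged rank. The result is approximately standard normal, so
#' downstream odds ratios are per SD of the feature. Ties (which half-minimum
#' imputation creates) receive averaged ranks, keeping the map well defined
#' and symmetric.
#'
#' @param matrix Complete subjects x features matrix (impute first).
#' @return A `transformed_matrix` on the SD scale.
#' @export
blom_transform <- function(matrix) {
  m <- unclass_matrix(matrix)
  if (anyNA(m)) stop("blom_transform requires a complete matrix; impute first")
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (max(v) == min(v))
      stop("constant feature (degenerate ranks): ",
           colnames(m)[j] %||% j)
    r <- rank(v, ties.method = "average")
    m[, j] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }
  new_transformed(m, "blom", c(provenance_of(matrix), "blom"))
}

#' Deviations from matching-stratum means
#'
#' Centers each feature on its matched stratum's mean, the transform used to
#' carry the matched design into the (unconditional) random-forest and
#' elastic-net stages: within a stratum only the case-vs-control contrast
#' remains.
#'
#' @param matrix Subjects x features matrix.
#' @param strata Stratum label per row.
#' @return A `transformed_matrix` whose within-stratum column sums are 0.
#' @export
strata_deviation <- function(matrix, strata) {
  m <- unclass_matrix(matrix)
  if (length(strata) != nrow(m)) stop("strata must label every row")
  sizes <- table(strata)
  if (any(sizes < 2))
    stop("singleton stratum (deviation identically 0): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  g <- match(strata, unique(strata))
  means <- rowsum(m, g) / as.vector(table(g))
  m <- m - means[g, , drop = FALSE]
  new_transformed(m, "strata_deviation",
                  c(provenance_of(matrix), "strata_deviation"))
}

unclass_matrix <- function(x) {
  m <- x
  attr(m, "transform_tag") <- NULL
  attr(m, "provenance") <- NULL
  class(m) <- c("matrix", "array")
  m
}
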