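#' Rank lipid clusters by grouped out-of-bag permutation importance
#'
#' Grows a classification forest (default 500 trees, per-tree subsample of
#' 2/3 drawn without replacement) on the strata-deviation lipid matrix, then
#' measures each cluster's importance as the increase in out-of-bag
#' misclassification when all of the cluster's member columns are jointly
#' permuted with one shared row permutation -- preserving the within-cluster
#' dependence structure while severing the link to the outcome. The
#' permutation is repeated `n_perm` times and the error increases averaged.
#' Clusters are ranked descending (rank 1 = largest increase; ties broken by
#' cluster id).
#'
#' OOB predictions (baseline and permuted) are majority votes over the trees
#' for which a row is out of bag, with ties going to the first class, so the
#' baseline is computed once under exactly the same vote rule as the
#' permuted passes.
#'
#' @param deviations Strata-deviation subjects x features matrix (see
#'   [strata_deviation()]).
#' @param outcome Case indicator per row (0/1 or logical).
#' @param partition Named integer vector feature -> cluster id covering all
#'   columns.
#' @param n_trees Number of trees (default 500).
#' @param sample_rate Per-tree subsample fraction, without replacement
#'   (default 2/3). Set `replace = TRUE` to bootstrap instead.
#' @param replace Sample with replacement (default `FALSE`).
#' @param n_perm Permutation repeats per cluster (default 10).
#' @param seed Seed for forest growth and permutations.
#' @return A `cluster_importance` object: `table` (cluster_id,
#'   member_features, oob_error_increase, rank), `baseline_oob_error`,
#'   `rf_params`.
#' @export
rank_clusters <- function(deviations, outcome, partition, n_trees = 500,
                          sample_rate = 2 / 3, replace = FALSE, n_perm = 10,
                          seed = 1L) {
  m <- unclass_matrix(deviations)
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2) stop("outcome is constant")
  if (is.null(names(partition))) {
    if (length(partition) != ncol(m)) stop("partition must cover all features")
    names(partition) <- colnames(m)
  }
  miss <- setdiff(colnames(m), names(partition))
  if (length(miss)) stop("partition missing feature(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  part <- partition[colnames(m)]
  cl_ids <- sort(unique(as.integer(part)))
  members <- split(seq_len(ncol(m)), as.integer(part))
  if (any(lengths(members) == 0)) stop("cluster with zero features")

  df <- data.frame(.y = factor(y, levels = c(0, 1)), m, check.names = FALSE)
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = df, num.trees = n_trees,
    sample.fraction = sample_rate, replace = replace, keep.inbag = TRUE,
    seed = seed, num.threads = 1, classification = TRUE,
    respect.unordered.factors = "ignore")
  inbag <- do.call(cbind, rf$inbag.counts)
  oob <- inbag == 0
  n_oob <- rowSums(oob)
  if (any(n_oob == 0))
    warning(sum(n_oob == 0), " row(s) never out of bag; excluded from the error")
  scored <- n_oob > 0

  oob_vote_error <- function(data_m) {
    pr <- stats::predict(rf, data.frame(data_m, check.names = FALSE),
                         predict.all = TRUE, num.threads = 1)$predictions
    votes1 <- rowSums((pr == 2) * oob)  # class "1" stored as level 2
    pred <- as.integer(votes1 > n_oob / 2)  # tie -> first class (0)
    mean(pred[scored] != y[scored])
  }
  baseline <- oob_vote_error(m)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed + 1L)
  n <- nrow(m)
  inc <- stats::setNames(numeric(length(cl_ids)), cl_ids)
  for (ci in seq_along(cl_ids)) {
    cols <- members[[as.character(cl_ids[ci])]]
    errs <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      perm <- sample.int(n)  # one shared permutation for all member columns
      mp <- m
      mp[, cols] <- m[perm, cols, drop = FALSE]
      errs[r] <- oob_vote_error(mp)
    }
    inc[ci] <- mean(errs) - baseline
  }
  rk <- rank(-inc, ties.method = "first")
  tab <- data.frame(
    cluster_id = cl_ids,
    member_features = vapply(members[as.character(cl_ids)], function(ix)
      paste(colnames(m)[ix], collapse = ","), character(1)),
    oob_error_increase = as.numeric(inc),
    rank = as.integer(rk),
    stringsAsFactors = FALSE)
  structure(list(table = tab[order(tab$rank), ],
                 baseline_oob_error = baseline,
                 rf_params = list(n_trees = n_trees, sample_rate = sample_rate,
                                  replace = replace, n_perm = n_perm,
                                  seed = seed)),
            class = "cluster_importance")
}

#' @export
print.cluster_importance <- function(x, ...) {
  cat("cluster_importance: baseline OOB error",
      format(x$baseline_oob_error, digits = 4), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Top-ranked clusters
#'
#' @param importance A `cluster_importance`.
#' @param k How many clusters to keep (default 7, the shape of a short
#'   "most important clusters" table).
#' @return Integer vector of cluster ids, best first.
#' @export
top_clusters <- function(importance, k = 7) {
  tab <- importance$table
  utils::head(tab$cluster_id[order(tab$rank)], k)
}
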