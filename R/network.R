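#' Partial correlation given a conditioning set
#'
#' From the inverse of the correlation submatrix over `(i, j, S)`.
#'
#' @param C Correlation matrix.
#' @param i,j Variable indices.
#' @param S Integer vector of conditioning indices (possibly empty).
#' @return Scalar partial correlation.
#' @export
partial_cor <- function(C, i, j, S = integer(0)) {
  if (!length(S)) return(C[i, j])
  sub <- C[c(i, j, S), c(i, j, S)]
  P <- tryCatch(solve(sub), error = function(e)
    solve(sub + diag(1e-10, nrow(sub))))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

fisher_z_p <- function(r, n, s_size) {
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  z <- sqrt(n - s_size - 3) * 0.5 * log((1 + r) / (1 - r))
  2 * stats::pnorm(-abs(z))
}

#' PC-algorithm skeleton over Gaussian variables
#'
#' Starts from the complete undirected graph and, for conditioning orders
#' `0..max_order`, removes an edge (i, j) whenever some subset S of the
#' current neighbors of i (excluding j) or of j (excluding i) with |S| equal
#' to the order makes the Fisher-z partial-correlation test non-significant
#' (p > alpha). The statistic is `sqrt(n - |S| - 3) * atanh(r)`. Adjacency is
#' frozen at the start of each order (the order-independent "stable"
#' variant) and subsets are enumerated lexicographically in the input column
#' order, so the output is deterministic given the column order and
#' invariant to row permutation of the data.
#'
#' @param data Subjects x variables numeric matrix (complete).
#' @param alpha Test level for conditional-independence tests (default 0.05).
#' @param max_order Maximum conditioning-set size (default 3).
#' @return List of class `pc_skeleton`: `adjacency` (logical matrix),
#'   `sepsets` (list keyed `"i|j"` of the separating set found, replayable
#'   against the recorded test), `n`, `params`.
#' @export
pc_skeleton <- function(data, alpha = 0.05, max_order = 3) {
  m <- unclass_matrix(data)
  if (anyNA(m)) stop("pc_skeleton requires complete data")
  if (max_order < 0) stop("max_order must be >= 0")
  n <- nrow(m)
  p <- ncol(m)
  C <- stats::cor(m)
  if (any(!is.finite(C))) stop("non-finite correlations (constant variable?)")
  labels <- colnames(m) %||% paste0("V", seq_len(p))

  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  sepsets <- list()

  for (ell in 0:max_order) {
    if (n <= ell + 3) break  # test undefined beyond this order
    snap <- adj  # freeze adjacency for this order
    deg <- rowSums(snap)
    if (all(deg - 1 < ell)) break
    for (i in seq_len(p - 1)) {
      for (j in seq((i + 1), p)) {
        if (!adj[i, j]) next
        cands <- list(setdiff(which(snap[i, ]), j),
                      setdiff(which(snap[j, ]), i))
        removed <- FALSE
        for (side in cands) {
          if (removed || length(side) < ell) next
          subsets <- if (ell == 0) list(integer(0))
            else if (length(side) == ell) list(side)  # combn(scalar, k) trap
            else utils::combn(side, ell, simplify = FALSE)
          for (S in subsets) {
            r <- partial_cor(C, i, j, S)
            if (fisher_z_p(r, n, length(S)) > alpha) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepsets[[paste0(i, "|", j)]] <-
                list(set = S, parcor = r, p = fisher_z_p(r, n, length(S)))
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
    }
  }
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, sepsets = sepsets, n = n,
                 params = list(alpha = alpha, max_order = max_order)),
            class = "pc_skeleton")
}

skeleton_edges <- function(skel) {
  w <- which(skel$adjacency & upper.tri(skel$adjacency), arr.ind = TRUE)
  data.frame(i = w[, 1], j = w[, 2])
}

#' Retain edges robust across two skeletons and above a partial-correlation
#' threshold
#'
#' An edge is kept iff it is present in both input skeletons and its partial
#' correlation on the pooled data -- conditioning on the union of the two
#' endpoints' remaining neighbors, capped at `max_order` strongest by
#' marginal correlation -- exceeds `threshold` in absolute value. This
#' emulates retaining edges "robust across two case-control studies" when
#' only one dataset is at hand: see [split_half_skeletons()].
#'
#' @param net_a,net_b `pc_skeleton` objects over the same node set.
#' @param data Pooled subjects x variables matrix for the partial
#'   correlations.
#' @param threshold Absolute partial-correlation cutoff (default 0.1).
#' @param max_order Cap on the conditioning-set size (default 3).
#' @return A `lipid_network`: nodes, edge table with `partial_correlation`
#'   and `robust` flag, an igraph graph, empty partition, and
#'   `algorithm_params` recording the conditioning rule.
#' @export
robust_edges <- function(net_a, net_b, data, threshold = 0.1, max_order = 3) {
  la <- rownames(net_a$adjacency); lb <- rownames(net_b$adjacency)
  if (!identical(la, lb)) stop("node sets of the two skeletons differ")
  m <- unclass_matrix(data)
  if (!identical(colnames(m), la)) stop("data columns do not match the skeletons")
  C <- stats::cor(m)
  inter <- net_a$adjacency & net_b$adjacency
  w <- which(inter & upper.tri(inter), arr.ind = TRUE)
  keep <- logical(nrow(w))
  pc <- numeric(nrow(w))
  if (nrow(w)) for (e in seq_len(nrow(w))) {
    i <- w[e, 1]; j <- w[e, 2]
    S <- setdiff(union(which(inter[i, ]), which(inter[j, ])), c(i, j))
    if (length(S) > max_order) {
      strength <- pmax(abs(C[i, S]), abs(C[j, S]))
      S <- S[order(-strength)][seq_len(max_order)]
      S <- sort(S)
    }
    pc[e] <- partial_cor(C, i, j, S)
    keep[e] <- abs(pc[e]) > threshold
  }
  edges <- data.frame(node_a = la[w[, 1]], node_b = la[w[, 2]],
                      partial_correlation = pc, robust = keep,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = la))
  igraph::E(g)$partial_correlation <- edges$partial_correlation
  structure(list(nodes = la, edges = edges, graph = g,
                 partition = NULL,
                 algorithm_params = list(
                   alpha = net_a$params$alpha,
                   max_order = net_a$params$max_order,
                   threshold = threshold,
                   conditioning = "union of endpoint neighbors in the intersected skeleton, capped at max_order strongest by marginal correlation",
                   walktrap_steps = NA)),
            class = "lipid_network")
}

#' @export
print.lipid_network <- function(x, ...) {
  cat("lipid_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (!is.null(x$partition))
    cat(";", max(x$partition), "walktrap clusters")
  cat("\n")
  invisible(x)
}

#' Learn two skeletons on random halves of the matched strata
#'
#' Stand-in for a companion case-control study on the same platform: the
#' strata are split at random into two halves and a PC skeleton is learned
#' on each, so that edge robustness means stability across independent
#' halves of the data.
#'
#' @param transformed Subjects x features matrix.
#' @param strata Stratum label per row (splitting keeps strata intact).
#' @param alpha,max_order Passed to [pc_skeleton()].
#' @param seed Seed for the split.
#' @return List with elements `a` and `b` (`pc_skeleton` objects) and
#'   `split` (stratum ids in half `a`).
#' @export
split_half_skeletons <- function(transformed, strata, alpha = 0.05,
                                 max_order = 3, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  ids <- unique(strata)
  half <- sample(ids, floor(length(ids) / 2))
  in_a <- strata %in% half
  m <- unclass_matrix(transformed)
  list(a = pc_skeleton(m[in_a, , drop = FALSE], alpha, max_order),
       b = pc_skeleton(m[!in_a, , drop = FALSE], alpha, max_order),
       split = half)
}

#' Walktrap community detection on the lipid network
#'
#' Agglomerates nodes by short-random-walk distance and cuts the dendrogram
#' at maximum modularity. Isolated nodes become singleton clusters. Cluster
#' ids are dense from 1, ordered by each cluster's first node in input
#' order.
#'
#' @param network A `lipid_network` (or igraph graph).
#' @param steps Random-walk length (default 4, the algorithm's canonical
#'   choice).
#' @return The network with `partition` filled (named integer vector), or
#'   the bare partition when given an igraph graph.
#' @export
walktrap_clusters <- function(network, steps = 4) {
  if (steps < 1) stop("steps must be >= 1")
  g <- if (inherits(network, "lipid_network")) network$graph else network
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  memb <- rep(NA_integer_, length(nodes))
  names(memb) <- nodes
  if (igraph::ecount(g) == 0) {
    warning("empty graph: every node is a singleton cluster")
    memb[] <- seq_along(nodes)
  } else {
    sub <- igraph::induced_subgraph(g, which(deg > 0))
    wt <- igraph::cluster_walktrap(sub, steps = steps)
    memb[igraph::V(sub)$name] <- igraph::membership(wt)
    iso <- which(is.na(memb))
    if (length(iso)) memb[iso] <- max(memb, na.rm = TRUE) + seq_along(iso)
  }
  # dense ids ordered by first appearance
  memb <- match(memb, unique(memb))
  names(memb) <- nodes
  if (inherits(network, "lipid_network")) {
    network$partition <- memb
    network$algorithm_params$walktrap_steps <- steps
    network
  } else memb
}

#' Write a lipid network as edge-list and partition TSVs (plus GraphML)
#'
#' @param network A `lipid_network` with a partition.
#' @param edge_path,partition_path Output TSV paths.
#' @param graphml_path Optional GraphML path for graph tools.
#' @return Invisibly, the edge path.
#' @export
write_network <- function(network, edge_path, partition_path,
                          graphml_path = NULL) {
  e <- network$edges
  write_stage_tsv(e, edge_path)
  part <- data.frame(feature = names(network$partition),
                     cluster_id = as.integer(network$partition))
  write_stage_tsv(part, partition_path)
  if (!is.null(graphml_path)) {
    g <- network$graph
    igraph::V(g)$cluster <- as.integer(network$partition[igraph::V(g)$name])
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
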