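test_that("PC skeleton identifies the chain structure and its separation set", {
  set.seed(12)
  n <- 5000
  X <- rnorm(n); Y <- 0.8 * X + rnorm(n); Z <- 0.8 * Y + rnorm(n)
  sk <- pc_skeleton(cbind(X = X, Y = Y, Z = Z))
  expect_true(sk$adjacency["X", "Y"])
  expect_true(sk$adjacency["Y", "Z"])
  expect_false(sk$adjacency["X", "Z"])
  ss <- sk$sepsets[["1|3"]]
  expect_equal(ss$set, 2L)       # separated by Y
  expect_gt(ss$p, sk$params$alpha)
})

test_that("mutually independent features give an empty skeleton", {
  set.seed(5)
  d <- matrix(rnorm(5000 * 3), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(sum(pc_skeleton(d)$adjacency), 0)
})

test_that("skeleton of a sparse random DAG is close to the true skeleton", {
  dag <- sim_dag(p = 10, n = 5000, edge_prob = 0.2, seed = 3)
  sk <- pc_skeleton(dag$data)
  expect_lte(structural_hamming(sk$adjacency, dag$skeleton), 2)
})

test_that("skeleton is invariant under row permutation and its sepsets replay", {
  dag <- sim_dag(p = 6, n = 800, edge_prob = 0.3, seed = 4)
  sk <- pc_skeleton(dag$data)
  set.seed(9)
  sk2 <- pc_skeleton(dag$data[sample(nrow(dag$data)), ])
  expect_identical(sk$adjacency, sk2$adjacency)
  # replayable audit: every recorded separation test is non-significant
  C <- cor(dag$data)
  for (key in names(sk$sepsets)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    ss <- sk$sepsets[[key]]
    r <- partial_cor(C, ij[1], ij[2], ss$set)
    expect_equal(r, ss$parcor, tolerance = 1e-12)
    expect_gt(ss$p, sk$params$alpha)
  }
  expect_error(pc_skeleton(dag$data, max_order = -1), "max_order")
})

test_that("robust edges require presence in both skeletons and pass the threshold", {
  set.seed(6)
  n <- 2000
  A <- rnorm(n)
  B <- 0.6 * A + rnorm(n)          # strong edge, parcor ~ 0.5
  C <- 0.1 * B + rnorm(n) * 2.2    # weak edge, parcor ~ 0.045 < 0.1
  d <- cbind(A = A, B = B, C = C)
  ska <- pc_skeleton(d, alpha = 0.2)
  # a second skeleton missing A-B: only edges in both survive
  skb <- ska
  skb$adjacency["A", "B"] <- skb$adjacency["B", "A"] <- FALSE
  net <- robust_edges(ska, skb, d, threshold = 0.1)
  expect_false(any(net$edges$node_a == "A" & net$edges$node_b == "B"))
  # with both skeletons full, the strong edge passes, the weak edge fails
  net2 <- robust_edges(ska, ska, d, threshold = 0.1)
  pairs <- paste(net2$edges$node_a, net2$edges$node_b)
  expect_true("A B" %in% pairs)
  expect_false("B C" %in% pairs)
  # the kept-edge set shrinks monotonically in the threshold
  sizes <- vapply(c(0, 0.1, 0.3, 0.6),
                  function(t) nrow(robust_edges(ska, ska, d, t)$edges), 0)
  expect_true(all(diff(sizes) <= 0))
  # node-set mismatch is an error
  skc <- pc_skeleton(d[, c(1, 2)], alpha = 0.2)
  expect_error(robust_edges(ska, skc, d, 0.1), "node sets")
})

test_that("split-half robust edges are contained in each half's skeleton", {
  co <- small_cohort()
  blom <- blom_of(co)
  halves <- split_half_skeletons(blom, co$subjects$stratum_id, seed = 9)
  net <- robust_edges(halves$a, halves$b, blom, threshold = 0.1)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$node_a[e]; j <- net$edges$node_b[e]
    expect_true(halves$a$adjacency[i, j])
    expect_true(halves$b$adjacency[i, j])
  }
  expect_gt(nrow(net$edges), 0)
})

test_that("walktrap separates disjoint cliques and isolates exactly", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("n", 1:10)
  memb <- walktrap_clusters(g)
  expect_equal(max(memb), 2)
  expect_equal(unname(memb), rep(1:2, each = 5))
  # single edge plus isolate
  g2 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g2)$name <- c("A", "B", "C")
  g2 <- igraph::add_edges(g2, c("A", "B"))
  memb2 <- walktrap_clusters(g2)
  expect_equal(unname(memb2[c("A", "B")]), c(1, 1))
  expect_equal(unname(memb2["C"]), 2)
  # empty graph: all singletons with a warning
  g3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g3)$name <- c("A", "B", "C")
  expect_warning(memb3 <- walktrap_clusters(g3), "singleton")
  expect_equal(unname(memb3), 1:3)
  expect_error(walktrap_clusters(g, steps = 0), "steps")
})

test_that("walktrap recovers a planted partition with high adjusted Rand index", {
  set.seed(4)
  g <- igraph::sample_sbm(50, pref.matrix = matrix(0.02, 5, 5) + diag(0.78, 5),
                          block.sizes = rep(10, 5))
  igraph::V(g)$name <- paste0("n", 1:50)
  memb <- walktrap_clusters(g, steps = 4)
  expect_gte(adjusted_rand(memb, rep(1:5, each = 10)), 0.9)
})

test_that("network clusters align with the generating correlation blocks", {
  co <- small_cohort()
  blom <- blom_of(co)
  halves <- split_half_skeletons(blom, co$subjects$stratum_id, seed = 2)
  net <- walktrap_clusters(robust_edges(halves$a, halves$b, blom, 0.1))
  truth <- co$truth$clusters[net$nodes]
  # majority-label purity within detected clusters
  purity <- vapply(split(truth, net$partition),
                   function(v) max(table(v)) / length(v), 0)
  expect_gte(stats::weighted.mean(purity, lengths(split(truth, net$partition))),
             0.8)
})
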