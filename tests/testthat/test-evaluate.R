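test_that("nmi handles identity, relabelling and independence", {
  a <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2)
  expect_equal(nmi(a, a), 1)
  relabel <- c(g1 = 7, g2 = 7, g3 = 3, g4 = 3)
  expect_equal(nmi(a, relabel), 1)
  # independent balanced splits share no information
  b <- c(g1 = 1, g2 = 2, g3 = 1, g4 = 2)
  expect_equal(nmi(a, b), 0)
  expect_equal(nmi(a, b), nmi(b, a))
  expect_error(nmi(a, c(zz = 1, yy = 1)), "no genes shared")
})

test_that("nmi degenerate cases are pinned", {
  one <- c(g1 = 1, g2 = 1, g3 = 1)
  two <- c(g1 = 1, g2 = 1, g3 = 2)
  expect_equal(nmi(one, one), 1)   # both single-cluster
  expect_equal(nmi(one, two), 0)   # exactly one single-cluster
  # unassigned genes are singletons, not a shared module
  zeros <- c(g1 = 0, g2 = 0, g3 = 0)
  expect_lt(nmi(zeros, two), 1)
})

test_that("rewiring recall score matches hand-evaluated cases", {
  # |V| = 10, |U| = 2: pair1 together in a 2-module (w = 5), pair2 split
  genes <- paste0("g", 1:10)
  p <- module_partition(stats::setNames(c(1, 1, 2, 3, rep(0, 6)), genes))
  pairs <- data.frame(original = c("g1", "g3"),
                      duplicate = c("g2", "g4"))
  expect_equal(rewiring_recall_score(p, pairs, 10), 0.5)
  # all pairs split -> 0
  p2 <- module_partition(stats::setNames(c(1, 2, 1, 2, 1, 2, rep(0, 4)),
                                         genes))
  expect_equal(rewiring_recall_score(p2, pairs, 10), 0)
  # module 0 never counts as a shared module
  p3 <- module_partition(stats::setNames(rep(0, 10), genes))
  expect_equal(rewiring_recall_score(p3, pairs, 10), 0)
  expect_error(rewiring_recall_score(p, pairs[0, ], 10), "no pairs")
  expect_error(rewiring_recall_score(p, pairs, 0), "positive")
})

test_that("ideal pair assignment scores exactly 1", {
  net <- clean_network(random_digraph(40, 0.1, seed = 21))
  rw <- duplicate_and_rewire(net, n = 8, rewire_prob = 0, seed = 22)
  p <- ideal_pair_partition(rw)
  expect_identical(rewiring_recall_score(p, rw$pairs,
                                         length(rw$network$nodes)), 1)
})

test_that("RRS vectorized implementation matches a literal transcription", {
  rrs_literal <- function(partition, pairs, total_nodes) {
    a <- stats::setNames(as.integer(partition), names(partition))
    sizes <- table(a[a > 0])
    num <- 0
    for (i in seq_len(nrow(pairs))) {
      u <- a[[pairs[[1]][i]]]; v <- a[[pairs[[2]][i]]]
      s_i <- as.integer(u > 0 && u == v)
      if (s_i == 1) num <- num + total_nodes / sizes[[as.character(u)]]
    }
    num / (total_nodes * nrow(pairs) / 2)
  }
  for (seed in 1:20) {
    with_seed_t(seed, {
      n <- 30
      genes <- paste0("g", 1:n)
      p <- module_partition(stats::setNames(
        sample(0:5, n, replace = TRUE), genes))
      pairs <- data.frame(original = sample(genes, 6),
                          duplicate = sample(genes, 6))
      expect_equal(rewiring_recall_score(p, pairs, n),
                   rrs_literal(p, pairs, n))
    })
  }
})

test_that("bipartite transform splits nodes by edge role", {
  net <- directed_network(c("A", "B"), c("B", "C"))
  bp <- bipartite_transform(net)
  expect_setequal(bp$head_nodes, c("A_h", "B_h"))
  expect_setequal(bp$tail_nodes, c("B_t", "C_t"))
  expect_equal(nrow(bp$edges), nrow(net$edges))
  # B has both roles and appears on both sides
  expect_true("B_h" %in% bp$head_nodes && "B_t" %in% bp$tail_nodes)
  labels <- c(A_h = 1, B_h = 1, B_t = 2, C_t = 2)
  merged <- merge_bipartite_labels(labels)
  expect_equal(merged$B, c(1L, 2L))
  expect_equal(merged$A, 1L)
})

test_that("wt similarity matches an explicit matrix-power oracle", {
  net <- directed_network(c("A", "B"), c("B", "C"))
  # oracle: adjacency + I, row-normalize, square
  A <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 1))
  T_ <- A / rowSums(A)
  P <- T_ %*% T_
  got <- wt_probability_matrix(net, steps = 2)
  d <- unname(attr(got, "degree"))
  got_m <- matrix(as.numeric(got), 3, 3)
  expect_equal(got_m, P, tolerance = 1e-12)
  expect_equal(d, rowSums(A))
  D <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    D[i, j] <- sqrt(sum((P[i, ] - P[j, ])^2) / d[i])
  D_sym <- (D + t(D)) / 2
  s <- wt_similarity(net, steps = 2)
  off <- upper.tri(D)
  expect_equal(as.matrix(s)[off], (1 - D_sym)[off], tolerance = 1e-12)
})

test_that("wt transition rows sum to 1 and isolated self-pairs score 1", {
  net <- clean_network(random_digraph(15, 0.2, seed = 23))
  P1 <- wt_probability_matrix(net, steps = 1)
  expect_equal(unname(rowSums(P1)), rep(1, length(net$nodes)))
  P4 <- wt_probability_matrix(net, steps = 4)
  expect_equal(unname(rowSums(P4)), rep(1, length(net$nodes)))
  # identical probability rows give D = 0, S = 1 (tested via the formula)
  s <- wt_similarity(net, steps = 2)
  expect_true(all(as.matrix(s) <= 1 + 1e-12))
})

test_that("roc_auc spans perfect, inverted and chance separation", {
  expect_equal(roc_auc(c(3, 4, 5), c(0, 1, 2))$auc, 1)
  expect_equal(roc_auc(c(0, 1), c(2, 3))$auc, 0)
  with_seed_t(24, {
    auc <- roc_auc(stats::rnorm(10000), stats::rnorm(10000))$auc
    expect_equal(auc, 0.5, tolerance = 0.02)
  })
  # ties get the midpoint convention
  expect_equal(roc_auc(c(1, 1), c(1, 1))$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  curve <- roc_auc(c(2, 3), c(1, 2))$curve
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
})

test_that("compare_tree_cuts searches the full grid and reports maxima", {
  sim <- generate_simulated_network(3, 4, 8, 60, prob = 0.9, seed = 25)
  net <- clean_network(sim$network)
  rw <- duplicate_and_rewire(net, n = 6, rewire_prob = 0.3, seed = 26)
  cleaned <- clean_network(rw$network)
  s <- combine_similarity(jaccard_similarity(cleaned, "in"),
                          jaccard_similarity(cleaned, "out"))
  d <- to_dissimilarity(s)
  rep_ <- compare_tree_cuts(d, rw)
  expect_equal(nrow(rep_$static), 11L)
  expect_equal(nrow(rep_$dynamic), 11L * 5L)
  expect_gte(rep_$best_static$rrs, max(rep_$static$rrs) - 1e-12)
  expect_gte(rep_$best_dynamic$rrs, max(rep_$dynamic$rrs) - 1e-12)
  expect_true(all(rep_$static$rrs >= 0 & rep_$static$rrs <= 1))
})
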