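# hand-checked values frozen from the brute-force set-arithmetic oracle

test_that("jaccard similarity matches hand-computed overlaps", {
  # out-neighbors: A={x,y,z}, B={y,z,w} -> 2 common / 4 union = 0.5
  net <- directed_network(c("A", "A", "A", "B", "B", "B"),
                          c("x", "y", "z", "y", "z", "w"))
  s <- jaccard_similarity(net, "out")
  expect_equal(s$values["A", "B"], 0.5)
  # neither A nor B has in-neighbors -> 0
  expect_equal(jaccard_similarity(net, "in")$values["A", "B"], 0)
  # identical nonempty sets -> 1
  net2 <- directed_network(c("A", "A", "B", "B"), c("x", "y", "x", "y"))
  expect_equal(jaccard_similarity(net2, "out")$values["A", "B"], 1)
})

test_that("geometric similarity matches the formula", {
  net <- directed_network(c("A", "A", "A", "B", "B", "B"),
                          c("x", "y", "z", "y", "z", "w"))
  expect_equal(geometric_similarity(net, "out")$values["A", "B"], 4 / 9)
  # either side empty -> 0
  expect_equal(geometric_similarity(net, "in")$values["A", "x"], 0)
  net2 <- directed_network(c("A", "A", "B", "B"), c("x", "y", "x", "y"))
  expect_equal(geometric_similarity(net2, "out")$values["A", "B"], 1)
})

test_that("inverse log-weighted similarity uses natural log of total degree", {
  # common out-neighbor c with total degree 4 (2 in + 2 out)
  net <- directed_network(c("A", "B", "c", "c"),
                          c("c", "c", "p", "q"))
  s <- invlogweighted_similarity(net, "out")
  expect_equal(s$values["A", "B"], 1 / log(4), tolerance = 1e-12)
  # no common neighbors -> 0
  expect_equal(s$values["A", "p"], 0)
  # two common neighbors with total degrees 3 and 8
  net2 <- directed_network(
    c("A", "A", "B", "B", "c1", rep("c2", 6)),
    c("c1", "c2", "c1", "c2", "u1", paste0("v", 1:6)))
  expect_equal(invlogweighted_similarity(net2, "out")$values["A", "B"],
               1 / log(3) + 1 / log(8), tolerance = 1e-12)
})

test_that("all indices match the brute-force oracle on random digraphs", {
  for (seed in 1:25) {
    net <- clean_network(random_digraph(sample(5:30, 1), 0.15,
                                        seed = seed))
    for (dir in c("in", "out")) {
      oracle <- oracle_similarity(net, dir)
      for (idx in names(oracle)) {
        got <- as.matrix(neighbor_similarity(net, idx, dir))
        expect_equal(got, oracle[[idx]], tolerance = 1e-12,
                     info = sprintf("seed %d %s %s", seed, idx, dir))
      }
    }
  }
})

test_that("similarity matrices are symmetric and label-equivariant", {
  net <- clean_network(random_digraph(15, 0.2, seed = 42))
  s <- jaccard_similarity(net, "out")
  expect_equal(as.matrix(s), t(as.matrix(s)))
  # relabelling nodes permutes rows/columns identically
  perm_names <- stats::setNames(paste0("n", seq_along(net$nodes)),
                                net$nodes)
  shuffle <- with_seed_t(1, sample.int(nrow(net$edges)))
  net_p <- directed_network(perm_names[net$edges$regulator[shuffle]],
                            perm_names[net$edges$target[shuffle]])
  sp <- as.matrix(jaccard_similarity(net_p, "out"))
  expect_equal(unname(sp[perm_names[net$nodes], perm_names[net$nodes]]),
               unname(as.matrix(s)))
})

test_that("jaccard and geometric hit 1 together iff neighbor sets match", {
  net <- clean_network(random_digraph(20, 0.25, seed = 9))
  j <- as.matrix(jaccard_similarity(net, "out"))
  g <- as.matrix(geometric_similarity(net, "out"))
  expect_equal(j == 1, g == 1)
})

test_that("combine_similarity applies weights and validates inputs", {
  net <- directed_network(c("A", "B", "x"), c("x", "x", "A"))
  s_in <- jaccard_similarity(net, "in")
  s_out <- jaccard_similarity(net, "out")
  comb <- combine_similarity(s_in, s_out, 1, 1)
  expect_equal(comb$values["A", "B"],
               s_in$values["A", "B"] + s_out$values["A", "B"])
  proj <- combine_similarity(s_in, s_out, 1, 0)
  expect_equal(as.matrix(proj), as.matrix(s_in))
  g_out <- geometric_similarity(net, "out")
  expect_error(combine_similarity(s_in, g_out), "indices differ")
  expect_error(combine_similarity(s_in, s_out, 0, 0), "not both zero")
})

test_that("to_dissimilarity normalizes by the off-diagonal maximum", {
  net <- directed_network(c("A", "A", "B", "B", "C"),
                          c("x", "y", "x", "y", "x"))
  s <- combine_similarity(jaccard_similarity(net, "in"),
                          jaccard_similarity(net, "out"))
  d <- to_dissimilarity(s)
  mx <- max(as.matrix(s))
  expect_equal(d$source_max, mx)
  expect_equal(d$values["A", "B"], 0)            # the maximal pair
  expect_equal(d$values["A", "x"], 1)            # zero-similarity pair
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_equal(diag(d$values), stats::setNames(rep(0, 5), s$genes))
  # all-zero similarity -> no signal
  chain <- directed_network(c("A", "B"), c("B", "C"))
  s0 <- combine_similarity(jaccard_similarity(chain, "in"),
                           jaccard_similarity(chain, "out"))
  expect_error(to_dissimilarity(s0), "no co-regulation signal")
})

test_that("sparse and dense paths agree", {
  net <- clean_network(random_digraph(25, 0.2, seed = 3))
  for (idx in c("jaccard", "geometric", "invlogweighted")) {
    dense <- neighbor_similarity(net, idx, "out", sparse = FALSE)
    sp <- neighbor_similarity(net, idx, "out", sparse = TRUE)
    expect_s4_class(sp$values, "Matrix")
    expect_equal(as.matrix(sp), as.matrix(dense), tolerance = 1e-14)
  }
})
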