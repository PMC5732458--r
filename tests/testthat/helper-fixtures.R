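# Fixture builders and independent oracles shared across the test files.
# All fixtures are generated in code; nothing is read from disk.

# Random simple digraph with <= n nodes: each ordered non-self pair kept
# with probability p; guaranteed non-empty.
random_digraph <- function(n, p = 0.1, seed = NULL) {
  with_seed_t(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample.int(length(keep), 2L)] <- TRUE
    directed_network(paste0("g", pairs$from[keep]),
                     paste0("g", pairs$to[keep]))
  })
}

with_seed_t <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Brute-force similarity oracle: explicit set arithmetic over adjacency
# lists, all three indices at once. Deliberately independent of the
# package's matrix-algebra implementation.
oracle_similarity <- function(net, direction) {
  nodes <- net$nodes
  e <- net$edges
  nb <- lapply(nodes, function(v)
    if (direction == "out") e$target[e$regulator == v]
    else e$regulator[e$target == v])
  names(nb) <- nodes
  deg_tot <- vapply(nodes, function(v)
    sum(e$regulator == v) + sum(e$target == v), numeric(1))
  n <- length(nodes)
  jac <- geo <- ilw <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(nb[[i]], nb[[j]])
    un <- union(nb[[i]], nb[[j]])
    if (length(un) > 0)
      jac[i, j] <- jac[j, i] <- length(common) / length(un)
    if (length(nb[[i]]) > 0 && length(nb[[j]]) > 0)
      geo[i, j] <- geo[j, i] <-
        length(common)^2 / (length(nb[[i]]) * length(nb[[j]]))
    if (length(common) > 0)
      ilw[i, j] <- ilw[j, i] <- sum(1 / log(deg_tot[common]))
  }
  list(jaccard = jac, geometric = geo, invlogweighted = ilw)
}

# Two groups of regulators with identical within-group target sets and no
# cross-group overlap: recovery of the two groups is forced.
two_block_network <- function() {
  edges <- rbind(
    expand.grid(r = c("a1", "a2", "a3"), t = paste0("x", 1:4)),
    expand.grid(r = c("b1", "b2", "b3"), t = paste0("y", 1:4)))
  directed_network(as.character(edges$r), as.character(edges$t))
}

# i.i.d. Gaussian expression matrix: the global null for co-expression
gaussian_expression <- function(n_genes, n_samples, seed = 1) {
  with_seed_t(seed, matrix(stats::rnorm(n_genes * n_samples),
                           nrow = n_genes,
                           dimnames = list(paste0("g", seq_len(n_genes)),
                                           paste0("s", seq_len(n_samples)))))
}

# partition placing every (original, duplicate) pair in its own 2-gene
# module; all other nodes unassigned
ideal_pair_partition <- function(rewired) {
  nodes <- rewired$network$nodes
  v <- stats::setNames(rep(0L, length(nodes)), nodes)
  v[rewired$pairs$original] <- seq_len(nrow(rewired$pairs))
  v[rewired$pairs$duplicate] <- seq_len(nrow(rewired$pairs))
  module_partition(v)
}
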