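#' Normalized mutual information between two partitions
#'
#' Information-theoretic agreement between two module assignments,
#' normalized by the arithmetic mean of the two entropies
#' (`2 I / (H_a + H_b)`, the community-detection convention of Danon et
#' al.). The score is 1 exactly when the partitions are identical up to a
#' relabelling on the compared gene set, and label-permutation invariant.
#' Unassigned genes (module 0) carry no shared-module claim: each is
#' treated as its own singleton cluster. Degenerate cases are pinned: if
#' both partitions have a single cluster the score is 1; if exactly one
#' does (zero entropy), the score is 0.
#'
#' @param partition_a,partition_b [module_partition()] objects or named
#'   integer vectors.
#' @param restrict_to optional gene set to compare on; default is the
#'   intersection of the two gene sets.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(partition_a, partition_b, restrict_to = NULL) {
  a <- as_assignment(partition_a)
  b <- as_assignment(partition_b)
  genes <- intersect(names(a), names(b))
  if (!is.null(restrict_to)) genes <- intersect(genes, restrict_to)
  if (length(genes) == 0L)
    stop("no genes shared by the two partitions")
  a <- singletonize_zeros(a[genes])
  b <- singletonize_zeros(b[genes])
  tab <- table(a, b)
  n <- sum(tab)
  ha <- entropy_nats(rowSums(tab) / n)
  hb <- entropy_nats(colSums(tab) / n)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  p <- tab / n
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  2 * mi / (ha + hb)
}

as_assignment <- function(x) {
  if (inherits(x, "module_partition")) return(stats::setNames(as.integer(x),
                                                              names(x)))
  if (is.null(names(x))) stop("partition must be named (names = genes)")
  stats::setNames(as.integer(x), names(x))
}

# module 0 = no claim: each unassigned gene becomes its own cluster
singletonize_zeros <- function(v) {
  z <- v == 0L
  if (any(z)) v[z] <- max(v) + seq_len(sum(z))
  v
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Rewiring recall score
#'
#' Size-weighted recall of true (original, duplicate) co-regulator pairs
#' landing in the same module:
#' \deqn{score = \frac{\sum_i s_i w_i}{|V| |U| / 2}, \quad w_i = |V|/m_i}
#' where \eqn{s_i} is 1 iff the pair shares an assigned (non-zero) module,
#' \eqn{m_i} the size of that module, \eqn{|U|} the number of pairs and
#' \eqn{|V|} the node count of the evaluated network. The weight penalizes
#' recall achieved through large modules; the denominator is the maximum
#' of the numerator, attained when every pair sits alone in its own
#' two-node module, so the score lies in \[0, 1\] and equals 1 exactly in
#' that ideal case.
#'
#' @param partition a [module_partition()] covering the pair members.
#' @param pairs data.frame with columns `original` and `duplicate` (or any
#'   two columns of gene names).
#' @param total_nodes number of nodes |V| in the evaluated network.
#' @return The rewiring recall score.
#' @export
rewiring_recall_score <- function(partition, pairs, total_nodes) {
  a <- as_assignment(partition)
  if (nrow(pairs) == 0L) stop("no pairs to score")
  if (total_nodes <= 0) stop("total_nodes must be positive")
  u <- as.character(pairs[[1L]])
  v <- as.character(pairs[[2L]])
  missing <- setdiff(c(u, v), names(a))
  if (length(missing) > 0L)
    stop("pair members missing from the partition: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sizes <- module_sizes(partition)
  same <- a[u] > 0L & a[u] == a[v]
  w <- ifelse(same, total_nodes / sizes[as.character(a[u])], 0)
  sum(w) / (total_nodes * nrow(pairs) / 2)
}

#' Transform a directed network into a bipartite network
#'
#' Every node with outgoing edges contributes a head copy (`<gene>_h`),
#' every node with incoming edges a tail copy (`<gene>_t`), and each
#' directed edge u -> v becomes the undirected edge (u_h, v_t). The edge
#' count is preserved. This makes undirected community detectors
#' applicable to directed regulatory networks while preserving direction
#' information.
#'
#' @param net a cleaned [directed_network()].
#' @return A `bipartite_network`: list with `head_nodes`, `tail_nodes`,
#'   `edges` (data.frame `head`, `tail`) and the suffix conventions.
#' @export
bipartite_transform <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  heads <- unique(net$edges$regulator)
  tails <- unique(net$edges$target)
  structure(list(head_nodes = paste0(heads, "_h"),
                 tail_nodes = paste0(tails, "_t"),
                 edges = data.frame(head = paste0(net$edges$regulator, "_h"),
                                    tail = paste0(net$edges$target, "_t"),
                                    stringsAsFactors = FALSE)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d head + %d tail nodes, %d edges\n",
              length(x$head_nodes), length(x$tail_nodes), nrow(x$edges)))
  invisible(x)
}

#' Merge module labels of bipartite copies back onto genes
#'
#' After running a community detector on a [bipartite_transform()]ed
#' network, each gene may have been assigned modules through its head copy
#' and through its tail copy. A gene receives the union of the modules of
#' its two copies.
#'
#' @param partition named module assignment over copy names (`<gene>_h`,
#'   `<gene>_t`).
#' @return Named list: gene -> integer vector of module ids.
#' @export
merge_bipartite_labels <- function(partition) {
  a <- as_assignment(partition)
  base <- sub("_[ht]$", "", names(a))
  lapply(split(unname(a), base), function(v) sort(unique(v[v > 0L])))
}

#' Random-walk (walk trap) similarity between genes
#'
#' Baseline similarity used for comparison. The directed adjacency matrix
#' is augmented with self-loops (unit diagonal) so that every row sum is
#' positive, row-normalized into a transition matrix `T`, and powered into
#' the m-step probability matrix `P = T^m`. The distance between genes i
#' and j is
#' \deqn{D(v_i, v_j) = \sqrt{\sum_k (P_{ik} - P_{jk})^2 / d(v_i)}}
#' and the similarity is `S = 1 - D`. `d(v_i)` is the out-degree on the
#' self-loop-augmented adjacency (the row sum that also normalizes `T`).
#' As written the distance is divided by the degree of the *first* gene of
#' the pair, which is asymmetric; the returned matrix averages the two
#' orientations. `per_k_degree = TRUE` instead divides each term by the
#' degree of the summation node k (the original walk-trap distance, which
#' is symmetric by construction).
#'
#' @param net a cleaned [directed_network()].
#' @param steps random-walk length m (2 and 4 are the usual choices).
#' @param per_k_degree use the per-summation-node degree variant.
#' @return A `similarity_matrix` (index `"walktrap"`, direction
#'   `"combined"`).
#' @export
wt_similarity <- function(net, steps = 4, per_k_degree = FALSE) {
  stopifnot(inherits(net, "directed_network"))
  if (steps < 1) stop("steps must be a positive integer")
  P <- wt_probability_matrix(net, steps)
  d <- attr(P, "degree")
  if (per_k_degree) {
    Pw <- P %*% diag(1 / sqrt(d))
    sq <- rowSums(Pw^2)
    D2 <- outer(sq, sq, "+") - 2 * Matrix::tcrossprod(Pw)
    D <- sqrt(pmax(as.matrix(D2), 0))
  } else {
    sq <- rowSums(P^2)
    cross <- as.matrix(Matrix::tcrossprod(P))
    D2 <- outer(sq, sq, "+") - 2 * cross  # ||P_i - P_j||^2
    Drow <- sqrt(pmax(D2, 0) / d)         # divide by d(v_i), as defined
    D <- (Drow + t(Drow)) / 2
  }
  S <- 1 - D
  diag(S) <- 0
  dimnames(S) <- list(net$nodes, net$nodes)
  new_similarity_matrix(net$nodes, S, "walktrap", "combined")
}

#' m-step transition probabilities of the self-loop-augmented walk
#'
#' @param net a cleaned [directed_network()].
#' @param steps walk length m.
#' @return Dense matrix `P = T^m`; the augmented out-degrees are attached
#'   as attribute `"degree"`.
#' @export
wt_probability_matrix <- function(net, steps) {
  A <- as.matrix(adjacency_matrix(net, use_weights = FALSE))
  diag(A) <- 1
  d <- rowSums(A)
  T_ <- A / d
  P <- diag(nrow(A))
  for (i in seq_len(steps)) P <- P %*% T_
  dimnames(P) <- list(net$nodes, net$nodes)
  attr(P, "degree") <- d
  P
}

#' Extract pairwise similarity scores for gene pairs
#'
#' @param s a `similarity_matrix`.
#' @param pairs data.frame whose first two columns are gene names.
#' @return Numeric vector of scores, one per pair.
#' @export
pair_scores <- function(s, pairs) {
  stopifnot(inherits(s, "similarity_matrix"))
  idx <- stats::setNames(seq_along(s$genes), s$genes)
  i <- idx[as.character(pairs[[1L]])]
  j <- idx[as.character(pairs[[2L]])]
  if (anyNA(i) || anyNA(j))
    stop("pair members missing from the similarity matrix")
  m <- s$values
  vapply(seq_along(i), function(k) as.numeric(m[i[k], j[k]]), numeric(1))
}

#' ROC curve and AUC from positive and negative scores
#'
#' Ranks the pooled scores and computes the standard ROC curve; the AUC is
#' the Mann-Whitney statistic, so tied scores contribute 1/2 (the
#' trapezoidal midpoint convention).
#'
#' @param positive_scores,negative_scores numeric score vectors, higher =
#'   more likely positive.
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(positive_scores, negative_scores) {
  if (length(positive_scores) == 0L || length(negative_scores) == 0L)
    stop("both score vectors must be nonempty")
  np <- length(positive_scores)
  nn <- length(negative_scores)
  r <- rank(c(positive_scores, negative_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(positive_scores, negative_scores)),
              decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(negative_scores >= t),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(positive_scores >= t),
                      numeric(1))))
  list(auc = auc, curve = curve)
}

#' Grid-search comparison of static and dynamic tree cutting
#'
#' Builds the complete-linkage tree once, then scores every static cutting
#' height on an 11-point grid (0 to 1, step 0.1) and every (maximum
#' height, deep split) combination of the dynamic cut on the 11 x 5 grid,
#' using the rewiring recall score against the true duplicate pairs. The
#' best score of each strategy is reported with its winning parameters;
#' whether the dynamic cut wins is recorded, not guaranteed.
#'
#' @param d a `dissimilarity_matrix` computed on `rewired$network`.
#' @param rewired a `rewired_network` supplying the true pairs.
#' @param heights static-cut / maximum-height grid.
#' @param deep_split_values deep-split grid for the dynamic cut.
#' @param min_cluster_size minimum module size (default 2).
#' @return List with `static` and `dynamic` grid data.frames (all RRS
#'   values) and `best_static` / `best_dynamic` rows.
#' @export
compare_tree_cuts <- function(d, rewired, heights = seq(0, 1, by = 0.1),
                              deep_split_values = 0:4,
                              min_cluster_size = 2) {
  stopifnot(inherits(d, "dissimilarity_matrix"),
            inherits(rewired, "rewired_network"))
  tree <- hierarchical_cluster(d)
  total_nodes <- n_nodes(rewired$network)
  pairs <- rewired$pairs
  rrs_of <- function(p) rewiring_recall_score(p, pairs, total_nodes)
  static <- data.frame(height = heights,
                       rrs = vapply(heights, function(h)
                         rrs_of(static_tree_cut(tree, h, min_cluster_size)),
                         numeric(1)))
  grid <- expand.grid(max_height = heights, deep_split = deep_split_values)
  grid$rrs <- vapply(seq_len(nrow(grid)), function(i)
    rrs_of(dynamic_tree_cut(tree, d, grid$deep_split[i], min_cluster_size,
                            grid$max_height[i])),
    numeric(1))
  list(static = static, dynamic = grid,
       best_static = static[which.max(static$rrs), ],
       best_dynamic = grid[which.max(grid$rrs), ])
}
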