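#' Pairwise neighbor-overlap similarity
#'
#' Computes a symmetric gene-by-gene similarity matrix from shared in- or
#' out-neighborhoods. Three indices are supported. Writing
#' \eqn{N(v)} for the in- (or out-) neighbor set of node \eqn{v}:
#' \describe{
#'   \item{jaccard}{\eqn{|N(i) \cap N(j)| / |N(i) \cup N(j)|}; 0 when the
#'     union is empty.}
#'   \item{geometric}{\eqn{|N(i) \cap N(j)|^2 / (|N(i)| |N(j)|)}; 0 when
#'     either set is empty.}
#'   \item{invlogweighted}{\eqn{\sum_{c \in N(i) \cap N(j)} 1/\log d(c)}
#'     where \eqn{d(c)} is the total (in + out) degree of the common
#'     neighbor \eqn{c}; natural logarithm. With `use_weights`, \eqn{d(c)}
#'     is the total incident edge weight, which must exceed 1 for every
#'     common neighbor (rescale weights otherwise).}
#' }
#' Self-similarities are never computed; the diagonal is fixed at 0 and
#' downstream clustering ignores it.
#'
#' @param net a cleaned [directed_network()].
#' @param index similarity index name.
#' @param direction `"in"` (shared regulators) or `"out"` (shared targets).
#' @param use_weights for `invlogweighted` only: replace degrees by summed
#'   edge weights.
#' @param sparse store values as a sparse `Matrix` (default for networks
#'   above 4096 nodes).
#' @return A `similarity_matrix`: list with `genes` (node order), `values`
#'   (symmetric matrix, zero diagonal), `index`, `direction`, and `weights`
#'   (combination weights, set by [combine_similarity()]).
#' @export
neighbor_similarity <- function(net,
                                index = c("jaccard", "geometric",
                                          "invlogweighted"),
                                direction = c("in", "out"),
                                use_weights = FALSE,
                                sparse = n_nodes(net) > 4096) {
  index <- match.arg(index)
  direction <- match.arg(direction)
  A <- adjacency_matrix(net, use_weights = FALSE)
  B <- if (direction == "out") A else Matrix::t(A)
  # B[i, c] = 1 iff c is a `direction`-neighbor of i
  deg <- Matrix::rowSums(B)
  common <- Matrix::tcrossprod(B)  # |N(i) n N(j)|
  n <- length(net$nodes)
  if (index == "jaccard") {
    # nonzero only where common > 0; union = d_i + d_j - common there
    cc <- methods::as(methods::as(common, "generalMatrix"), "TsparseMatrix")
    keep <- cc@i != cc@j
    i <- cc@i[keep]; j <- cc@j[keep]; x <- cc@x[keep]
    un <- deg[i + 1L] + deg[j + 1L] - x
    vals <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = x / un,
                                 dims = c(n, n),
                                 dimnames = list(net$nodes, net$nodes))
  } else if (index == "geometric") {
    cc <- methods::as(methods::as(common, "generalMatrix"), "TsparseMatrix")
    keep <- cc@i != cc@j
    i <- cc@i[keep]; j <- cc@j[keep]; x <- cc@x[keep]
    vals <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L,
                                 x = x^2 / (deg[i + 1L] * deg[j + 1L]),
                                 dims = c(n, n),
                                 dimnames = list(net$nodes, net$nodes))
  } else {
    d_tot <- total_degree(net, use_weights = use_weights)
    # only nodes that are neighbors of >= 2 genes can be common neighbors;
    # those always have total degree >= 2 in an unweighted clean network
    is_common <- Matrix::colSums(B) >= 2
    if (any(is_common & d_tot <= 1))
      stop("invlogweighted: a common neighbor has total ",
           if (use_weights) "weight" else "degree",
           " <= 1; rescale edge weights so every node's total exceeds 1")
    w <- ifelse(d_tot > 1, 1 / log(d_tot), 0)
    vals <- Matrix::tcrossprod(B %*% Matrix::Diagonal(n, sqrt(w)))
    vals <- methods::as(methods::as(vals, "generalMatrix"), "CsparseMatrix")
    Matrix::diag(vals) <- 0
    vals <- Matrix::drop0(vals)
    dimnames(vals) <- list(net$nodes, net$nodes)
  }
  if (!sparse) vals <- as.matrix(vals)
  new_similarity_matrix(net$nodes, vals, index, direction)
}

total_degree <- function(net, use_weights = FALSE) {
  A <- adjacency_matrix(net, use_weights = use_weights)
  Matrix::rowSums(A) + Matrix::colSums(A)
}

new_similarity_matrix <- function(genes, values, index, direction,
                                  weights = NULL) {
  structure(list(genes = genes, values = values, index = index,
                 direction = direction, weights = weights),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s, %s): %d genes\n",
              x$index, x$direction, length(x$genes)))
  invisible(x)
}

#' @export
as.matrix.similarity_matrix <- function(x, ...) as.matrix(x$values)

#' @rdname neighbor_similarity
#' @export
jaccard_similarity <- function(net, direction = c("in", "out"), ...)
  neighbor_similarity(net, "jaccard", direction, ...)

#' @rdname neighbor_similarity
#' @export
geometric_similarity <- function(net, direction = c("in", "out"), ...)
  neighbor_similarity(net, "geometric", direction, ...)

#' @rdname neighbor_similarity
#' @export
invlogweighted_similarity <- function(net, direction = c("in", "out"),
                                      use_weights = FALSE, ...)
  neighbor_similarity(net, "invlogweighted", direction,
                      use_weights = use_weights, ...)

#' Combine in- and out-similarity matrices
#'
#' Elementwise weighted sum `S = w1 * S_in + w2 * S_out`. The default
#' weights `w1 = w2 = 1` give both directions equal say.
#'
#' @param s_in,s_out `similarity_matrix` objects over the same genes and
#'   index, with directions `"in"` and `"out"`.
#' @param w1,w2 non-negative weights, not both zero.
#' @return A combined `similarity_matrix` (direction `"combined"`).
#' @export
combine_similarity <- function(s_in, s_out, w1 = 1, w2 = 1) {
  stopifnot(inherits(s_in, "similarity_matrix"),
            inherits(s_out, "similarity_matrix"))
  if (!identical(s_in$genes, s_out$genes))
    stop("gene lists of the two similarity matrices differ")
  if (!identical(s_in$index, s_out$index))
    stop("similarity indices differ: ", s_in$index, " vs ", s_out$index)
  if (w1 < 0 || w2 < 0 || (w1 == 0 && w2 == 0))
    stop("weights must be non-negative and not both zero")
  vals <- w1 * s_in$values + w2 * s_out$values
  new_similarity_matrix(s_in$genes, vals, s_in$index, "combined",
                        weights = c(w1 = w1, w2 = w2))
}

#' Transform a similarity matrix into a dissimilarity matrix
#'
#' Applies `S'_ij = (max(S) - S_ij) / max(S)` with the maximum taken over
#' off-diagonal entries, mapping the most similar pair to distance 0 and
#' pairs with no shared neighbors to distance 1. The diagonal is 0.
#'
#' @param s a `similarity_matrix` (any direction).
#' @return A `dissimilarity_matrix`: list with `genes`, `values` (dense
#'   symmetric matrix in \[0, 1\]) and `source_max` (the max(S) used).
#' @export
to_dissimilarity <- function(s) {
  stopifnot(inherits(s, "similarity_matrix"))
  v <- as.matrix(s$values)
  diag(v) <- 0
  mx <- max(v)
  if (mx <= 0)
    stop("no co-regulation signal: all pairwise similarities are zero")
  d <- (mx - v) / mx
  diag(d) <- 0
  dimnames(d) <- list(s$genes, s$genes)
  structure(list(genes = s$genes, values = d, source_max = mx),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix: %d genes (max similarity %.4g)\n",
              length(x$genes), x$source_max))
  invisible(x)
}

#' @export
as.matrix.dissimilarity_matrix <- function(x, ...) x$values

#' Export a similarity or dissimilarity matrix as labelled TSV
#'
#' @param x a `similarity_matrix` or `dissimilarity_matrix`.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- as.matrix(x)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
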