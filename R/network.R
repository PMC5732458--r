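#' Construct a directed regulatory network
#'
#' A `directed_network` holds a regulator -> target edge list over gene
#' identifiers (opaque, case-sensitive strings). The node set is defined by
#' the edge list: every node appears in at least one edge, in first-appearance
#' order (regulator column scanned before target column, row by row).
#'
#' @param regulator character vector of edge head nodes (regulators).
#' @param target character vector of edge tail nodes (targets), same length.
#' @param weight optional numeric vector of non-negative edge weights.
#' @return An object of class `directed_network` with components `edges`
#'   (data.frame with columns `regulator`, `target` and optionally `weight`)
#'   and `nodes` (character vector).
#' @export
directed_network <- function(regulator, target, weight = NULL) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  if (length(regulator) != length(target))
    stop("regulator and target must have the same length")
  if (length(regulator) == 0L)
    stop("a directed network needs at least one edge")
  edges <- data.frame(regulator = regulator, target = target,
                      stringsAsFactors = FALSE)
  if (!is.null(weight)) {
    weight <- as.numeric(weight)
    if (length(weight) != length(regulator))
      stop("weight must match the number of edges")
    if (anyNA(weight) || any(weight < 0))
      stop("edge weights must be non-negative and non-missing")
    edges$weight <- weight
  }
  # first-appearance order: interleave head/tail per row
  nodes <- unique(as.vector(rbind(regulator, target)))
  structure(list(edges = edges, nodes = nodes),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is_weighted(x)) " (weighted)" else ""))
  invisible(x)
}

is_weighted <- function(net) "weight" %in% names(net$edges)

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Read a directed network from an edge-list file
#'
#' Parses a plain-text edge list: one edge per line, first field the
#' regulator (head), second the target (tail), optional third field a
#' non-negative weight. Fields are separated by `delimiter` (default: any
#' run of whitespace, which covers both space- and tab-delimited files).
#' Lines starting with `#` and blank lines are skipped. The parser is
#' verbatim: duplicated edges and self-loops are kept; use
#' [clean_network()] to enforce the simple-graph invariants.
#'
#' @param path path to the edge-list file.
#' @param has_weights if `TRUE`, require and parse a third numeric column.
#' @param delimiter field separator; `""` (default) splits on whitespace.
#' @return A [directed_network()].
#' @export
read_edge_list <- function(path, has_weights = FALSE, delimiter = "") {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges found in ", path)
  split_re <- if (identical(delimiter, "")) "\\s+" else delimiter
  fields <- strsplit(trimws(lines[idx]), split_re)
  nf <- lengths(fields)
  need <- if (has_weights) 3L else 2L
  bad <- which(nf < need)
  if (length(bad) > 0L)
    stop(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                 idx[bad[1L]], path, need, nf[bad[1L]]))
  reg <- vapply(fields, `[[`, character(1), 1L)
  tar <- vapply(fields, `[[`, character(1), 2L)
  w <- NULL
  if (has_weights) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(w))
      stop(sprintf("malformed line %d in %s: weight is not numeric",
                   idx[which(is.na(w))[1L]], path))
  }
  directed_network(reg, tar, w)
}

#' Remove self-loops and duplicated edges
#'
#' Drops edges whose head equals their tail, then collapses repeated
#' (regulator, target) pairs to a single edge. For weighted networks the
#' first occurrence's weight is kept (with a warning when dropped
#' duplicates carried different weights). The counts of removed edges are
#' attached as attributes `removed_self_loops` and `removed_duplicates`.
#'
#' @param net a [directed_network()].
#' @return A cleaned `directed_network` satisfying: no self-loops, no
#'   duplicated ordered pairs, every node incident to an edge.
#' @export
clean_network <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  e <- net$edges
  self <- e$regulator == e$target
  e <- e[!self, , drop = FALSE]
  key <- paste(e$regulator, e$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup) && is_weighted(net)) {
    w_first <- e$weight[match(key[dup], key)]
    if (any(w_first != e$weight[dup]))
      warning("duplicated weighted edges with differing weights: ",
              "keeping first occurrence")
  }
  e <- e[!dup, , drop = FALSE]
  if (nrow(e) == 0L) stop("network is empty after cleaning")
  out <- directed_network(e$regulator, e$target, e$weight)
  attr(out, "removed_self_loops") <- sum(self)
  attr(out, "removed_duplicates") <- sum(dup)
  out
}

# node -> index lookup in the network's canonical order
node_index <- function(net) {
  idx <- seq_along(net$nodes)
  names(idx) <- net$nodes
  idx
}

#' Sparse adjacency matrix of a directed network
#'
#' Rows are regulators (edge heads), columns targets (edge tails), in the
#' network's node order. Entries are edge weights when present, else 1.
#'
#' @param net a cleaned [directed_network()].
#' @param use_weights use edge weights as entries when available.
#' @return A `dgCMatrix` of dimension |V| x |V|.
#' @export
adjacency_matrix <- function(net, use_weights = is_weighted(net)) {
  idx <- node_index(net)
  n <- length(idx)
  x <- if (use_weights && is_weighted(net)) net$edges$weight else
    rep(1, n_edges(net))
  Matrix::sparseMatrix(i = idx[net$edges$regulator],
                       j = idx[net$edges$target],
                       x = x, dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

#' Write a module partition to a TSV file
#'
#' Writes three columns: `gene`, `module_id`, `module_type`. Unassigned
#' genes carry module_id 0 and an empty type field. The table round-trips
#' losslessly through [read_modules()].
#'
#' @param partition a [module_partition()] (gene -> module id mapping).
#' @param path output file path.
#' @param types optional module type table from [classify_modules()]; when
#'   supplied, the `module_type` column is filled for assigned genes.
#' @export
write_modules <- function(partition, path, types = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  if (length(partition) == 0L) stop("empty partition")
  type_col <- rep("", length(partition))
  if (!is.null(types)) {
    m <- match(as.integer(partition), types$module_id)
    type_col <- ifelse(partition > 0L & !is.na(m),
                       as.character(types$type[m]), "")
  }
  df <- data.frame(gene = names(partition),
                   module_id = as.integer(partition),
                   module_type = type_col, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a module partition written by [write_modules()]
#'
#' @param path path to the module TSV.
#' @return A [module_partition()]; module types, when present, are kept in
#'   the `"types"` attribute as a gene-level character vector.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("module file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character"),
                          quote = "", comment.char = "")
  p <- module_partition(stats::setNames(df$module_id, df$gene))
  attr(p, "types") <- stats::setNames(df$module_type, df$gene)
  p
}
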