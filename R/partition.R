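#' Construct a module partition
#'
#' A `module_partition` maps each gene to a non-negative integer module id;
#' 0 means no module assignment. Assigned module ids are relabelled to
#' contiguous positive integers ordered by decreasing module size (ties by
#' first appearance in the gene vector), which makes partitions produced by
#' different code paths comparable.
#'
#' @param assignment named integer (or integer-like) vector, names are gene
#'   identifiers, values are module ids (>= 0, 0 = unassigned).
#' @param params optional list of clustering settings to record.
#' @return A named integer vector of class `module_partition`.
#' @export
module_partition <- function(assignment, params = NULL) {
  if (length(assignment) == 0L) stop("empty partition")
  if (is.null(names(assignment)) || anyNA(names(assignment)))
    stop("assignment must be a named vector (names = genes)")
  if (anyDuplicated(names(assignment)))
    stop("duplicated gene names in partition")
  v <- as.integer(assignment)
  if (anyNA(v) || any(v < 0L)) stop("module ids must be integers >= 0")
  names(v) <- names(assignment)
  v <- relabel_partition(v)
  structure(v, params = params, class = "module_partition")
}

# contiguous ids 1..M by decreasing size, ties by first appearance
relabel_partition <- function(v) {
  assigned <- v > 0L
  if (!any(assigned)) return(v)
  old <- v[assigned]
  sizes <- table(old)
  first <- tapply(seq_along(v)[assigned], old, min)
  ord <- order(-as.integer(sizes[names(first)]), as.integer(first))
  map <- stats::setNames(seq_along(ord), names(first)[ord])
  v[assigned] <- map[as.character(old)]
  v
}

#' @export
print.module_partition <- function(x, ...) {
  m <- sum(unique(x) > 0L)
  cat(sprintf("module_partition: %d genes, %d modules, %d unassigned\n",
              length(x), m, sum(x == 0L)))
  invisible(x)
}

#' Sizes of assigned modules
#'
#' @param partition a [module_partition()].
#' @return Named integer vector: module id -> number of genes (ids > 0 only).
#' @export
module_sizes <- function(partition) {
  v <- as.integer(partition)
  v <- v[v > 0L]
  if (length(v) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Genes belonging to one module
#'
#' @param partition a [module_partition()].
#' @param id module id (> 0).
#' @return Character vector of gene names.
#' @export
module_genes <- function(partition, id) {
  names(partition)[as.integer(partition) == as.integer(id)]
}
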