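#' Classify modules as regulator, target or intermediate
#'
#' Pools the edges incident to each module's genes and measures the share
#' of outgoing edges. A module whose incident edges are more than
#' `threshold` (default 90%) outgoing is a *regulator* module; more than
#' `threshold` incoming, a *target* module; anything else is
#' *intermediate*. An edge internal to a module is simultaneously outgoing
#' (from its head gene) and incoming (to its tail gene) and therefore
#' counts once in each direction.
#'
#' By default the rule is applied to the module's pooled edges. With
#' `per_gene = TRUE` a stricter reading is used: the module is a regulator
#' (target) module only if every member gene individually exceeds the
#' threshold.
#'
#' @param net a cleaned [directed_network()].
#' @param partition a [module_partition()]; every assigned gene must be a
#'   node of `net`.
#' @param threshold fraction of edges in one direction required, in (0, 1).
#' @param per_gene apply the threshold gene-by-gene instead of pooled.
#' @return A `module_types` data.frame with columns `module_id`, `type`
#'   (`"regulator"`, `"target"` or `"intermediate"`), `out_fraction` and
#'   `edge_count` (pooled incident edge endpoints).
#' @export
classify_modules <- function(net, partition, threshold = 0.9,
                             per_gene = FALSE) {
  stopifnot(inherits(net, "directed_network"),
            inherits(partition, "module_partition"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- sort(unique(as.integer(partition)))
  ids <- ids[ids > 0L]
  assigned <- names(partition)[partition > 0L]
  missing <- setdiff(assigned, net$nodes)
  if (length(missing) > 0L)
    stop("assigned genes absent from the network: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  out_deg <- table(factor(net$edges$regulator, levels = net$nodes))
  in_deg <- table(factor(net$edges$target, levels = net$nodes))
  gene_type <- function(o, i, thr) {
    frac <- o / (o + i)
    if (frac > thr) "regulator" else if (1 - frac > thr) "target"
    else "intermediate"
  }
  rows <- lapply(ids, function(id) {
    genes <- module_genes(partition, id)
    o <- sum(out_deg[genes]); i <- sum(in_deg[genes])
    if (o + i == 0L)
      stop("module ", id, " has no incident edges")
    type <- if (per_gene) {
      per <- vapply(genes, function(g) {
        if (out_deg[g] + in_deg[g] == 0L) return("intermediate")
        gene_type(out_deg[g], in_deg[g], threshold)
      }, character(1))
      if (all(per == "regulator")) "regulator"
      else if (all(per == "target")) "target"
      else "intermediate"
    } else gene_type(o, i, threshold)
    data.frame(module_id = id, type = type,
               out_fraction = o / (o + i),
               edge_count = as.integer(o + i))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("module_types", "data.frame")
  res
}
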