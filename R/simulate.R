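# seed scoping: run expr under set.seed(seed) without disturbing the
# caller's RNG stream; seed = NULL uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a simulated co-regulatory network with planted modules
#'
#' Builds a directed network with known co-regulatory structure.
#' `msize * mnum` regulator nodes are created and assigned to `mnum`
#' equally sized modules; `aux_num` auxiliary nodes act as potential
#' targets (they never have outgoing edges). Each module owns a pool of
#' `target_num` candidate targets drawn from the auxiliaries; pools of
#' different modules are disjoint whenever `aux_num >= mnum * target_num`
#' (otherwise pools are sampled independently, with a warning). Every
#' regulator then receives exactly `target_num` distinct targets: each one
#' is drawn from its module's pool with probability `prob` and from the
#' auxiliaries outside the pool otherwise. Higher `prob` yields stronger
#' co-regulation within modules.
#'
#' Regulators have in-degree 0 and out-degree `target_num`; auxiliary
#' nodes have out-degree 0. Auxiliaries that receive no edge do not appear
#' in the network (the edge list defines the node set).
#'
#' @param msize regulators per module.
#' @param mnum number of modules.
#' @param target_num targets per regulator; also the pool size.
#' @param aux_num number of auxiliary target-only nodes.
#' @param prob co-regulation probability in \[0, 1\].
#' @param seed optional integer seed; same seed and parameters give a
#'   bit-identical network.
#' @return A `sim_network`: list with `network` ([directed_network()]),
#'   `planted` (named integer vector regulator -> module label), `pools`
#'   (list module label -> pool gene names) and `params`.
#' @export
generate_simulated_network <- function(msize = 5, mnum = 10,
                                       target_num = 20, aux_num = 200,
                                       prob = 0.8, seed = NULL) {
  if (msize < 1 || mnum < 1 || target_num < 1 || aux_num < 1)
    stop("msize, mnum, target_num and aux_num must be positive")
  if (prob < 0 || prob > 1) stop("prob must be in [0, 1]")
  if (aux_num < target_num)
    stop("aux_num must be >= target_num (a pool must be fillable)")
  if (prob < 1 && aux_num - target_num < target_num)
    stop("not enough non-pool candidates: need aux_num - target_num >= ",
         "target_num when prob < 1")
  regs <- paste0("r", seq_len(msize * mnum))
  aux <- paste0("t", seq_len(aux_num))
  planted <- stats::setNames(rep(seq_len(mnum), each = msize), regs)
  with_seed(seed, {
    disjoint <- aux_num >= mnum * target_num
    if (disjoint) {
      picked <- sample(aux, mnum * target_num)
      pools <- split(picked, rep(seq_len(mnum), each = target_num))
    } else {
      warning("aux_num < mnum * target_num: module pools sampled ",
              "independently and may overlap")
      pools <- lapply(seq_len(mnum), function(i) sample(aux, target_num))
    }
    names(pools) <- as.character(seq_len(mnum))
    edges <- lapply(regs, function(r) {
      pool <- pools[[planted[[r]]]]
      off_pool <- setdiff(aux, pool)
      n_in <- sum(stats::runif(target_num) < prob)
      targets <- c(sample(pool, n_in),
                   if (target_num - n_in > 0)
                     sample(off_pool, target_num - n_in))
      data.frame(regulator = r, target = targets,
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, edges)
    structure(list(network = directed_network(edges$regulator,
                                              edges$target),
                   planted = planted, pools = pools,
                   params = list(msize = msize, mnum = mnum,
                                 target_num = target_num,
                                 aux_num = aux_num, prob = prob,
                                 seed = seed)),
              class = "sim_network")
  })
}

#' @export
print.sim_network <- function(x, ...) {
  cat(sprintf(paste0("sim_network: %d regulators in %d planted modules, ",
                     "%d edges (prob = %g)\n"),
              length(x$planted), x$params$mnum, n_edges(x$network),
              x$params$prob))
  invisible(x)
}

#' Duplicate nodes and rewire their outgoing edges
#'
#' Constructs ground-truth co-regulator pairs by node duplication: `n`
#' nodes with outgoing edges are picked at random and copied, each
#' duplicate inheriting all in- and out-edges of its original. Every
#' (original, duplicate) pair is a true co-regulator pair. Noise is then
#' injected by a degree-preserving swap phase: each outgoing edge of each
#' duplicate is, independently with probability `rewire_prob`, paired with
#' a uniformly chosen outgoing edge of a *different* duplicate and the two
#' target nodes are exchanged. Swaps change neither the total number of
#' interactions nor any node's degree, and edges among non-duplicated
#' nodes are never touched. Duplicates are processed in deterministic
#' order, so a run is reproducible under `seed`.
#'
#' @param net a cleaned [directed_network()].
#' @param n number of nodes to duplicate; default
#'   `min(80, max(2, floor(0.2 * #out-degree-positive nodes)))`.
#' @param rewire_prob per-edge swap probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return A `rewired_network`: list with `network` (the duplicated,
#'   rewired [directed_network()]), `pairs` (data.frame `original`,
#'   `duplicate`), `rewire_prob` and `seed`.
#' @export
duplicate_and_rewire <- function(net, n = NULL, rewire_prob = 0,
                                 seed = NULL) {
  stopifnot(inherits(net, "directed_network"))
  if (rewire_prob < 0 || rewire_prob > 1)
    stop("rewire_prob must be in [0, 1]")
  candidates <- unique(net$edges$regulator)
  if (is.null(n)) n <- min(80L, max(2L, floor(0.2 * length(candidates))))
  if (n > length(candidates))
    stop("n exceeds the number of nodes with outgoing edges")
  if (n < 2L && rewire_prob > 0)
    stop("n must be >= 2 when rewire_prob > 0 (a swap needs a partner)")
  with_seed(seed, {
    originals <- sample(candidates, n)
    dups <- paste0(originals, "_dup")
    clash <- dups %in% net$nodes
    if (any(clash)) dups[clash] <- paste0(dups[clash], "_x")
    names(dups) <- originals
    e <- net$edges
    # duplicates inherit every in- and out-edge of their originals
    out_copy <- e[e$regulator %in% originals, c("regulator", "target")]
    out_copy$regulator <- dups[out_copy$regulator]
    in_copy <- e[e$target %in% originals, c("regulator", "target")]
    in_copy$target <- dups[in_copy$target]
    dup_out <- out_copy
    # swap phase over duplicates' outgoing edges, one pass, fixed order
    dup_out <- dup_out[order(match(dup_out$regulator, dups),
                             dup_out$target), ]
    rownames(dup_out) <- NULL
    if (rewire_prob > 0 && nrow(dup_out) > 0) {
      for (i in seq_len(nrow(dup_out))) {
        if (stats::runif(1) >= rewire_prob) next
        partners <- which(dup_out$regulator != dup_out$regulator[i])
        if (length(partners) == 0L) next
        j <- partners[sample.int(length(partners), 1L)]
        tmp <- dup_out$target[i]
        dup_out$target[i] <- dup_out$target[j]
        dup_out$target[j] <- tmp
      }
    }
    all_edges <- rbind(e[, c("regulator", "target")], dup_out, in_copy)
    structure(list(network = directed_network(all_edges$regulator,
                                              all_edges$target),
                   pairs = data.frame(original = unname(originals),
                                      duplicate = unname(dups),
                                      stringsAsFactors = FALSE),
                   rewire_prob = rewire_prob, seed = seed),
              class = "rewired_network")
  })
}

#' @export
print.rewired_network <- function(x, ...) {
  cat(sprintf("rewired_network: %d duplicate pairs, rewire_prob = %g, %d edges\n",
              nrow(x$pairs), x$rewire_prob, n_edges(x$network)))
  invisible(x)
}

#' Sample negative co-regulator pairs
#'
#' Negative pairs are two duplicated nodes originating from different
#' originals. Since every original is duplicated once, any unordered pair
#' of distinct duplicates qualifies; `count` of them are sampled without
#' replacement.
#'
#' @param rewired a `rewired_network` from [duplicate_and_rewire()].
#' @param count number of pairs to draw.
#' @param seed optional integer seed.
#' @return data.frame with columns `a`, `b` (duplicate node names).
#' @export
sample_negative_pairs <- function(rewired, count, seed = NULL) {
  stopifnot(inherits(rewired, "rewired_network"))
  dups <- rewired$pairs$duplicate
  n <- length(dups)
  if (n < 2L) stop("need at least 2 duplicated nodes")
  n_avail <- n * (n - 1) / 2
  if (count > n_avail)
    stop("requested ", count, " negative pairs but only ", n_avail,
         " distinct pairs exist")
  with_seed(seed, {
    idx <- sample.int(n_avail, count)
    # unrank the unordered pair index: pairs (i, j), i < j, in column order
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
    data.frame(a = dups[i], b = dups[j], stringsAsFactors = FALSE)
  })
}
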