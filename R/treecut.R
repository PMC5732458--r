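#' Complete-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Builds the agglomerative tree used for module detection. Complete
#' linkage is used throughout: the distance between two clusters is the
#' maximum pairwise dissimilarity, so merge heights are monotone and stay
#' within \[0, 1\] for inputs from [to_dissimilarity()]. Ties between equal
#' linkage distances are broken deterministically by the agglomeration
#' engine ([stats::hclust()]), so repeated runs give identical trees.
#'
#' @param d a `dissimilarity_matrix` with at least two genes.
#' @return A `cluster_tree`: list with the `hclust` object (`hc`) and the
#'   gene order (`genes`).
#' @export
hierarchical_cluster <- function(d) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  if (length(d$genes) < 2L)
    stop("need at least 2 genes to build a tree")
  hc <- stats::hclust(stats::as.dist(d$values), method = "complete")
  structure(list(hc = hc, genes = d$genes), class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves, complete linkage, max height %.4g\n",
              length(x$genes), max(x$hc$height)))
  invisible(x)
}

#' Cut the clustering tree adaptively (hybrid dynamic tree cut)
#'
#' Implements the hybrid variant of the dynamic tree cut algorithm
#' (Langfelder, Zhang & Horvath 2008). Instead of slicing the dendrogram at
#' one fixed height, branches are examined bottom-up and declared clusters
#' when they satisfy shape criteria: minimum size, a sufficiently tight
#' core (average within-core dissimilarity below a threshold) and a
#' sufficiently large gap between the core and the height at which the
#' branch joins the rest of the tree. `deep_split` (0-4) tunes the shape
#' thresholds; higher values yield smaller, more numerous clusters. A
#' second, PAM-like stage assigns leftover genes to the closest detected
#' cluster on their own branch when they are close enough. Genes in no
#' qualifying cluster keep module id 0.
#'
#' @param tree a `cluster_tree` from [hierarchical_cluster()].
#' @param d the `dissimilarity_matrix` the tree was built from.
#' @param deep_split integer 0-4 (default 1), cluster-splitting sensitivity.
#' @param min_cluster_size smallest allowed module (default 2: co-regulation
#'   needs at least two genes).
#' @param max_height maximum joining height considered (default 1, the
#'   upper bound of the normalized dissimilarity); merges above it are
#'   never clustered.
#' @param pam_stage run the second-stage assignment of unlabelled genes.
#' @return A [module_partition()] over the tree's genes; `params` records
#'   the settings.
#' @export
dynamic_tree_cut <- function(tree, d, deep_split = 1, min_cluster_size = 2,
                             max_height = 1, pam_stage = TRUE) {
  stopifnot(inherits(tree, "cluster_tree"),
            inherits(d, "dissimilarity_matrix"))
  if (!identical(tree$genes, d$genes))
    stop("tree and dissimilarity matrix cover different genes")
  if (length(deep_split) != 1L || !(deep_split %in% 0:4))
    stop("deep_split must be one of 0, 1, 2, 3, 4")
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  labels <- cut_tree_hybrid(tree$hc$merge, tree$hc$height,
                            as.matrix(d), min_cluster_size,
                            deep_split, max_height, pam_stage)
  module_partition(stats::setNames(labels, tree$genes),
                   params = list(method = "dynamic-hybrid",
                                 deep_split = deep_split,
                                 min_cluster_size = min_cluster_size,
                                 max_height = max_height,
                                 pam_stage = pam_stage))
}

#' Cut the clustering tree at a fixed height
#'
#' Classic static cut: all branches are severed at `height`; the resulting
#' groups smaller than `min_cluster_size` are relabelled 0 (unassigned).
#'
#' @param tree a `cluster_tree`.
#' @param height cutting height in \[0, 1\].
#' @param min_cluster_size smallest allowed module (default 2).
#' @return A [module_partition()].
#' @export
static_tree_cut <- function(tree, height, min_cluster_size = 2) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (height < 0 || height > 1) stop("height must be in [0, 1]")
  raw <- stats::cutree(tree$hc, h = height)
  sizes <- table(raw)
  raw[sizes[as.character(raw)] < min_cluster_size] <- 0L
  module_partition(stats::setNames(as.integer(raw), tree$genes),
                   params = list(method = "static", height = height,
                                 min_cluster_size = min_cluster_size))
}

# deep_split -> (max core scatter, min gap), relative to the truncated
# height range; the five levels of the hybrid dynamic tree cut
split_thresholds <- function(deep_split) {
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  c(max_core_scatter = mcs, min_gap = (1 - mcs) * 3 / 4)
}

# branch core = the first core_size leaves that joined it (joining order)
core_size <- function(branch_size, min_cluster_size) {
  base <- min_cluster_size / 2 + 1
  if (base < branch_size) as.integer(base + sqrt(branch_size - base))
  else as.integer(branch_size)
}

# average pairwise dissimilarity within the branch core
core_scatter <- function(singletons, n_singl, min_cluster_size, distM) {
  cs <- core_size(n_singl, min_cluster_size)
  core <- singletons[seq_len(cs)]
  if (cs < 2L) return(0)
  mean(colSums(distM[core, core, drop = FALSE]) / (cs - 1))
}

# Hybrid dynamic tree cut engine. merge/heights come from stats::hclust
# (heights non-decreasing); distM is the dense dissimilarity matrix.
# Returns integer labels per leaf, 0 = unassigned.
cut_tree_hybrid <- function(merge, heights, distM, min_cluster_size,
                            deep_split, cut_height, pam_stage) {
  n_merge <- length(heights)
  n <- n_merge + 1L
  if (cut_height > max(heights)) cut_height <- max(heights)
  # reference height: the 5% quantile merge, used to truncate the height
  # range so that a dense bottom does not inflate the shape thresholds
  ref_height <- heights[max(1L, round(n_merge * 0.05))]
  th <- split_thresholds(deep_split)
  max_abs_scatter <- ref_height + th[["max_core_scatter"]] *
    (cut_height - ref_height)
  min_abs_gap <- th[["min_gap"]] * (cut_height - ref_height)
  min_abs_split_height <- ref_height
  max_pam_dist <- cut_height

  if (sum(heights <= cut_height) < min_cluster_size)
    return(rep(0L, n))

  # branch bookkeeping (grows as merges are processed)
  br_basic <- logical(0)      # still a single candidate cluster?
  br_top <- logical(0)        # basic and not absorbed into another basic
  br_fail_size <- logical(0)  # merged away only for being too small
  br_size <- integer(0)
  br_singl <- list()          # leaves in joining order (basic branches)
  br_basics <- list()         # constituent basic branches (composite)
  br_merged_into <- integer(0)
  br_attach <- numeric(0)     # height at which branch joined something
  merge_branch <- integer(n_merge)  # merge row -> branch id
  on_branch <- integer(n)     # leaf -> composite branch it sits on

  new_branch <- function(basic, singl, basics, size) {
    br_basic[[length(br_basic) + 1L]] <<- basic
    br_top[[length(br_top) + 1L]] <<- basic
    br_fail_size[[length(br_fail_size) + 1L]] <<- FALSE
    br_size[[length(br_size) + 1L]] <<- size
    br_singl[[length(br_singl) + 1L]] <<- singl
    br_basics[[length(br_basics) + 1L]] <<- basics
    br_merged_into[[length(br_merged_into) + 1L]] <<- 0L
    br_attach[[length(br_attach) + 1L]] <<- NA_real_
    length(br_basic)
  }
  # the set of basic branches inside a branch (itself if basic)
  basics_of <- function(b) if (br_basic[b]) b else br_basics[[b]]

  for (m in seq_len(n_merge)) {
    if (heights[m] > cut_height) next
    h <- heights[m]
    a <- merge[m, 1L]; b <- merge[m, 2L]
    if (a < 0L && b < 0L) {
      merge_branch[m] <- new_branch(TRUE, c(-a, -b), integer(0), 2L)
    } else if (a < 0L || b < 0L) {
      leaf <- -min(a, b)
      cl <- merge_branch[max(a, b)]
      if (br_basic[cl]) {
        br_singl[[cl]] <- c(br_singl[[cl]], leaf)
      } else {
        on_branch[leaf] <- cl
      }
      br_size[cl] <- br_size[cl] + 1L
      merge_branch[m] <- cl
    } else {
      cl <- merge_branch[c(a, b)]
      ord <- order(br_size[cl])        # smaller branch first
      small <- cl[ord[1L]]; large <- cl[ord[2L]]
      sc_small <- if (br_basic[small])
        core_scatter(br_singl[[small]], length(br_singl[[small]]),
                     min_cluster_size, distM) else 0
      sc_large <- if (br_basic[large])
        core_scatter(br_singl[[large]], length(br_singl[[large]]),
                     min_cluster_size, distM) else 0
      # a basic branch failing any criterion is merged into its sibling
      fails <- function(side, sc)
        c(br_size[side] < min_cluster_size,
          sc > max_abs_scatter,
          h - sc < min_abs_gap,
          h < min_abs_split_height)
      do_merge <- FALSE; fail_size <- FALSE
      if (br_basic[small] && any(fails(small, sc_small))) {
        do_merge <- TRUE
        f <- fails(small, sc_small)
        fail_size <- !(f[2L] || f[3L])
      } else if (br_basic[large] && any(fails(large, sc_large))) {
        do_merge <- TRUE
        f <- fails(large, sc_large)
        fail_size <- !(f[2L] || f[3L])
        tmp <- small; small <- large; large <- tmp
      }
      if (do_merge) {
        br_fail_size[small] <- fail_size
        br_merged_into[small] <- large
        br_attach[small] <- h
        br_top[small] <- FALSE
        if (br_basic[large]) {
          br_singl[[large]] <- c(br_singl[[large]], br_singl[[small]])
        } else {
          on_branch[br_singl[[small]]] <- large
        }
        br_size[large] <- br_size[large] + br_size[small]
        merge_branch[m] <- large
      } else {
        # both sides hold on to their clusters: record a composite branch
        nb <- new_branch(FALSE, integer(0),
                         c(basics_of(small), basics_of(large)),
                         br_size[small] + br_size[large])
        br_attach[c(small, large)] <- h
        br_merged_into[c(small, large)] <- nb
        merge_branch[m] <- nb
      }
    }
  }

  # mark clusters among surviving basic branches
  n_br <- length(br_basic)
  if (n_br == 0L) return(rep(0L, n))
  br_attach[is.na(br_attach)] <- cut_height
  is_cluster <- logical(n_br)
  small_group <- rep(0L, n)  # leaves of size-failed branches, by branch
  for (bidx in seq_len(n_br)) {
    if (br_top[bidx]) {
      sc <- core_scatter(br_singl[[bidx]], length(br_singl[[bidx]]),
                         min_cluster_size, distM)
      is_cluster[bidx] <- br_size[bidx] >= min_cluster_size &&
        sc < max_abs_scatter && br_attach[bidx] - sc > min_abs_gap
    }
    if (br_fail_size[bidx]) small_group[br_singl[[bidx]]] <- bidx
  }

  labels <- rep(0L, n)
  branch_label <- rep(0L, n_br)
  col <- 0L
  for (bidx in which(is_cluster)) {
    col <- col + 1L
    labels[br_singl[[bidx]]] <- col
    small_group[br_singl[[bidx]]] <- 0L
    branch_label[bidx] <- col
  }
  if (col == 0L || !pam_stage) return(labels)

  # stage 2: attach close-by leftovers to detected clusters, respecting
  # the dendrogram (candidates = clusters on the leaf's own branch)
  diam <- vapply(seq_len(col), function(k) {
    members <- which(labels == k)
    if (length(members) < 2L) return(0)
    max(colSums(distM[members, members, drop = FALSE]) /
          (length(members) - 1L))
  }, numeric(1))
  stage1 <- labels
  labels_on <- function(obj_branch) {
    if (obj_branch == 0L) return(integer(0))
    lab <- branch_label[br_basics[[obj_branch]]]
    lab[lab > 0L]
  }
  # size-failed small branches move as one unit
  for (g in setdiff(unique(small_group), 0L)) {
    members <- which(small_group == g)
    cand <- labels_on(unique(on_branch[members])[1L])
    if (length(cand) == 0L) next
    use <- which(stage1 %in% cand)
    mean_d <- colMeans(distM[members, use, drop = FALSE])
    per_cl <- tapply(mean_d, stage1[use], mean)
    best <- which.min(per_cl)
    lab <- as.integer(names(per_cl)[best])
    if (per_cl[best] < diam[lab] || per_cl[best] < max_pam_dist)
      labels[members] <- lab
  }
  leftovers <- which(labels == 0L & small_group == 0L & on_branch > 0L)
  for (obj in leftovers) {
    cand <- labels_on(on_branch[obj])
    if (length(cand) == 0L) next
    use <- which(stage1 %in% cand)
    per_cl <- tapply(distM[use, obj], stage1[use], mean)
    best <- which.min(per_cl)
    lab <- as.integer(names(per_cl)[best])
    if (per_cl[best] < diam[lab] || per_cl[best] < max_pam_dist)
      labels[obj] <- lab
  }
  labels
}
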