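#' Read a gene-by-sample expression matrix
#'
#' Expects a delimited text file with a header row of sample names and
#' gene identifiers in the first column. Rows containing any missing value
#' are rejected (no imputation: correlations on ragged data are silently
#' biased).
#'
#' @param path path to the TSV/CSV file.
#' @param sep field separator (default tab).
#' @return A numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "",
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("expression values must be numeric")
  if (anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1, any)]
    stop("missing values in expression rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (ncol(m) < 3L) stop("need at least 3 samples for correlations")
  m
}

#' Average pairwise Pearson correlation of a gene set
#'
#' The signed mean of Pearson correlation coefficients over all unordered
#' pairs of module genes present in the matrix. Genes with constant
#' expression have undefined correlations; their pairs are excluded with a
#' warning.
#'
#' @param expr numeric genes x samples matrix.
#' @param genes character vector of gene identifiers.
#' @return Mean PCC in \[-1, 1\].
#' @export
module_mean_pcc <- function(expr, genes) {
  genes <- intersect(unique(genes), rownames(expr))
  if (length(genes) < 2L)
    stop("fewer than 2 module genes present in the expression matrix")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  sub <- expr[genes, , drop = FALSE]
  const <- apply(sub, 1, stats::sd) == 0
  if (any(const)) {
    warning("constant expression, pairs excluded for: ",
            paste(genes[const], collapse = ", "))
    sub <- sub[!const, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("fewer than 2 non-constant module genes")
  }
  cm <- stats::cor(t(sub))
  mean(cm[upper.tri(cm)])
}

#' Permutation p-value for module co-expression
#'
#' Compares the observed mean pairwise PCC of a module against the mean
#' PCC of equally sized gene sets drawn at random from the whole matrix.
#' The p-value is the fraction of permutations whose random mean PCC is
#' strictly higher than the observed one (ties favor significance;
#' set `strict = FALSE` for the conservative `>=` count). The random pool
#' is the full gene universe, module genes included.
#'
#' @param expr numeric genes x samples matrix.
#' @param genes module gene set.
#' @param n_perm number of random draws (default 1000).
#' @param seed optional integer seed.
#' @param strict count strictly greater random means (default TRUE).
#' @return A `coexpression_result`: list with `mean_pcc`, `p_value`,
#'   `method = "permutation"`, `n_genes`, `n_pairs`.
#' @details The random draws are computed through row-standardized
#'   expression, for which the mean pairwise PCC of a gene set g is
#'   `(||sum_i z_i||^2 - k) / (k (k - 1))`; this is algebraically identical
#'   to averaging the correlation matrix but runs in O(k x samples) per
#'   draw. Genes with constant expression contribute zero correlation to
#'   random draws (they are excluded from the observed statistic, with a
#'   warning, by [module_mean_pcc()]).
#' @export
permutation_pvalue <- function(expr, genes, n_perm = 1000, seed = NULL,
                               strict = TRUE) {
  observed <- module_mean_pcc(expr, genes)
  present <- intersect(unique(genes), rownames(expr))
  k <- length(present)
  if (nrow(expr) <= k)
    stop("expression matrix must contain more genes than the module")
  z <- row_standardize(expr)
  rand <- with_seed(seed, {
    picks <- replicate(n_perm, sample.int(nrow(expr), k))
    sums <- rowsum(z[as.vector(picks), , drop = FALSE],
                   group = rep(seq_len(n_perm), each = k))
    (rowSums(sums^2) - k) / (k * (k - 1))
  })
  hits <- if (strict) sum(rand > observed) else sum(rand >= observed)
  coexpression_result(mean_pcc = observed, p_value = hits / n_perm,
                      method = "permutation", n_genes = k)
}

# rows scaled so that z_i . z_j = cor(x_i, x_j); constant rows become 0
row_standardize <- function(expr) {
  mu <- rowMeans(expr)
  cx <- expr - mu
  ss <- sqrt(rowSums(cx^2))
  ss[ss == 0] <- Inf
  cx / ss
}

#' Empirical null distribution of pairwise co-expression
#'
#' Draws `n_draws` random gene pairs and records their PCC, yielding an
#' empirical null against which observed pairwise correlations can be
#' tested (upper tail). The one-sided p-value of an observed PCC r is
#' `(#\{null >= r\} + 1) / (n_draws + 1)`; the +1 guard keeps p strictly
#' positive so that downstream log-based combination is well defined.
#'
#' @param expr numeric genes x samples matrix (>= 2 genes, >= 3 samples).
#' @param n_draws number of random pairs (default 10000).
#' @param seed optional integer seed.
#' @return An `empirical_null` object; use [empirical_pvalue()] to query
#'   it.
#' @export
empirical_pair_null <- function(expr, n_draws = 10000, seed = NULL) {
  if (nrow(expr) < 2L) stop("need at least 2 genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  draws <- with_seed(seed, {
    i <- sample.int(nrow(expr), n_draws, replace = TRUE)
    j_raw <- sample.int(nrow(expr) - 1L, n_draws, replace = TRUE)
    j <- ifelse(j_raw >= i, j_raw + 1L, j_raw)  # j != i, uniform
    vapply(seq_len(n_draws), function(k)
      stats::cor(expr[i[k], ], expr[j[k], ]), numeric(1))
  })
  draws <- draws[!is.na(draws)]  # constant rows give NA correlations
  structure(list(draws = sort(draws), n_draws = length(draws)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical_null: %d pairwise PCC draws (mean %.3f)\n",
              x$n_draws, mean(x$draws)))
  invisible(x)
}

#' Upper-tail empirical p-value of an observed correlation
#'
#' @param null an `empirical_null` from [empirical_pair_null()].
#' @param observed observed PCC (vectorized).
#' @return p-values in (0, 1\], guarded away from zero by the +1 rule.
#' @export
empirical_pvalue <- function(null, observed) {
  stopifnot(inherits(null, "empirical_null"))
  n <- null$n_draws
  vapply(observed, function(r)
    (sum(null$draws >= r) + 1) / (n + 1), numeric(1))
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values through the statistic
#' \eqn{X^2_{2k} = -2 \sum_i \ln p_i}, which follows a chi-squared
#' distribution with 2k degrees of freedom under the joint null; the
#' combined p-value is its upper-tail probability. For k = 1 the combined
#' p-value equals the input.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return Combined p-value.
#' @export
fisher_combined_pvalue <- function(pvalues) {
  if (length(pvalues) < 1L) stop("need at least one p-value")
  if (any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]; guard zeros upstream")
  stat <- -2 * sum(log(pvalues))
  stats::pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Module co-expression significance via Fisher's method
#'
#' For every unordered pair of module genes, computes the upper-tail
#' empirical p-value of its PCC against a pairwise null, then combines
#' the k = C(n, 2) pair p-values with [fisher_combined_pvalue()]. This is
#' the cheap alternative to [permutation_pvalue()] for large collections
#' of modules: the null is built once and reused.
#'
#' @param expr numeric genes x samples matrix.
#' @param genes module gene set (>= 2 genes present).
#' @param null an `empirical_null` from [empirical_pair_null()].
#' @return A `coexpression_result` (method `"fisher"`).
#' @export
module_fisher_pvalue <- function(expr, genes, null) {
  genes <- intersect(unique(genes), rownames(expr))
  if (length(genes) < 2L)
    stop("fewer than 2 module genes present in the expression matrix")
  cm <- suppressWarnings(stats::cor(t(expr[genes, , drop = FALSE])))
  rs <- cm[upper.tri(cm)]
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0L) stop("no valid gene pairs (constant expression)")
  p <- fisher_combined_pvalue(empirical_pvalue(null, rs))
  coexpression_result(mean_pcc = mean(rs), p_value = p,
                      method = "fisher", n_genes = length(genes))
}

coexpression_result <- function(mean_pcc, p_value, method, n_genes) {
  structure(list(mean_pcc = mean_pcc, p_value = p_value, method = method,
                 n_genes = n_genes,
                 n_pairs = n_genes * (n_genes - 1) / 2),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("coexpression_result (%s): mean PCC %.3f, p = %.4g (%d genes, %d pairs)\n",
              x$method, x$mean_pcc, x$p_value, x$n_genes, x$n_pairs))
  invisible(x)
}

#' Batch co-expression scoring of a module table
#'
#' Applies [permutation_pvalue()] or [module_fisher_pvalue()] to every
#' assigned module of a partition. Genes absent from the expression
#' matrix are dropped; modules left with fewer than 2 genes are skipped
#' (reported with NA) rather than erroring.
#'
#' @param expr numeric genes x samples matrix.
#' @param partition a [module_partition()].
#' @param method `"permutation"` or `"fisher"`.
#' @param n_perm permutations for the permutation method.
#' @param n_draws null draws for the Fisher method.
#' @param seed optional integer seed.
#' @return data.frame: `module_id`, `n_genes`, `n_pairs`, `mean_pcc`,
#'   `p_value`, `method`.
#' @export
coexpression_table <- function(expr, partition,
                               method = c("permutation", "fisher"),
                               n_perm = 1000, n_draws = 10000,
                               seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(partition, "module_partition"))
  ids <- as.integer(names(module_sizes(partition)))
  null <- if (method == "fisher")
    empirical_pair_null(expr, n_draws = n_draws, seed = seed) else NULL
  rows <- lapply(ids, function(id) {
    genes <- intersect(module_genes(partition, id), rownames(expr))
    if (length(genes) < 2L)
      return(data.frame(module_id = id, n_genes = length(genes),
                        n_pairs = 0L, mean_pcc = NA_real_,
                        p_value = NA_real_, method = method))
    res <- if (method == "permutation")
      permutation_pvalue(expr, genes, n_perm = n_perm, seed = seed)
    else module_fisher_pvalue(expr, genes, null)
    data.frame(module_id = id, n_genes = res$n_genes,
               n_pairs = res$n_pairs, mean_pcc = res$mean_pcc,
               p_value = res$p_value, method = method)
  })
  do.call(rbind, rows)
}
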