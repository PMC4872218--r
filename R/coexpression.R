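#' Spearman rank correlation of two tissue profiles
#'
#' Spearman's rho with average ranks for ties. A constant profile has no
#' ranks to correlate; the result is then `NA` with a warning (an explicit
#' undefined value, never a silent 0).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return rho in \[-1, 1\], or `NA` for a constant input.
#' @examples
#' spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_bad_arg("profiles must have equal length")
  if (length(x) < 3) stop_bad_arg("need at least 3 tissues")
  if (anyNA(x) || anyNA(y)) stop_bad_arg("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("constant profile: Spearman rho undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' P-value for a Spearman correlation (t approximation)
#'
#' Two-sided p from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Adequate at the compendium scale (n = 64 tissues);
#' for small n use [spearman_test()] with a permutation null.
#'
#' @param rho Correlation in (-1, 1); `|rho| = 1` is reported as p = 0 with
#'   a warning.
#' @param n Number of tissues (>= 4).
#' @return Two-sided p-value.
#' @examples
#' correlation_pvalue(0.8, 5)  # ~0.104
#' @export
correlation_pvalue <- function(rho, n) {
  if (n < 4) stop_bad_arg("need n >= 4")
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) > 1) stop_bad_arg("|rho| must be <= 1")
  if (abs(rho) == 1) {
    rlang::warn("|rho| = 1: p reported as 0 by convention")
    return(0)
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Spearman correlation test
#'
#' Combines [spearman_rho()] with either the t-approximation p-value or a
#' seeded permutation p-value (permuting `y`, two-sided, with the +1/(B+1)
#' correction).
#'
#' @param x,y Tissue profiles.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation null (default 1); the global RNG
#'   state is left untouched.
#' @return One-row tibble: `rho`, `p_value`, `method`.
#' @export
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 999, seed = 1) {
  method <- match.arg(method)
  rho <- suppressWarnings(spearman_rho(x, y))
  if (is.na(rho)) return(tibble(rho = NA_real_, p_value = NA_real_, method = method))
  p <- if (method == "t") {
    if (abs(rho) == 1) 0 else correlation_pvalue(rho, length(x))
  } else {
    with_seed(seed, {
      null <- replicate(n_perm, cor(x, sample(y), method = "spearman"))
      (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  tibble(rho = rho, p_value = p, method = method)
}

#' All-pairs Spearman correlations of an expression table
#'
#' @param expr Expression tibble (`gene_id` + tissue columns) or a gene x
#'   tissue matrix with rownames.
#' @return Tibble with one row per unordered gene pair: `gene_a`, `gene_b`,
#'   `rho`, `p_value`, and `significant_at` (`p01`, `p05` or `none`).
#'   Constant genes yield `NA` rho and `significant_at = "none"`.
#' @export
correlate_pairs <- function(expr) {
  m <- as_expr_matrix(expr)
  ids <- rownames(m)
  n_t <- ncol(m)
  pairs <- utils::combn(seq_along(ids), 2)
  const <- apply(m, 1, sd) == 0
  if (any(const)) rlang::warn(paste0("constant gene profile(s): ",
                                     paste(ids[const], collapse = ", ")))
  rho <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (const[i] || const[j]) NA_real_ else cor(m[i, ], m[j, ], method = "spearman")
  }, numeric(1))
  p <- vapply(rho, function(r) {
    if (is.na(r)) NA_real_
    else if (abs(r) == 1) 0
    else correlation_pvalue(r, n_t)
  }, numeric(1))
  tibble(gene_a = ids[pairs[1, ]], gene_b = ids[pairs[2, ]],
         rho = rho, p_value = p,
         significant_at = ifelse(is.na(p), "none",
                                 ifelse(p < 0.01, "p01",
                                        ifelse(p < 0.05, "p05", "none"))))
}

#' Hierarchical co-expression clustering
#'
#' Agglomerative clustering of genes with distance `1 - rho` (Spearman) and
#' average linkage, cut at `k` clusters. Rows are sorted lexicographically by
#' gene id first, making the tree (and tie-breaks) deterministic for a given
#' gene set regardless of input order. At k = 2 on the tissue compendium this
#' is the step that splits candidates into the two co-expression groups.
#'
#' @param expr Expression tibble (`gene_id` + tissue columns) or matrix.
#' @param k Number of clusters (default 2).
#' @return An object of class `coexpr_clusters`: list with `assignments`
#'   (tibble `gene_id`, `cluster`), the `hclust` tree, `k`, and the
#'   correlation matrix. `tidy()` returns the assignments.
#' @examples
#' sim <- simulate_expression(expr_config(seed = 1))
#' cl <- cluster_expression(sim$expression, k = 2)
#' tidy(cl)
#' @export
cluster_expression <- function(expr, k = 2) {
  m <- as_expr_matrix(expr)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) < k) stop_bad_arg("k exceeds the number of genes")
  if (any(apply(m, 1, sd) == 0)) stop_bad_arg("constant gene rows cannot be clustered")
  rho <- cor(t(m), method = "spearman")
  d <- as.dist(1 - rho)
  hc <- hclust(d, method = "average")
  assignments <- tibble(gene_id = rownames(m),
                        cluster = as.integer(cutree(hc, k = k)))
  structure(list(assignments = assignments, hclust = hc, k = k, rho = rho),
            class = "coexpr_clusters")
}

#' @export
print.coexpr_clusters <- function(x, ...) {
  cat("Co-expression clustering: ", nrow(x$assignments), " genes, k = ", x$k,
      " (average linkage on 1 - Spearman rho)\n", sep = "")
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Label candidate genes by reference-set co-expression
#'
#' A candidate is `cesa_associated` when it shows a significant positive
#' Spearman correlation (`rho > 0`, `p < alpha`) with a majority of the
#' CESA reference genes, `cals_associated` likewise against the CALS
#' references, `both` or `none` accordingly.
#'
#' @param expr Expression tibble or matrix containing candidates and
#'   references.
#' @param candidates Character vector of candidate gene ids.
#' @param cesa_refs,cals_refs Non-empty reference gene-id sets.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `gene_id`, `label`, and a `supporting` list column of
#'   per-reference (`ref_gene`, `rho`, `p_value`) tibbles.
#' @export
associate <- function(expr, candidates, cesa_refs, cals_refs, alpha = 0.05) {
  m <- as_expr_matrix(expr)
  if (length(cesa_refs) == 0 || length(cals_refs) == 0)
    stop_bad_arg("reference sets must be non-empty")
  missing_ref <- setdiff(c(cesa_refs, cals_refs, candidates), rownames(m))
  if (length(missing_ref) > 0)
    stop_bad_arg(paste0("gene(s) absent from matrix: ",
                        paste(missing_ref, collapse = ", ")))
  n_t <- ncol(m)
  score <- function(cand, refs) {
    purrr::map_dfr(refs, function(r) {
      rho <- suppressWarnings(spearman_rho(m[cand, ], m[r, ]))
      p <- if (is.na(rho)) NA_real_ else if (abs(rho) == 1) 0
      else correlation_pvalue(rho, n_t)
      tibble(ref_gene = r, rho = rho, p_value = p)
    })
  }
  purrr::map_dfr(candidates, function(cand) {
    sc <- score(cand, cesa_refs)
    sl <- score(cand, cals_refs)
    hit <- function(s) sum(!is.na(s$rho) & s$rho > 0 & s$p_value < alpha) > length(s$rho) / 2
    cesa <- hit(sc); cals <- hit(sl)
    label <- if (cesa && cals) "both" else if (cesa) "cesa_associated"
    else if (cals) "cals_associated" else "none"
    tibble(gene_id = cand, label = label,
           supporting = list(bind_rows(mutate(sc, ref_set = "cesa"),
                                       mutate(sl, ref_set = "cals"))))
  })
}
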