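#' Tidy an enhancement classification
#'
#' Long per-experiment view: one row per protein x experiment with blank and
#' treated totals and the total/distinct enhancement percents.
#'
#' @param x A `coip_enhancement` tibble from [classify_all()].
#' @param ... Unused.
#' @return A long tibble.
#' @method tidy coip_enhancement
#' @export
tidy.coip_enhancement <- function(x, ...) {
  if (nrow(x) == 0)
    return(tibble(protein_id = character(), experiment = integer(),
                  blank_total = integer(), treated_total = integer(),
                  pct_total = integer(), pct_distinct = integer(),
                  group = character()))
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    tibble(protein_id = r$protein_id,
           experiment = seq_len(r$n_experiments),
           blank_total = r$blank_total[[1]],
           treated_total = r$treated_total[[1]],
           pct_total = r$total_pct[[1]],
           pct_distinct = r$distinct_pct[[1]],
           group = r$group)
  })
}

#' Glance at an enhancement classification
#'
#' @param x A `coip_enhancement` tibble.
#' @param ... Unused.
#' @return One-row tibble: `n_proteins`, `n_group_I`, `n_group_II`.
#' @method glance coip_enhancement
#' @export
glance.coip_enhancement <- function(x, ...) {
  tibble(n_proteins = nrow(x),
         n_group_I = sum(x$group == "group_I"),
         n_group_II = sum(x$group == "group_II"))
}

#' Tidy a specificity classification
#'
#' @param x A `coip_specificity` tibble from [classify_specificity()].
#' @param ... Unused.
#' @return The underlying tibble, unclassed.
#' @method tidy coip_specificity
#' @export
tidy.coip_specificity <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "coip_specificity")
  out
}

#' Glance at a specificity classification
#'
#' @param x A `coip_specificity` tibble.
#' @param ... Unused.
#' @return One-row tibble of class tallies.
#' @method glance coip_specificity
#' @export
glance.coip_specificity <- function(x, ...) {
  tibble(n_proteins = nrow(x),
         n_specific_absent = sum(x$klass == "specific_absent_control"),
         n_specific_enriched = sum(x$klass == "specific_enriched"),
         n_nonspecific = sum(x$klass == "nonspecific"))
}

#' Tidy a co-expression clustering
#'
#' @param x A `coexpr_clusters` object from [cluster_expression()].
#' @param ... Unused.
#' @return The assignments tibble (`gene_id`, `cluster`).
#' @method tidy coexpr_clusters
#' @export
tidy.coexpr_clusters <- function(x, ...) x$assignments

#' Glance at a co-expression clustering
#'
#' @param x A `coexpr_clusters` object.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `k`, cluster sizes.
#' @method glance coexpr_clusters
#' @export
glance.coexpr_clusters <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  out <- tibble(n_genes = nrow(x$assignments), k = x$k)
  for (i in seq_along(sizes)) out[[paste0("size_", names(sizes)[i])]] <- as.integer(sizes[i])
  out
}

#' Tidy an assay summary
#'
#' @param x A `glucan_assay_tbl` from [summarize_assay()].
#' @param ... Unused.
#' @return The underlying tibble, unclassed.
#' @method tidy glucan_assay_tbl
#' @export
tidy.glucan_assay_tbl <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "glucan_assay_tbl")
  out
}

#' Glance at an assay summary
#'
#' @param x A `glucan_assay_tbl`.
#' @param ... Unused.
#' @return One-row tibble: conversion factor used and, when implied per-row
#'   factors are available, their relative spread.
#' @method glance glucan_assay_tbl
#' @export
glance.glucan_assay_tbl <- function(x, ...) {
  out <- tibble(n_rows = nrow(x), factor = attr(x, "factor"))
  if ("implied_factor" %in% names(x)) {
    f <- x$implied_factor
    out$implied_factor_spread <- (max(f) - min(f)) / mean(f)
  }
  out
}
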