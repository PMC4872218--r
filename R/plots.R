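#' Plot an enhancement classification
#'
#' Bar chart of the average total-count enhancement percent per protein,
#' filled by Group I/II membership.
#'
#' @param object A `coip_enhancement` tibble from [classify_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coip_enhancement
#' @export
autoplot.coip_enhancement <- function(object, ...) {
  df <- as_tibble(object[, c("protein_id", "avg_total_pct", "group")])
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$protein_id, .data$avg_total_pct),
    y = .data$avg_total_pct, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "average enhancement of total peptide counts (%)",
                  fill = "group",
                  title = "Cellulase-treatment enhancement") +
    ggplot2::theme_minimal()
}

#' Plot a specificity classification
#'
#' Per-protein target/control fold enrichment (log10 scale; infinite folds
#' from control-absent proteins are drawn at the plot ceiling), coloured by
#' class, with the fold threshold marked.
#'
#' @param object A `coip_specificity` tibble.
#' @param fold_threshold Threshold line to draw (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coip_specificity
#' @export
autoplot.coip_specificity <- function(object, fold_threshold = 2, ...) {
  df <- as_tibble(object)
  finite_max <- max(c(df$fold[is.finite(df$fold)], fold_threshold)) * 2
  df$fold_plot <- ifelse(is.finite(df$fold), df$fold, finite_max)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$protein_id, .data$fold_plot),
    y = .data$fold_plot, colour = .data$klass)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = fold_threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "target / pre-immune fold (total peptide counts)",
                  colour = "class", title = "Specificity vs pre-immune control") +
    ggplot2::theme_minimal()
}

#' Plot a co-expression clustering
#'
#' Spearman correlation heatmap with genes ordered by the dendrogram and
#' cluster membership shown on the axis labels.
#'
#' @param object A `coexpr_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coexpr_clusters
#' @export
autoplot.coexpr_clusters <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  df <- as_tibble(as.data.frame(as.table(object$rho)), .name_repair = "minimal")
  names(df) <- c("gene_a", "gene_b", "rho")
  df$gene_a <- factor(df$gene_a, levels = ord)
  df$gene_b <- factor(df$gene_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$gene_a, .data$gene_b, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  title = paste0("Co-expression clustering (k = ", object$k, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot an assay summary
#'
#' Mean incorporated product per method and glucan, with SD error bars when
#' available.
#'
#' @param object A `glucan_assay_tbl` from [summarize_assay()].
#' @param value `"cpm"` (default) or `"nmol"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glucan_assay_tbl
#' @export
autoplot.glucan_assay_tbl <- function(object, value = c("cpm", "nmol"), ...) {
  value <- match.arg(value)
  df <- as_tibble(object)
  df$y <- if (value == "cpm") df$cpm_mean else df$nmol
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$glucan, y = .data$y,
                                        fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, fill = "extraction method",
                  y = if (value == "cpm") "cpm incorporated (per mg protein)"
                  else "nmol glucose incorporated (per mg protein)",
                  title = "In vitro glucan synthesis") +
    ggplot2::theme_minimal()
  if (value == "cpm" && "cpm_sd" %in% names(df) && !anyNA(df$cpm_sd)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$cpm_sd, ymax = .data$y + .data$cpm_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2)
  }
  p
}
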