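#' Cellulase-treatment enhancement percentage
#'
#' The enhancement statistic of the analysis: the relative increase of a
#' protein's peptide count in cellulase-treated extract (T) over untreated
#' blank (B), `100 * (T - B) / B`, rounded half-up to an integer percent.
#' With a zero blank baseline the ratio is undefined and `NA` is returned
#' (never an infinity): a protein absent without treatment has no meaningful
#' relative increase.
#'
#' @param blank_count,treated_count Non-negative integer spectral counts of
#'   the same protein/experiment/metric under the target antibody. Vectorised.
#' @return Integer percent vector; may be negative; `NA` where `blank_count`
#'   is 0.
#' @examples
#' enhancement_percent(49, 82)  # 67
#' enhancement_percent(1, 11)   # 1000
#' enhancement_percent(0, 4)    # NA: undefined at zero baseline
#' @export
enhancement_percent <- function(blank_count, treated_count) {
  if (any(blank_count < 0, na.rm = TRUE) || any(treated_count < 0, na.rm = TRUE))
    stop_bad_arg("counts must be non-negative")
  out <- ifelse(blank_count > 0,
                round_half_up(100 * (treated_count - blank_count) / blank_count),
                NA_real_)
  as.integer(out)
}

#' Average per-experiment enhancement percentages
#'
#' The three-experiment summary: the arithmetic mean of the already-rounded
#' per-experiment integer percents, itself rounded half-up. Averaging the
#' rounded values (not the raw ratios) is what reproduces every printed
#' average in the packaged tables.
#'
#' @param per_experiment_pcts Integer percent vector from
#'   [enhancement_percent()].
#' @return Integer percent, or `NA` if any element is undefined.
#' @examples
#' average_enhancement(c(67, 64, 38))     # 56
#' average_enhancement(c(33, 300, 1000))  # 444
#' @export
average_enhancement <- function(per_experiment_pcts) {
  if (length(per_experiment_pcts) == 0) stop_bad_arg("empty percent list")
  if (anyNA(per_experiment_pcts)) return(NA_integer_)
  as.integer(round_half_up(mean(per_experiment_pcts)))
}

# per-protein worker: expects target-antibody rows of one protein
enhance_one <- function(cells, protein_id) {
  exps <- sort(unique(cells$experiment))
  get <- function(exp, treat, col) {
    v <- cells[cells$experiment == exp & cells$treatment == treat, ][[col]]
    if (length(v) == 0)
      stop_bad_arg(sprintf("missing cell: %s / experiment %d / target / %s",
                           protein_id, exp, treat))
    v[[1]]
  }
  b_tot <- vapply(exps, get, integer(1), treat = "blank", col = "total_peptides")
  t_tot <- vapply(exps, get, integer(1), treat = "treated", col = "total_peptides")
  b_dis <- vapply(exps, get, integer(1), treat = "blank", col = "distinct_peptides")
  t_dis <- vapply(exps, get, integer(1), treat = "treated", col = "distinct_peptides")
  pct_tot <- enhancement_percent(b_tot, t_tot)
  pct_dis <- enhancement_percent(b_dis, t_dis)
  tibble(
    protein_id = protein_id,
    n_experiments = length(exps),
    blank_total = list(b_tot), treated_total = list(t_tot),
    total_pct = list(pct_tot), distinct_pct = list(pct_dis),
    avg_total_pct = if (anyNA(pct_tot)) NA_integer_ else average_enhancement(pct_tot),
    avg_distinct_pct = if (anyNA(pct_dis)) NA_integer_ else average_enhancement(pct_dis),
    group = if (all(t_tot > b_tot)) "group_I" else "group_II"
  )
}

#' Classify one protein by cellulase enhancement
#'
#' Group I: the treated total peptide count strictly exceeds the blank count
#' in every experiment — the consistently cellulase-enhanced proteins that
#' match the printed grouping of all 19 candidates. Group II: everything
#' else (any tie or decrease). The distinct-peptide series is reported
#' alongside but does not gate the grouping, since the printed membership is
#' driven by total counts alone.
#'
#' @param profiles A `coip_profiles` tibble (or count-record tibble).
#' @param protein_id Protein to classify; must have blank and treated total
#'   counts for every experiment under the target antibody.
#' @return One-row tibble: per-experiment percent series (list columns),
#'   averages, and `group`.
#' @examples
#' profiles <- build_profiles(load_fixture("table2"))
#' classify_enhancement(profiles, "GhCALS")
#' @export
classify_enhancement <- function(profiles, protein_id) {
  cells <- profiles[profiles$protein_id == protein_id & profiles$antibody == "target", ]
  if (nrow(cells) == 0) stop_bad_arg(paste0("no target-antibody cells for ", protein_id))
  enhance_one(cells, protein_id)
}

#' Classify all proteins by cellulase enhancement
#'
#' Applies [classify_enhancement()] to every protein in the table and returns
#' a classed result; `glance()` gives the Group I / Group II tally and
#' `tidy()` a long per-experiment view. On the packaged 19-protein tables
#' this reproduces the printed grouping: 9 Group I (four GhCESAs, GhCALS and
#' four novel proteins), 10 Group II.
#'
#' @param profiles A `coip_profiles` or count-record tibble.
#' @return A tibble of class `coip_enhancement`, one row per protein.
#' @examples
#' res <- classify_all(build_profiles(load_all_counts()))
#' glance(res)
#' @export
classify_all <- function(profiles) {
  target <- profiles[profiles$antibody == "target", , drop = FALSE]
  ids <- unique(target$protein_id)
  out <- purrr::map_dfr(ids, function(id)
    enhance_one(target[target$protein_id == id, ], id))
  if (length(ids) == 0)
    out <- tibble(protein_id = character(), n_experiments = integer(),
                  blank_total = list(), treated_total = list(),
                  total_pct = list(), distinct_pct = list(),
                  avg_total_pct = integer(), avg_distinct_pct = integer(),
                  group = character())
  class(out) <- c("coip_enhancement", setdiff(class(out), "coip_profiles"))
  out
}

#' Write an enhancement table as TSV
#'
#' Flattens the list columns into per-experiment columns (blank total,
#' treated total, percent of totals and of distinct counts), mirroring the
#' layout of the printed table.
#'
#' @param result A `coip_enhancement` tibble.
#' @param path Output TSV path.
#' @return The flattened tibble, invisibly.
#' @export
write_enhancement_table <- function(result, path) {
  flat <- flatten_enhancement(result)
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(flat)
}

flatten_enhancement <- function(result) {
  if (nrow(result) == 0) {
    return(tibble(protein_id = character(), avg_total_pct = integer(),
                  avg_distinct_pct = integer(), group = character()))
  }
  wide <- purrr::map_dfr(seq_len(nrow(result)), function(i) {
    r <- result[i, ]
    e <- seq_len(r$n_experiments)
    vals <- c(r$blank_total[[1]], r$treated_total[[1]], r$total_pct[[1]], r$distinct_pct[[1]])
    names(vals) <- c(paste0("blank_total_exp", e), paste0("treated_total_exp", e),
                     paste0("pct_total_exp", e), paste0("pct_distinct_exp", e))
    as_tibble(c(list(protein_id = r$protein_id), as.list(vals),
                list(avg_total_pct = r$avg_total_pct,
                     avg_distinct_pct = r$avg_distinct_pct,
                     group = r$group)))
  })
  wide
}
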