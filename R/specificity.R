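#' Replicate-presence filter
#'
#' Retains proteins detected (total peptide count >= 1 in at least one
#' treatment cell) under the target antibody in every one of the required
#' independent experiments. This is the "found in three independent
#' experiments" rule that reduces the raw identification list to reproducible
#' candidates; detection in either the blank or the treated extract counts.
#'
#' @param profiles A `coip_profiles` or count-record tibble.
#' @param required_experiments Number of experiments a protein must appear
#'   in (default 3).
#' @return Sorted character vector of retained protein ids.
#' @examples
#' presence_filter(build_profiles(load_fixture("table3")))
#' @export
presence_filter <- function(profiles, required_experiments = 3) {
  if (required_experiments < 1) stop_bad_arg("required_experiments must be >= 1")
  target <- profiles[profiles$antibody == "target" & profiles$total_peptides >= 1, ]
  if (nrow(target) == 0) return(character())
  seen <- distinct(as_tibble(target)[, c("protein_id", "experiment")])
  tally <- summarise(group_by(seen, .data$protein_id), n_exp = n(), .groups = "drop")
  sort(tally$protein_id[tally$n_exp >= required_experiments])
}

#' Classify one protein's specificity against the pre-immune control
#'
#' Compares total peptide counts under the target antibody with those of the
#' pre-immune serum IP, summed over all experiments (and both treatments).
#' Three classes: `specific_absent_control` — never seen in the control;
#' `specific_enriched` — target/control fold at or above the threshold
#' (default 2); `nonspecific` — below it ("less than 2-fold" over the
#' background).
#'
#' @param target_counts,control_counts Per-experiment total peptide counts
#'   for the same experiments under target antibody and pre-immune control.
#' @param fold_threshold Minimum fold for `specific_enriched` (default 2,
#'   inclusive).
#' @param protein_id Optional id carried into the result.
#' @return One-row tibble: `protein_id`, `target_sum`, `control_sum`, `fold`
#'   (`Inf` when the control sum is 0) and `klass`.
#' @examples
#' specificity_classify(c(12, 9, 9), c(4, 3, 3))  # fold 3: specific_enriched
#' @export
specificity_classify <- function(target_counts, control_counts,
                                 fold_threshold = 2, protein_id = NA_character_) {
  if (length(target_counts) != length(control_counts))
    stop_bad_arg("target and control series must cover the same experiments")
  specificity_from_sums(sum(target_counts), sum(control_counts),
                        fold_threshold, protein_id)
}

specificity_from_sums <- function(ts, cs, fold_threshold, protein_id) {
  if (ts < 0 || cs < 0) stop_bad_arg("counts must be non-negative")
  if (ts == 0 && cs == 0)
    stop_bad_arg("all counts zero: protein should not have reached specificity classification")
  fold <- if (cs == 0) Inf else ts / cs
  klass <- if (cs == 0 && ts > 0) "specific_absent_control"
  else if (fold >= fold_threshold) "specific_enriched"
  else "nonspecific"
  tibble(protein_id = protein_id, target_sum = as.integer(ts),
         control_sum = as.integer(cs), fold = fold, klass = klass)
}

#' Classify all proteins' specificity
#'
#' Runs [specificity_classify()] for every protein that has pre-immune
#' control rows, summing total counts across all experiments and both
#' treatments for each antibody. `glance()` tallies the classes.
#'
#' @param profiles A `coip_profiles` or count-record tibble containing both
#'   `target` and `preimmune` antibody rows.
#' @param fold_threshold Minimum fold for `specific_enriched` (default 2).
#' @return A tibble of class `coip_specificity`, one row per protein.
#' @export
classify_specificity <- function(profiles, fold_threshold = 2) {
  ids <- sort(unique(profiles$protein_id))
  has_ctrl <- vapply(ids, function(id)
    any(profiles$antibody == "preimmune" & profiles$protein_id == id), logical(1))
  if (any(!has_ctrl)) {
    rlang::warn(paste0("no pre-immune control cells for ",
                       sum(!has_ctrl), " protein(s); skipped (not measured != zero)"))
    ids <- ids[has_ctrl]
  }
  out <- purrr::map_dfr(ids, function(id) {
    rows <- profiles[profiles$protein_id == id, ]
    specificity_from_sums(
      sum(rows$total_peptides[rows$antibody == "target"]),
      sum(rows$total_peptides[rows$antibody == "preimmune"]),
      fold_threshold = fold_threshold, protein_id = id)
  })
  if (length(ids) == 0)
    out <- tibble(protein_id = character(), target_sum = integer(),
                  control_sum = integer(), fold = double(), klass = character())
  class(out) <- c("coip_specificity", setdiff(class(out), "coip_profiles"))
  out
}
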