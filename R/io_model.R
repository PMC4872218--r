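#' Read a peptide-count table
#'
#' Reads a tab-separated table of spectral-count records, one row per measured
#' cell of the design: a protein in one experiment, under one antibody
#' (`target` = anti-GhCESA8, `preimmune` = pre-immune serum control) and one
#' extraction treatment (`blank` = no cellulase, `treated` = 1% cellulase).
#' `total_peptides` is the spectral count (total peptide-spectrum matches);
#' `distinct_peptides` the number of unique peptide sequences. A cell absent
#' from the file is "not measured", which is deliberately distinct from a
#' measured zero: true 0(0) cells occur in the packaged tables and take part
#' in classification, absences do not.
#'
#' @param path Path to a TSV file with header columns `protein_id`,
#'   `experiment`, `antibody`, `treatment`, `total_peptides`,
#'   `distinct_peptides`. Extra columns are preserved.
#' @return A tibble of validated count records.
#' @details Validation is strict: counts must be non-negative integers,
#'   `distinct_peptides` must not exceed `total_peptides`, enum columns must
#'   use the values above, and a duplicated (protein, experiment, antibody,
#'   treatment) key is rejected. Errors name the offending file line.
#' @seealso [write_count_table()], [build_profiles()], [load_fixture()]
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop_bad_arg(paste0("count table not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("protein_id", "experiment", "antibody", "treatment",
                "total_peptides", "distinct_peptides")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop_bad_arg(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
                 "coipquant_parse_error")
  validate_count_records(raw, source = path)
}

# Shared validator; `line` = file line (header is line 1) for messages.
validate_count_records <- function(raw, source = "<data>") {
  line <- seq_len(nrow(raw)) + 1L
  fail <- function(what, rows) {
    stop_bad_arg(sprintf("%s in %s (line %s)", what, source,
                         paste(line[rows], collapse = ", ")),
                 "coipquant_parse_error")
  }
  as_count <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) | x < 0 | x != floor(x)
    if (any(bad)) fail(paste0("malformed non-negative integer in '", col, "'"), which(bad))
    as.integer(x)
  }
  exper <- as_count("experiment")
  total <- as_count("total_peptides")
  dist <- as_count("distinct_peptides")
  bad_ab <- !raw$antibody %in% c("target", "preimmune")
  if (any(bad_ab)) fail("unknown antibody value", which(bad_ab))
  bad_tr <- !raw$treatment %in% c("blank", "treated")
  if (any(bad_tr)) fail("unknown treatment value", which(bad_tr))
  if (any(dist > total)) fail("distinct_peptides > total_peptides", which(dist > total))
  key <- paste(raw$protein_id, exper, raw$antibody, raw$treatment, sep = "\r")
  if (anyDuplicated(key)) fail("duplicate (protein, experiment, antibody, treatment) key",
                               which(duplicated(key)))
  out <- raw
  out$experiment <- exper
  out$total_peptides <- total
  out$distinct_peptides <- dist
  as_tibble(out)
}

#' Write a peptide-count table
#'
#' Deterministic TSV writer for count records: fixed column order, rows sorted
#' by (protein, experiment, antibody, treatment), so identical records always
#' produce identical bytes. `read_count_table()` round-trips its output.
#'
#' @param records A count-record tibble (as from [read_count_table()]).
#' @param path Output file path.
#' @return `records`, invisibly.
#' @export
write_count_table <- function(records, path) {
  lead <- c("protein_id", "experiment", "antibody", "treatment",
            "total_peptides", "distinct_peptides")
  extra <- setdiff(names(records), lead)
  out <- records[, c(lead, extra)]
  out <- arrange(out, .data$protein_id, .data$experiment, .data$antibody, .data$treatment)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(records)
}

#' Assemble per-protein count profiles
#'
#' Groups validated count records into profiles, the unit all classification
#' operates on. Profiles contain exactly the cells present in the input — no
#' imputation. Use [profile_cell()] to look up a single cell; absent cells
#' return `NA` ("not measured"), never a silent zero.
#'
#' @param records A count-record tibble.
#' @return A tibble of class `coip_profiles`, one row per measured cell,
#'   keyed and sorted.
#' @examples
#' tab2 <- load_fixture("table2")
#' profiles <- build_profiles(tab2)
#' profile_cell(profiles, "GhCALS", 3, "target", "treated")
#' @export
build_profiles <- function(records) {
  if (nrow(records) == 0) {
    out <- tibble(protein_id = character(), experiment = integer(),
                  antibody = character(), treatment = character(),
                  total_peptides = integer(), distinct_peptides = integer())
  } else {
    out <- validate_count_records(
      mutate(records, across(all_of(c("experiment", "antibody", "treatment",
                                      "total_peptides", "distinct_peptides")),
                             as.character)),
      source = "<records>")
    out <- arrange(out, .data$protein_id, .data$experiment, .data$antibody, .data$treatment)
  }
  class(out) <- c("coip_profiles", class(out))
  out
}

#' Look up one cell of a profile
#'
#' @param profiles A `coip_profiles` tibble from [build_profiles()].
#' @param protein_id,experiment,antibody,treatment Cell coordinates.
#' @return A named list with `total_peptides` and `distinct_peptides`;
#'   both `NA` when the cell was not measured.
#' @export
profile_cell <- function(profiles, protein_id, experiment,
                         antibody = "target", treatment = "blank") {
  hit <- profiles[profiles$protein_id == protein_id &
                    profiles$experiment == experiment &
                    profiles$antibody == antibody &
                    profiles$treatment == treatment, ]
  if (nrow(hit) == 0)
    return(list(total_peptides = NA_integer_, distinct_peptides = NA_integer_))
  list(total_peptides = hit$total_peptides[[1]],
       distinct_peptides = hit$distinct_peptides[[1]])
}

#' Load a packaged table fixture
#'
#' The package ships transcriptions of the four printed source tables:
#' `table1` — cpm and nmol of glucose incorporated per mg protein for the two
#' membrane-extraction methods (means and SDs, n = 3); `table2` — blank vs
#' cellulase-treated spectral counts of the four GhCESAs and GhCALS in three
#' experiments; `table3` — counts for the five well-known non-CESA proteins
#' (tubulins, KOR, sucrose synthase) with annotations; `table4` — counts for
#' the nine novel candidate proteins with their printed Group I/II labels and
#' CESA/CALS association.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return A tibble: assay summaries for `table1`, count records (with
#'   annotation columns joined for tables 3-4) otherwise.
#' @examples
#' load_fixture("table1")
#' load_fixture("table2")
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  ext <- function(f) system.file("extdata", f, package = "coipquant", mustWork = TRUE)
  if (name == "table1") {
    return(readr::read_tsv(ext("table1_glucan_assay.tsv"),
                           col_types = "ccdddd", progress = FALSE))
  }
  counts <- read_count_table(ext(paste0(name, "_counts.tsv")))
  if (name %in% c("table3", "table4")) {
    ann <- readr::read_tsv(ext(paste0(name, "_annotations.tsv")),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    counts <- left_join(counts, ann, by = "protein_id")
  }
  counts
}

#' Load the full 19-protein count set
#'
#' Convenience union of the count records of tables 2-4: the 19 proteins
#' found in all three independent anti-GhCESA8 experiments.
#'
#' @return A count-record tibble (19 proteins x 3 experiments x 2 treatments).
#' @export
load_all_counts <- function() {
  bind_rows(
    load_fixture("table2"),
    select(load_fixture("table3"), all_of(c("protein_id", "experiment", "antibody",
                                            "treatment", "total_peptides", "distinct_peptides"))),
    select(load_fixture("table4"), all_of(c("protein_id", "experiment", "antibody",
                                            "treatment", "total_peptides", "distinct_peptides")))
  )
}

#' Read / write an expression matrix
#'
#' Expression tables are TSV with a `gene_id` first column and one column per
#' tissue. At least 3 tissues are required for any correlation downstream;
#' missing values are rejected at load time.
#'
#' @param path File path.
#' @return A tibble, `gene_id` plus numeric tissue columns.
#' @export
read_expression_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  if (!"gene_id" %in% names(tbl)) stop_bad_arg("expression table needs a gene_id column",
                                               "coipquant_parse_error")
  if (ncol(tbl) - 1 < 3) stop_bad_arg("need at least 3 tissue columns")
  if (anyNA(tbl)) stop_bad_arg("missing values in expression matrix",
                               "coipquant_parse_error")
  if (anyDuplicated(tbl$gene_id)) stop_bad_arg("duplicated gene_id",
                                               "coipquant_parse_error")
  tbl
}

#' @rdname read_expression_matrix
#' @param tbl Expression tibble (`gene_id` + tissue columns).
#' @export
write_expression_matrix <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

# gene x tissue numeric matrix from either a tibble or a matrix
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop_bad_arg("expression matrix needs gene rownames")
    storage.mode(x) <- "double"
    return(x)
  }
  if (!"gene_id" %in% names(x)) stop_bad_arg("expression table needs a gene_id column")
  m <- as.matrix(x[, setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_bad_arg("missing values in expression matrix")
  m
}
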