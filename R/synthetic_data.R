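#' Configuration for the IP-MS count simulator
#'
#' Describes the statistical structure the classification stages assume: per
#' cell, total spectral counts are Poisson with a mean set by the planted
#' role of the protein, and distinct peptide numbers arise by multinomial
#' occupancy of an equiprobable peptide pool. Planted roles: every protein is
#' assigned a specificity class (`specific_absent` — never binds the
#' pre-immune control; `specific_enriched` — control binding at
#' `control_binding_fraction` of the target level; `background` — control
#' binding equal to target binding) and, independently, an enhanced flag that
#' multiplies its treated-condition mean by `enhancement_multiplier`.
#'
#' @param n_proteins Number of simulated proteins (default 60).
#' @param n_experiments Independent IP experiments (default 3).
#' @param baseline_lambda Mean spectral count in the blank condition
#'   (default 15).
#' @param enhancement_multiplier Treated-condition mean multiplier for
#'   planted-enhanced proteins (default 2, echoing the 2-4-fold count
#'   increases and 1.5-3.6-fold product increases seen under cellulase).
#' @param control_binding_fraction Pre-immune binding of
#'   `specific_enriched` proteins as a fraction of their target-antibody
#'   mean (default 0.2).
#' @param peptide_pool_size Detectable peptides per protein (default 50).
#' @param prop_enhanced Probability a protein is planted enhanced
#'   (default 1/3).
#' @param class_probs Probabilities of the three specificity classes, in the
#'   order absent/enriched/background (default 0.25, 0.25, 0.5).
#' @param overdispersion Optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson counts.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `ipms_config`.
#' @export
ipms_config <- function(n_proteins = 60, n_experiments = 3, baseline_lambda = 15,
                        enhancement_multiplier = 2, control_binding_fraction = 0.2,
                        peptide_pool_size = 50, prop_enhanced = 1 / 3,
                        class_probs = c(specific_absent = 0.25,
                                        specific_enriched = 0.25,
                                        background = 0.5),
                        overdispersion = NULL, seed = 1) {
  if (n_proteins < 1 || n_experiments < 1 || peptide_pool_size < 1)
    stop_bad_arg("sizes must be positive")
  if (baseline_lambda < 0) stop_bad_arg("baseline_lambda must be >= 0")
  if (enhancement_multiplier < 1) stop_bad_arg("enhancement_multiplier must be >= 1")
  if (control_binding_fraction < 0 || control_binding_fraction > 1)
    stop_bad_arg("control_binding_fraction must be in [0, 1]")
  if (length(class_probs) != 3 || any(class_probs < 0) || sum(class_probs) <= 0)
    stop_bad_arg("class_probs must be three non-negative weights")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_experiments = as.integer(n_experiments),
                 baseline_lambda = baseline_lambda,
                 enhancement_multiplier = enhancement_multiplier,
                 control_binding_fraction = control_binding_fraction,
                 peptide_pool_size = as.integer(peptide_pool_size),
                 prop_enhanced = prop_enhanced,
                 class_probs = class_probs / sum(class_probs),
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "ipms_config")
}

# distinct peptides: occupancy of `total` equiprobable draws over a pool
occupancy_distinct <- function(total, pool) {
  vapply(total, function(n) {
    if (n == 0) 0L else length(unique(sample.int(pool, n, replace = TRUE)))
  }, integer(1))
}

draw_counts <- function(n, mu, overdispersion) {
  if (is.null(overdispersion)) rpois(n, mu)
  else stats::rnbinom(n, size = overdispersion, mu = mu)
}

#' Simulate an IP-MS spectral-count dataset with planted truth
#'
#' Draws the full protein x experiment x antibody x treatment count table
#' the pipeline consumes, plus the planted labels needed to score recovery.
#' Cell means: target/blank = `baseline_lambda`; target/treated =
#' `baseline_lambda * enhancement_multiplier` for enhanced proteins, else
#' the baseline; pre-immune cells = 0 for `specific_absent`,
#' `control_binding_fraction` of the matching target mean for
#' `specific_enriched`, and equal to the matching target mean for
#' `background` binders. Distinct counts are occupancy draws bounded by
#' `min(total, peptide_pool_size)`.
#'
#' @param config An [ipms_config()].
#' @return List: `records` (count tibble, both antibodies) and `truth`
#'   (tibble `protein_id`, `enhanced`, `spec_class`, `specific`), with the
#'   generator parameters attached as `attr(truth, "params")`.
#' @examples
#' sim <- simulate_ipms(ipms_config(n_proteins = 8, seed = 42))
#' head(sim$records)
#' @export
simulate_ipms <- function(config) {
  stopifnot(inherits(config, "ipms_config"))
  with_seed(config$seed, {
    ids <- sprintf("prot_%03d", seq_len(config$n_proteins))
    enhanced <- stats::runif(config$n_proteins) < config$prop_enhanced
    spec_class <- sample(c("specific_absent", "specific_enriched", "background"),
                         config$n_proteins, replace = TRUE, prob = config$class_probs)
    grid <- tidyr::expand_grid(protein_id = ids,
                               experiment = seq_len(config$n_experiments),
                               antibody = c("target", "preimmune"),
                               treatment = c("blank", "treated"))
    idx <- match(grid$protein_id, ids)
    mu_target <- ifelse(grid$treatment == "treated" & enhanced[idx],
                        config$baseline_lambda * config$enhancement_multiplier,
                        config$baseline_lambda)
    ctrl_scale <- c(specific_absent = 0,
                    specific_enriched = config$control_binding_fraction,
                    background = 1)[spec_class[idx]]
    mu <- ifelse(grid$antibody == "target", mu_target, mu_target * ctrl_scale)
    total <- as.integer(draw_counts(nrow(grid), mu, config$overdispersion))
    distinct <- occupancy_distinct(total, config$peptide_pool_size)
    records <- mutate(grid, total_peptides = total, distinct_peptides = distinct)
    truth <- tibble(protein_id = ids, enhanced = enhanced, spec_class = spec_class,
                    specific = spec_class %in% c("specific_absent", "specific_enriched"))
    attr(truth, "params") <- unclass(config)
    list(records = records, truth = truth)
  })
}

#' Configuration for the expression-matrix simulator
#'
#' Emulates a tissue compendium with planted co-expression modules: genes of
#' a module are `loading_strength` times a shared latent tissue profile plus
#' Gaussian noise; background genes are pure standard-normal noise. The
#' defaults (64 tissues, two 10-gene modules, loading 1, noise SD 0.3) give
#' within-module Spearman rho around 0.9 and near-zero across modules.
#'
#' @param n_tissues Number of tissues (default 64).
#' @param module_sizes Named integer vector of module sizes
#'   (default `c(cesa_module = 10, cals_module = 10)`).
#' @param n_background Unstructured genes (default 10).
#' @param loading_strength Latent-profile loading (default 1).
#' @param noise_sd Within-module noise SD (default 0.3).
#' @param seed Integer seed.
#' @return A list of class `expr_config`.
#' @export
expr_config <- function(n_tissues = 64,
                        module_sizes = c(cesa_module = 10, cals_module = 10),
                        n_background = 10, loading_strength = 1,
                        noise_sd = 0.3, seed = 1) {
  if (n_tissues < 3) stop_bad_arg("need at least 3 tissues")
  if (any(module_sizes < 1)) stop_bad_arg("module sizes must be positive")
  if (is.null(names(module_sizes))) names(module_sizes) <- paste0("module_", seq_along(module_sizes))
  if (noise_sd < 0 || loading_strength <= 0) stop_bad_arg("invalid strength/noise")
  structure(list(n_tissues = as.integer(n_tissues), module_sizes = module_sizes,
                 n_background = as.integer(n_background),
                 loading_strength = loading_strength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expr_config")
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' @param config An [expr_config()].
#' @return List: `expression` (tibble `gene_id` + tissue columns) and
#'   `truth` (tibble `gene_id`, `module`; background genes labeled
#'   `"background"`), generator parameters attached as `attr(truth, "params")`.
#' @examples
#' sim <- simulate_expression(expr_config(seed = 7))
#' cluster_expression(sim$expression, k = 2)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_config"))
  with_seed(config$seed, {
    tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
    rows <- list(); modules <- character(); ids <- character()
    for (mn in names(config$module_sizes)) {
      latent <- rnorm(config$n_tissues)
      for (g in seq_len(config$module_sizes[[mn]])) {
        ids <- c(ids, sprintf("%s_g%02d", mn, g))
        modules <- c(modules, mn)
        rows[[length(rows) + 1]] <- config$loading_strength * latent +
          rnorm(config$n_tissues, sd = config$noise_sd)
      }
    }
    for (g in seq_len(config$n_background)) {
      ids <- c(ids, sprintf("bg_g%02d", g))
      modules <- c(modules, "background")
      rows[[length(rows) + 1]] <- rnorm(config$n_tissues)
    }
    m <- do.call(rbind, rows)
    expression <- as_tibble(setNames(as.data.frame(m), tissues))
    expression <- tibble(gene_id = ids, !!!expression)
    truth <- tibble(gene_id = ids, module = modules)
    attr(truth, "params") <- unclass(config)
    list(expression = expression, truth = truth)
  })
}

#' Simulate radioassay readings
#'
#' Generates cpm-per-mg readings from true product amounts through the
#' inverse of the cpm-to-nmol conversion, with multiplicative Gaussian noise
#' of coefficient of variation `noise_cv`, truncated at zero. Triplicate
#' defaults mirror the biological-triplicate design of the assay.
#'
#' @param true_nmol Named (or unnamed) vector of true nmol per mg protein.
#' @param factor nmol per cpm conversion factor (> 0).
#' @param noise_cv Coefficient of variation of the reading noise
#'   (default 0.05).
#' @param n_replicates Replicates per sample (default 3).
#' @param seed Integer seed.
#' @return Tibble: `sample_id`, `replicate`, `true_nmol`, `cpm_per_mg`.
#' @export
simulate_assay <- function(true_nmol, factor, noise_cv = 0.05,
                           n_replicates = 3, seed = 1) {
  if (factor <= 0) stop_bad_arg("factor must be positive")
  if (noise_cv < 0 || n_replicates < 1) stop_bad_arg("invalid noise/replicates")
  if (any(true_nmol < 0)) stop_bad_arg("true_nmol must be non-negative")
  ids <- names(true_nmol) %||% sprintf("sample_%02d", seq_along(true_nmol))
  with_seed(seed, {
    grid <- tidyr::expand_grid(sample_id = ids, replicate = seq_len(n_replicates))
    tn <- true_nmol[match(grid$sample_id, ids)]
    cpm <- pmax(0, tn / factor * (1 + rnorm(nrow(grid), sd = noise_cv)))
    tibble(sample_id = grid$sample_id, replicate = grid$replicate,
           true_nmol = unname(tn), cpm_per_mg = cpm)
  })
}

#' Write / read a planted-truth table
#'
#' Truth tables round-trip through TSV unchanged (logical columns included),
#' so simulated datasets can be regenerated and re-scored from disk.
#'
#' @param truth Truth tibble from a simulator.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                  progress = FALSE)
}
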