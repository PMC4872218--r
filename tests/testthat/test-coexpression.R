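test_that("Spearman rho handles perfect, reversed and tied profiles", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "3 tissues")
  # invariant under strictly monotone transforms
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_rho(exp(a), b^3 + 2 * b), spearman_rho(a, b))
})

test_that("Spearman rho matches the rank-then-Pearson brute force", {
  set.seed(22)
  for (i in 1:250) {
    n <- sample(5:40, 1)
    x <- if (i %% 2 == 0) rnorm(n) else sample(1:6, n, replace = TRUE) # with ties
    y <- if (i %% 3 == 0) rnorm(n) else sample(1:5, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("the t-approximation p-value behaves as the transform dictates", {
  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(0.8, 5), 0.104, tolerance = 1e-3)
  expect_warning(p <- correlation_pvalue(1, 10), "convention")
  expect_equal(p, 0)
  # decreasing in |rho| at fixed n, symmetric in sign
  rhos <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(rhos, correlation_pvalue, numeric(1), n = 20)
  expect_true(all(diff(ps) < 0))
  expect_equal(correlation_pvalue(-0.6, 20), correlation_pvalue(0.6, 20))
  expect_error(correlation_pvalue(0.5, 3), "n >= 4")
})

test_that("permutation and t p-values agree for clear effects at moderate n", {
  set.seed(23)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.6)
  tt <- spearman_test(x, y, method = "t")
  pp <- spearman_test(x, y, method = "permutation", n_perm = 499, seed = 9)
  expect_lt(tt$p_value, 0.01)
  expect_lt(pp$p_value, 0.01)
  # seeded permutation is reproducible and leaves the global RNG untouched
  before <- .Random.seed
  pp2 <- spearman_test(x, y, method = "permutation", n_perm = 499, seed = 9)
  expect_identical(.Random.seed, before)
  expect_equal(pp$p_value, pp2$p_value)
})

test_that("all-pairs correlation flags significance levels and constants", {
  sim <- simulate_expression(expr_config(module_sizes = c(m1 = 3, m2 = 3),
                                         n_background = 2, seed = 31))
  pairs <- correlate_pairs(sim$expression)
  expect_equal(nrow(pairs), choose(8, 2))
  within <- pairs[grepl("^m1", pairs$gene_a) & grepl("^m1", pairs$gene_b), ]
  expect_true(all(within$significant_at == "p01"))
  # constant gene: NA rho, never significant
  expr2 <- sim$expression
  expr2[1, -1] <- as.list(rep(1, 64))
  expect_warning(p2 <- correlate_pairs(expr2), "constant")
  flagged <- p2[p2$gene_a == expr2$gene_id[1] | p2$gene_b == expr2$gene_id[1], ]
  expect_true(all(is.na(flagged$rho)))
  expect_true(all(flagged$significant_at == "none"))
})

test_that("hierarchical clustering recovers planted modules deterministically", {
  sim <- simulate_expression(expr_config(n_background = 0, seed = 41))
  cl <- cluster_expression(sim$expression, k = 2)
  joined <- dplyr::inner_join(tidy(cl), sim$truth, by = "gene_id")
  tab <- table(joined$cluster, joined$module)
  expect_equal(min(apply(tab, 1, max)), 10)  # each cluster is one pure module
  expect_equal(max(tab) + min(tab), max(tab)) # no mixing
  # input order does not matter
  shuffled <- sim$expression[sample(nrow(sim$expression)), ]
  cl2 <- cluster_expression(shuffled, k = 2)
  expect_equal(tidy(cl2), tidy(cl))
  # k = 1 puts everything together; duplicated genes land together
  expect_equal(unique(tidy(cluster_expression(sim$expression, k = 1))$cluster), 1L)
  dup <- sim$expression[c(1, 1, 5, 11), ]
  dup$gene_id <- c("a_copy1", "a_copy2", "other", "far")
  cld <- tidy(cluster_expression(dup, k = 3))
  expect_equal(cld$cluster[cld$gene_id == "a_copy1"],
               cld$cluster[cld$gene_id == "a_copy2"])
  expect_error(cluster_expression(sim$expression, k = 100), "exceeds")
})

test_that("association labels candidates by reference co-expression", {
  sim <- simulate_expression(expr_config(seed = 51))
  cesa_refs <- paste0("cesa_module_g", sprintf("%02d", 1:3))
  cals_refs <- paste0("cals_module_g", sprintf("%02d", 1:3))
  cands <- c("cesa_module_g05", "cals_module_g05", "bg_g01")
  lab <- associate(sim$expression, cands, cesa_refs, cals_refs)
  expect_equal(lab$label[lab$gene_id == "cesa_module_g05"], "cesa_associated")
  expect_equal(lab$label[lab$gene_id == "cals_module_g05"], "cals_associated")
  expect_equal(lab$label[lab$gene_id == "bg_g01"], "none")
  # candidate identical to a reference profile: rho = 1 against it
  sup <- lab$supporting[[2]]
  expect_true(all(sup$rho[sup$ref_set == "cals"] > 0.5))
  expect_error(associate(sim$expression, cands, character(), cals_refs), "non-empty")
  expect_error(associate(sim$expression, "nope", cesa_refs, cals_refs), "absent")
})

test_that("white-noise candidates stay unlabeled at about the nominal rate", {
  # for a null candidate, each reference supports it (rho > 0, p < alpha)
  # with probability below alpha; the per-set majority label is rarer still
  set.seed(61)
  n_rep <- 200
  sim <- simulate_expression(expr_config(seed = 62))
  m <- as.data.frame(sim$expression)
  per_ref_hits <- 0L; cesa_labels <- 0L; cals_labels <- 0L
  for (i in seq_len(n_rep)) {
    cand <- tibble::tibble(gene_id = "null_cand",
                           !!!stats::setNames(as.list(rnorm(64)), names(m)[-1]))
    lab <- associate(dplyr::bind_rows(sim$expression, cand), "null_cand",
                     paste0("cesa_module_g", sprintf("%02d", 1:3)),
                     paste0("cals_module_g", sprintf("%02d", 1:3)))
    sup <- lab$supporting[[1]]
    per_ref_hits <- per_ref_hits + sum(sup$rho > 0 & sup$p_value < 0.05)
    cesa_labels <- cesa_labels + (lab$label %in% c("cesa_associated", "both"))
    cals_labels <- cals_labels + (lab$label %in% c("cals_associated", "both"))
  }
  expect_lte(per_ref_hits / (n_rep * 6), 0.05)
  expect_lte(cesa_labels / n_rep, 0.05)
  expect_lte(cals_labels / n_rep, 0.05)
})
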