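test_that("enhancement percent follows the (T-B)/B contract", {
  expect_equal(enhancement_percent(49, 82), 67L)
  expect_equal(enhancement_percent(1, 11), 1000L)
  expect_equal(enhancement_percent(5, 5), 0L)
  expect_true(is.na(enhancement_percent(0, 4)))   # zero baseline: undefined
  expect_equal(enhancement_percent(48, 44), -8L)  # negative, not clamped
  expect_error(enhancement_percent(-1, 4), "non-negative")
  # strictly increasing in treated count at fixed blank
  pcts <- enhancement_percent(rep(7L, 50), seq(0L, 490L, by = 10L))
  expect_true(all(diff(pcts) > 0))
})

test_that("enhancement percent agrees with exact rational arithmetic", {
  set.seed(101)
  blank <- sample(0:400, 1000, replace = TRUE)
  treated <- sample(0:1200, 1000, replace = TRUE)
  expect_equal(enhancement_percent(blank, treated),
               as.integer(oracle_enhancement(blank, treated)))
})

test_that("averaging happens on the rounded per-experiment percents", {
  expect_equal(average_enhancement(c(67, 64, 38)), 56L)
  expect_equal(average_enhancement(c(33, 300, 1000)), 444L)
  expect_equal(average_enhancement(c(0, 0, 0)), 0L)
  expect_true(is.na(average_enhancement(c(10, NA, 20))))
  expect_error(average_enhancement(integer()), "empty")
  set.seed(102)
  for (i in 1:200) {
    pcts <- sample(-100:1000, sample(2:5, 1))
    expect_equal(average_enhancement(pcts), as.integer(oracle_average(pcts)))
  }
})

test_that("every printed percent and average of the synthase table is reproduced", {
  res <- classify_all(build_profiles(load_fixture("table2")))
  for (id in names(printed_table2)) {
    row <- res[res$protein_id == id, ]
    exp <- printed_table2[[id]]
    # per-experiment: within 1 point (the source's own rounding wobbles once)
    expect_true(all(abs(row$total_pct[[1]] - exp$tot) <= 1), label = paste(id, "totals"))
    expect_true(all(abs(row$distinct_pct[[1]] - exp$dis) <= 1), label = paste(id, "distinct"))
    # averages: exact
    expect_equal(row$avg_total_pct, exp$avg_tot, label = paste(id, "avg total"))
    expect_equal(row$avg_distinct_pct, exp$avg_dis, label = paste(id, "avg distinct"))
  }
})

test_that("group assignment is strict increase of totals in every experiment", {
  profiles <- build_profiles(load_all_counts())
  expect_equal(classify_enhancement(profiles, "GhCALS")$group, "group_I")
  expect_equal(classify_enhancement(
    profiles, "glyceraldehyde-3-phosphate dehydrogenase C subunit")$group, "group_II")
  # all ties: no strict increase anywhere
  tied <- build_profiles(tibble::tibble(
    protein_id = "tied", experiment = rep(1:3, each = 2), antibody = "target",
    treatment = rep(c("blank", "treated"), 3),
    total_peptides = rep(5L, 6), distinct_peptides = rep(2L, 6)))
  expect_equal(classify_enhancement(tied, "tied")$group, "group_II")
  # missing cell is an error naming the cell
  holey <- profiles[!(profiles$protein_id == "GhCESA1" & profiles$experiment == 2 &
                        profiles$treatment == "treated"), ]
  expect_error(classify_enhancement(holey, "GhCESA1"), "GhCESA1 / experiment 2")
})

test_that("the 19-protein tables split into the printed 9 + 10 groups", {
  res <- classify_all(build_profiles(load_all_counts()))
  expect_equal(glance(res)$n_group_I, 9)
  expect_equal(glance(res)$n_group_II, 10)
  expect_setequal(res$protein_id[res$group == "group_I"], expected_group_I)
  # empty and single-protein edge cases
  empty <- classify_all(build_profiles(load_fixture("table2")[0, ]))
  expect_equal(glance(empty)$n_proteins, 0)
  one <- classify_all(build_profiles(load_fixture("table2")[
    load_fixture("table2")$protein_id == "GhCALS", ]))
  expect_equal(glance(one)$n_group_I, 1)
  expect_equal(glance(one)$n_group_II, 0)
})

test_that("tidy and the TSV writer flatten the per-experiment series faithfully", {
  res <- classify_all(build_profiles(load_fixture("table2")))
  long <- tidy(res)
  expect_equal(nrow(long), 15)
  expect_equal(long$pct_total[long$protein_id == "GhCALS"],
               c(33L, 300L, 1000L))
  path <- withr::local_tempfile(fileext = ".tsv")
  flat <- write_enhancement_table(res, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$avg_total_pct, res$avg_total_pct)
  expect_equal(back$pct_total_exp3[back$protein_id == "GhCALS"], 1000)
})
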