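# Independent oracles used to cross-check the implementation.

# Enhancement percent by exact integer rational arithmetic:
# floor(100*(t-b)/b + 1/2) computed without floating point as
# floor((200*(t-b) + b) / (2*b)); R's %/% floors toward -Inf, which is
# exactly round-half-up (ties toward +Inf) on the rational value.
oracle_enhancement <- function(blank, treated) {
  ifelse(blank > 0L,
         (200L * (treated - blank) + blank) %/% (2L * blank),
         NA_integer_)
}

oracle_average <- function(pcts) {
  # mean of k integers rounded half-up, exactly: floor((2*sum + k) / (2*k))
  k <- length(pcts)
  (2L * sum(pcts) + k) %/% (2L * k)
}

# Spearman by brute force: average ranks, then Pearson through the explicit
# sum formula (no call to cor()).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Printed per-experiment enhancement percents and averages of the five
# synthase proteins (total counts; distinct in *_dis), for fidelity checks.
printed_table2 <- list(
  GhCESA1 = list(tot = c(67, 64, 38), dis = c(48, 13, 8), avg_tot = 56, avg_dis = 23),
  GhCESA2 = list(tot = c(71, 112, 45), dis = c(33, 18, 19), avg_tot = 76, avg_dis = 23),
  GhCESA7 = list(tot = c(38, 52, 57), dis = c(15, 40, 41), avg_tot = 49, avg_dis = 32),
  GhCESA8 = list(tot = c(38, 56, 48), dis = c(23, 22, 47), avg_tot = 47, avg_dis = 31),
  GhCALS  = list(tot = c(33, 300, 1000), dis = c(0, 200, 700), avg_tot = 444, avg_dis = 300)
)

expected_group_I <- c(
  "GhCESA1", "GhCESA2", "GhCESA7", "GhCESA8", "GhCALS",
  "phenylcoumaran benzylic ether reductase-like protein",
  "vacuolar H+-ATPase catalytic subunit",
  "ubiquitin extension protein",
  "3-ketoacyl-CoA reductase 1"
)
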