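#' Round half-up
#'
#' Rounding used throughout the count arithmetic: ties at .5 go up (towards
#' +Inf), unlike base R's banker's rounding. This is the convention that
#' reproduces the printed per-experiment enhancement percentages and their
#' three-experiment averages from the packaged count tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, -8.33, 112.9))
#' round_half_up(1.725, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

# Run code with a private RNG stream: seeds locally, restores the caller's
# global .Random.seed afterwards so generators never perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_bad_arg <- function(msg, class = "coipquant_error") {
  rlang::abort(msg, class = c(class, "coipquant_error"))
}
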