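#' Derive independent sub-seeds from one master seed
#'
#' All stochastic stages of the pipeline (gamete simulation, bulk selection,
#' read sampling, null-band simulation) draw their own sub-seed from a single
#' master seed, so that each stage is independently reproducible and changing
#' the number of draws in one stage does not perturb the others.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return An integer vector of `n` sub-seeds, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(42, 3)
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(n), n >= 1)
  withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max - 1L, as.integer(n))
  )
}

# shared assertion helpers ----------------------------------------------------

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s, got %s",
                  name, min, deparse(substitute(x))))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(as.numeric(x))
}
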