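# Simulation-based confidence band for the delta-SNP-index under no linkage:
# resample bulk genotypes at an unlinked locus, then binomial reads, and take
# empirical two-sided quantiles of the resulting delta per sequencing depth.

#' Null confidence band for the delta-SNP-index
#'
#' At a locus unlinked to the causal gene both bulks are random draws from
#' the segregating population (genotypes 1:2:1 in an F2; 1:1 het/hom-mutant
#' in a BC1 to the mutant parent), so the pool allele frequencies are
#' resampled accordingly (each of `2 * bulk_size` allele copies is an
#' independent Bernoulli draw), read counts are Binomial(depth, f), and the
#' empirical two-sided quantiles of `delta = index_y - index_g` give the
#' band at each depth.
#'
#' @param bulk_size_g,bulk_size_y Individuals per pool.
#' @param depths Integer vector of per-pool sequencing depths at which to
#'   tabulate the band (default 4 to 60).
#' @param design `"F2"` or `"BC1"`.
#' @param n_sims Simulations per depth (>= 1000; default 10000).
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param seed Integer seed.
#' @return A tibble of class `bsa_null_band`: `depth`, `level`, `lower`,
#'   `upper`, with `n_sims` and `seed` as attributes.
#' @export
null_band <- function(bulk_size_g = 30, bulk_size_y = 30,
                      depths = c(4:60), design = c("F2", "BC1"),
                      n_sims = 10000, levels = c(0.95, 0.99), seed = 1L) {
  design <- match.arg(design)
  if (n_sims < 1) abort("n_sims must be >= 1 (>= 1000 recommended)")
  assert_count(bulk_size_g, "bulk_size_g")
  assert_count(bulk_size_y, "bulk_size_y")
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1)) abort("depths must be >= 1")

  per_depth <- function(d) {
    delta <- .simulate_null_deltas(bulk_size_g, bulk_size_y, d, design, n_sims)
    purrr::map_dfr(levels, function(lv) {
      q <- quantile(delta, c((1 - lv) / 2, 1 - (1 - lv) / 2), names = FALSE)
      tibble(depth = d, level = lv, lower = q[1], upper = q[2])
    })
  }
  out <- withr::with_seed(as.integer(seed), purrr::map_dfr(depths, per_depth))
  attr(out, "n_sims") <- n_sims
  attr(out, "seed") <- as.integer(seed)
  attr(out, "design") <- design
  class(out) <- c("bsa_null_band", class(out))
  out
}

# Draw n delta-SNP-index values at an unlinked locus; exported for the
# coverage checks in the test-suite via bsa_null_deltas().
.simulate_null_deltas <- function(bulk_size_g, bulk_size_y, depth, design,
                                  n) {
  pool_freq <- function(bulk_size) {
    if (design == "F2") {
      rbinom(n, 2L * bulk_size, 0.5) / (2 * bulk_size)   # 1:2:1 genotypes
    } else {
      (bulk_size + rbinom(n, bulk_size, 0.5)) / (2 * bulk_size)  # dosage 1 or 2
    }
  }
  idx_g <- rbinom(n, depth, pool_freq(bulk_size_g)) / depth
  idx_y <- rbinom(n, depth, pool_freq(bulk_size_y)) / depth
  idx_y - idx_g
}

#' Fresh draws of the unlinked-locus delta-SNP-index
#'
#' Convenience generator used to check the band's empirical coverage.
#'
#' @inheritParams null_band
#' @param depth Single per-pool depth.
#' @param n Number of draws.
#' @return Numeric vector of `n` delta values.
#' @export
bsa_null_deltas <- function(bulk_size_g = 30, bulk_size_y = 30, depth = 25,
                            design = c("F2", "BC1"), n = 10000, seed = 1L) {
  design <- match.arg(design)
  withr::with_seed(as.integer(seed),
    .simulate_null_deltas(bulk_size_g, bulk_size_y, depth, design, n))
}
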