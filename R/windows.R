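# Sliding-window aggregation of per-site indices: fixed window advanced by a
# fixed step, unweighted means of the member sites' statistics.

#' Sliding-window genome scan
#'
#' Windows start at 1, 1 + step, 1 + 2*step, ... on every chromosome; each
#' window `[start, start + window_size)` (1-based start, half-open end)
#' aggregates the unweighted mean index and delta of the sites it contains.
#' Windows with no sites are flagged `empty`; trailing windows truncated by
#' the chromosome end keep their true (shorter) span and are flagged
#' `partial`.
#'
#' @param records A filtered `bsa_index_table` (see [filter_sites()]);
#'   sites with undefined indices are ignored.
#' @param window_size Window width in bp (default 1 Mb).
#' @param step Step between window starts in bp (default 10 kb).
#' @param chrom_lengths Optional named vector of chromosome lengths; default
#'   is each chromosome's largest site position.
#' @return A tibble of class `bsa_windows`: `chrom`, `start`, `end`
#'   (half-open), `n_sites`, `mean_index_g`, `mean_index_y`, `mean_delta`,
#'   `mean_depth` (mean per-pool depth, used to look up the null band),
#'   `empty`, `partial`.
#' @export
sliding_windows <- function(records, window_size = 1e6, step = 1e4,
                            chrom_lengths = NULL) {
  stopifnot(inherits(records, "bsa_index_table"))
  if (!(window_size >= step && step > 0)) {
    abort("need window_size >= step > 0")
  }
  records <- records[!is.na(records$index_g) & !is.na(records$index_y), ]
  records <- arrange(records, .data$chrom, .data$pos)
  chroms <- unique(records$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms,
      function(cn) max(records$pos[records$chrom == cn]), numeric(1))
  }

  per_chrom <- function(cn) {
    r <- records[records$chrom == cn, ]
    len <- chrom_lengths[[cn]]
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window_size, len + 1)
    pos <- r$pos
    # sites with start <= pos < end, via cumulative sums over sorted sites
    lo <- findInterval(starts - 1, pos)        # sites strictly before start
    hi <- findInterval(ends - 1, pos)          # sites with pos <= end - 1
    csum <- function(v) cumsum(c(0, v))
    n <- hi - lo
    m <- function(v) {
      s <- csum(v)
      ifelse(n > 0, (s[hi + 1] - s[lo + 1]) / n, NA_real_)
    }
    tibble(
      chrom = cn, start = as.integer(starts), end = as.integer(ends),
      n_sites = as.integer(n),
      mean_index_g = m(r$index_g), mean_index_y = m(r$index_y),
      mean_delta = m(r$delta),
      mean_depth = m((r$depth_g + r$depth_y) / 2),
      empty = n == 0,
      partial = (starts + window_size) > len + 1
    )
  }

  out <- purrr::map_dfr(chroms, per_chrom)
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  class(out) <- c("bsa_windows", class(out))
  out
}
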