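# Candidate-region calling: windows whose mean delta exceeds the null band's
# upper bound are significant; runs of overlapping or adjacent significant
# windows merge into maximal candidate intervals.

#' Call candidate regions from a window scan
#'
#' A non-empty window is significant when its `mean_delta` exceeds the upper
#' bound of the null band at the window's mean per-pool depth (nearest
#' tabulated depth). Overlapping or book-ended significant windows are
#' merged into maximal intervals.
#'
#' @param windows A `bsa_windows` tibble from [sliding_windows()].
#' @param band A `bsa_null_band` from [null_band()].
#' @param level Confidence level; must be one of the band's levels
#'   (default 0.95).
#' @return A tibble of class `bsa_regions`: `chrom`, `start`, `end`
#'   (1-based, half-open end), `peak_delta` (largest member-window
#'   `mean_delta`), `n_windows`.
#' @export
call_candidate_regions <- function(windows, band, level = 0.95) {
  stopifnot(inherits(windows, "bsa_windows"), inherits(band, "bsa_null_band"))
  b <- band[abs(band$level - level) < 1e-9, ]
  if (nrow(b) == 0) {
    abort(sprintf("level %s is not tabulated in the band (has: %s)",
                  level, paste(unique(band$level), collapse = ", ")))
  }
  w <- windows[!windows$empty & windows$n_sites > 0, ]
  empty_regions <- tibble(chrom = character(), start = integer(),
                          end = integer(), peak_delta = numeric(),
                          n_windows = integer())
  if (nrow(w) == 0) {
    class(empty_regions) <- c("bsa_regions", class(empty_regions))
    return(empty_regions)
  }
  nearest <- vapply(w$mean_depth,
                    function(d) which.min(abs(b$depth - d)), integer(1))
  sig <- w$mean_delta > b$upper[nearest]
  w <- w[sig, ]
  if (nrow(w) == 0) {
    class(empty_regions) <- c("bsa_regions", class(empty_regions))
    return(empty_regions)
  }
  w <- arrange(w, .data$chrom, .data$start)
  # merge overlapping/adjacent half-open intervals into maximal runs
  new_run <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                 w$start[-1] > cummax_by(w$end, w$chrom)[-nrow(w)])
  run <- cumsum(new_run)
  out <- w |>
    mutate(run = run) |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1],
              start = min(.data$start),
              end = max(.data$end),
              peak_delta = max(.data$mean_delta),
              n_windows = dplyr::n(),
              .groups = "drop") |>
    select(!"run") |>
    arrange(.data$chrom, .data$start)
  class(out) <- c("bsa_regions", class(out))
  out
}

# running maximum of v restarted at each new value of the grouping key
cummax_by <- function(v, key) {
  unlist(lapply(split(v, factor(key, levels = unique(key))), cummax),
         use.names = FALSE)
}

#' Write candidate regions as BED
#'
#' Converts the 1-based inclusive-start, half-open-end internal intervals to
#' BED's 0-based half-open convention.
#'
#' @param regions A `bsa_regions` tibble.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  stopifnot(inherits(regions, "bsa_regions"))
  bed <- tibble(chrom = regions$chrom,
                start = regions$start - 1L,
                end = regions$end - 1L,
                name = sprintf("candidate_%d", seq_len(nrow(regions))),
                score = round(1000 * pmin(1, pmax(0, regions$peak_delta))))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Run the whole SNP-index scan on a variant table
#'
#' Chains [polarize()], [compute_snp_index()], [filter_sites()],
#' [sliding_windows()] and [call_candidate_regions()].
#'
#' @param table A [variant_table()].
#' @param band A [null_band()]; computed from `bulk_size` and the table's
#'   median pool depth when omitted.
#' @param bulk_size Individuals per pool (used only to build a default band).
#' @param window_size,step Window parameters (defaults 1 Mb / 10 kb).
#' @param level Band confidence level.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param seed Seed for the default band simulation.
#' @return A list with `index` (per-site records after filtering),
#'   `windows`, `regions`, and the `band` used.
#' @export
bsa_scan <- function(table, band = NULL, bulk_size = 30,
                     window_size = 1e6, step = 1e4, level = 0.95,
                     chrom_lengths = NULL, seed = 1L) {
  polarized <- polarize(table)
  rec <- filter_sites(compute_snp_index(polarized))
  if (is.null(band)) {
    band <- null_band(bulk_size, bulk_size, seed = seed)
  }
  win <- sliding_windows(rec, window_size, step, chrom_lengths)
  reg <- call_candidate_regions(win, band, level)
  list(index = rec, windows = win, regions = reg, band = band)
}
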