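# Per-site SNP-index and delta-SNP-index, and the published site filters.

#' Per-pool SNP-index
#'
#' The SNP-index of a pool at a site is the proportion of reads carrying the
#' variant (alt) allele: `alt / (ref + alt)`. Undefined (NA) when the pool
#' has no reads at the site.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @return Numeric vector of fractions in `[0, 1]`, NA where depth is zero.
#' @export
#' @examples
#' snp_index(3, 7)   # 0.7
#' snp_index(10, 0)  # 0
snp_index <- function(ref_count, alt_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  depth <- ref_count + alt_count
  ifelse(depth == 0, NA_real_, alt_count / depth)
}

#' Delta-SNP-index
#'
#' The SNP-index of the mutant-phenotype (Y) pool minus that of the
#' wild-type (G) pool. Near a locus causal for the selected recessive
#' phenotype the expectation is 1 - 1/3 = 2/3 in an F2 design; at unlinked
#' loci it is 0.
#'
#' @param index_g,index_y Per-pool SNP-indices (vectorised).
#' @return `index_y - index_g`, in `[-1, 1]`; NA propagates.
#' @export
delta_snp_index <- function(index_g, index_y) {
  index_y - index_g
}

#' Compute per-site SNP-index records from a variant table
#'
#' @param table A [variant_table()] (ideally [polarize()]d so that alt is
#'   the mutant-parent allele).
#' @return A tibble of class `bsa_index_table` with columns `chrom`, `pos`,
#'   `index_g`, `index_y`, `depth_g`, `depth_y`, `delta`. Sites where a pool
#'   has zero depth get NA indices (they are excluded from windows).
#' @export
compute_snp_index <- function(table) {
  table <- variant_table(table)
  out <- tibble(
    chrom = table$chrom, pos = table$pos,
    index_g = snp_index(table$g_ref, table$g_alt),
    index_y = snp_index(table$y_ref, table$y_alt),
    depth_g = table$g_ref + table$g_alt,
    depth_y = table$y_ref + table$y_alt
  )
  out$delta <- delta_snp_index(out$index_g, out$index_y)
  class(out) <- c("bsa_index_table", class(out))
  out
}

#' Filter SNP-index records before the window scan
#'
#' Removes (a) sites where the SNP-index is below `low_index` in *both*
#' pools (uninformative sites, usually shared background variants), and
#' (b) sites sequenced below `min_depth`. The depth rule is applied per pool
#' by default (`depth_semantics = "per_pool"`: a site must reach `min_depth`
#' in each pool); `"summed"` applies it to the two pools' combined depth.
#' Sites with an undefined index in either pool are removed as undefined.
#'
#' @param records A `bsa_index_table` from [compute_snp_index()].
#' @param low_index Both-pool index threshold (default 0.3).
#' @param min_depth Minimum depth (default 7).
#' @param depth_semantics `"per_pool"` or `"summed"`.
#' @return The filtered records; removal counts by reason are attached as
#'   attribute `"removed"`.
#' @export
#' @examples
#' rec <- compute_snp_index(variant_table(tibble::tibble(
#'   chrom = "A03", pos = c(100L, 200L), ref = "C", alt = "T",
#'   p1_ref = 20L, p1_alt = 0L, p2_ref = 0L, p2_alt = 20L,
#'   g_ref = c(16L, 10L), g_alt = c(4L, 10L),
#'   y_ref = c(15L, 0L), y_alt = c(5L, 20L))))
#' filter_sites(rec)  # site 100 (0.2/0.25) removed, site 200 (0.5/1) kept
filter_sites <- function(records, low_index = 0.3, min_depth = 7,
                         depth_semantics = c("per_pool", "summed")) {
  depth_semantics <- match.arg(depth_semantics)
  stopifnot(inherits(records, "bsa_index_table"))
  undefined <- is.na(records$index_g) | is.na(records$index_y)
  low_both <- !undefined &
    records$index_g < low_index & records$index_y < low_index
  shallow <- if (depth_semantics == "per_pool") {
    records$depth_g < min_depth | records$depth_y < min_depth
  } else {
    (records$depth_g + records$depth_y) < min_depth
  }
  keep <- !undefined & !low_both & !shallow
  removed <- c(undefined_index = sum(undefined),
               low_index_both_pools = sum(low_both & !undefined),
               low_depth = sum(shallow & !low_both & !undefined))
  out <- records[keep, ]
  attr(out, "removed") <- removed
  out
}
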