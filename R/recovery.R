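# Parameter-recovery study: repeated synthetic experiments scored for
# whether the called candidate region contains the true causal position.

#' Replicate the synthetic mapping experiment and score recovery
#'
#' Runs `n_reps` independent bulk-segregant experiments under the default
#' study conditions (F2 of 927 plants, 30/30 bulks, ~25x pooled depth,
#' 0.001 read error, recessive locus at A03:2,500,000 on a 3 x 10 Mb
#' genome with one SNP per 10 kb), maps each with the SNP-index scan, and
#' records per replicate whether the called candidate region contains the
#' causal position, the peak window's mean delta, the number of called
#' regions, and the mean delta at unlinked sites (the other chromosomes).
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate r uses the r-th derived sub-seed.
#' @param genome,design,causal,bulks,sequencing Study conditions
#'   (see [simulate_bsa_experiment()]).
#' @param band A [null_band()]; computed once from a derived sub-seed when
#'   omitted.
#' @param level Band confidence level.
#' @return A tibble of class `bsa_recovery`, one row per replicate:
#'   `rep`, `contained`, `peak_delta`, `n_regions`, `region_span_mb`,
#'   `mean_delta_unlinked`.
#' @export
bsa_recovery_study <- function(n_reps = 100, seed = 1L,
                               genome = genome_spec(),
                               design = cross_design(),
                               causal = causal_locus(),
                               bulks = bulk_spec(),
                               sequencing = seq_spec(),
                               band = NULL, level = 0.95) {
  seeds <- split_seed(seed, n_reps + 1)
  if (is.null(band)) {
    band <- null_band(bulks$bulk_size, bulks$bulk_size,
                      design = design$kind, seed = seeds[n_reps + 1])
  }
  chrom_lengths <- setNames(genome$chromosomes$length,
                            genome$chromosomes$name)
  loci <- default_loci(genome)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    ex <- simulate_bsa_experiment(genome, design, causal, bulks, sequencing,
                                  loci = loci, seed = seeds[r])
    sc <- suppressMessages(
      bsa_scan(ex$variants, band = band, level = level,
               chrom_lengths = chrom_lengths))
    reg <- sc$regions
    hit <- reg$chrom == causal$chromosome &
      reg$start <= causal$position & reg$end > causal$position
    unlinked <- sc$index$chrom != causal$chromosome
    tibble(
      rep = r,
      contained = any(hit),
      peak_delta = if (nrow(sc$windows)) {
        max(sc$windows$mean_delta[!sc$windows$empty], na.rm = TRUE)
      } else NA_real_,
      n_regions = nrow(reg),
      region_span_mb = if (any(hit)) {
        sum(reg$end[hit] - reg$start[hit]) / 1e6
      } else NA_real_,
      mean_delta_unlinked = mean(sc$index$delta[unlinked])
    )
  }) |> structure(class = c("bsa_recovery", class(tibble())))
}
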