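# Recombinant-driven fine mapping: in a panel of homozygous-mutant
# individuals, any marker genotype other than homozygous-mutant is a
# recombination event between that marker and the causal locus; the locus is
# confined between the innermost flanking markers that still show
# recombinants.

#' Genotype a marker panel from a simulated population
#'
#' Converts allele dosages at the requested marker loci into fine-mapping
#' genotype calls for a set of individuals (typically the mutant-phenotype
#' plants).
#'
#' @param pop A `bsa_population`.
#' @param marker_pos Tibble (`chrom`, `pos`, optionally `name`) of marker
#'   loci; each must be one of `pop`'s simulated loci.
#' @param individuals Integer indices of the individuals to genotype
#'   (default: all mutant-phenotype individuals).
#' @return A long tibble of class `marker_genotypes`: `individual`,
#'   `marker`, `chrom`, `pos`, `genotype` (one of `hom_mutant`, `het`,
#'   `hom_wildtype`, or NA for missing).
#' @export
genotype_markers <- function(pop, marker_pos, individuals = NULL) {
  stopifnot(inherits(pop, "bsa_population"))
  marker_pos <- as_tibble(marker_pos)
  if (!"name" %in% names(marker_pos)) {
    marker_pos$name <- sprintf("M%02d", seq_len(nrow(marker_pos)))
  }
  if (is.null(individuals)) {
    individuals <- which(pop$phenotype == "mutant")
    if (length(individuals) == 0) abort("no mutant-phenotype individuals")
  }
  j <- purrr::map2_int(marker_pos$chrom, marker_pos$pos, function(cn, p) {
    k <- which(pop$loci$chrom == cn & pop$loci$pos == p)
    if (length(k) != 1) abort(sprintf("marker %s:%d is not a simulated locus",
                                      cn, p))
    k
  })
  calls <- c("hom_wildtype", "het", "hom_mutant")
  out <- tidyr::expand_grid(individual = individuals,
                            mk = seq_len(nrow(marker_pos))) |>
    mutate(marker = marker_pos$name[.data$mk],
           chrom = marker_pos$chrom[.data$mk],
           pos = marker_pos$pos[.data$mk],
           genotype = calls[pop$dosage[cbind(.data$individual, j[.data$mk])] + 1L]) |>
    select(!"mk")
  class(out) <- c("marker_genotypes", class(out))
  out
}

#' Narrow the locus between flanking recombinant markers
#'
#' Every individual in the panel is homozygous mutant at the causal locus
#' (recessive phenotype), so for each marker a recombinant is any individual
#' whose genotype is not `hom_mutant` (missing genotypes are ignored).
#' Markers with zero recombinants form the co-segregating core; the mapped
#' interval is bounded by the innermost marker on each side of the core that
#' shows at least one recombinant. If no marker on a side shows a
#' recombinant, that flank stays at the outermost marker and is flagged
#' open.
#'
#' @param markers A `marker_genotypes` tibble (one chromosome at a time).
#' @return An object of class `fine_map_interval`: a list with `left`,
#'   `right` (marker names), `chrom`, `start`, `end` (bp of the flanking
#'   markers), `span` (bp), `open_left`, `open_right`, and
#'   `recombinants` (per-marker tibble: `marker`, `pos`, `n_recombinant`,
#'   `n_typed`).
#' @export
map_interval <- function(markers) {
  stopifnot(inherits(markers, "marker_genotypes"))
  if (nrow(markers) == 0) abort("no marker genotypes supplied")
  if (length(unique(markers$chrom)) != 1) {
    abort("map_interval works on one chromosome at a time")
  }
  if (length(unique(markers$individual)) == 0) abort("no individuals")

  per_marker <- markers |>
    group_by(.data$marker, .data$pos) |>
    summarise(
      n_recombinant = sum(.data$genotype != "hom_mutant", na.rm = TRUE),
      n_typed = sum(!is.na(.data$genotype)),
      .groups = "drop") |>
    arrange(.data$pos)

  rec <- per_marker$n_recombinant > 0
  core <- which(!rec)
  if (length(core) == 0) {
    # no co-segregating marker: centre on the marker(s) with fewest
    # recombinants and flank with their neighbours
    core <- which(per_marker$n_recombinant == min(per_marker$n_recombinant))
  }
  left_candidates <- which(rec & seq_along(rec) < min(core))
  right_candidates <- which(rec & seq_along(rec) > max(core))
  open_left <- length(left_candidates) == 0
  open_right <- length(right_candidates) == 0
  li <- if (open_left) 1L else max(left_candidates)
  ri <- if (open_right) nrow(per_marker) else min(right_candidates)

  structure(
    list(left = per_marker$marker[li], right = per_marker$marker[ri],
         chrom = markers$chrom[1],
         start = per_marker$pos[li], end = per_marker$pos[ri],
         span = per_marker$pos[ri] - per_marker$pos[li],
         open_left = open_left, open_right = open_right,
         recombinants = per_marker),
    class = "fine_map_interval"
  )
}

#' @export
print.fine_map_interval <- function(x, ...) {
  cat(sprintf(
    "<fine_map_interval> %s:%d-%d (%.1f kb) flanked by %s%s and %s%s\n",
    x$chrom, x$start, x$end, x$span / 1000,
    x$left, if (x$open_left) " (open)" else "",
    x$right, if (x$open_right) " (open)" else ""))
  invisible(x)
}
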