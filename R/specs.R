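# Experiment-design value objects for the synthetic bulk-segregant generator.
# Each constructor validates its invariants once; downstream code trusts them.

#' Describe a (reduced) genome for simulation
#'
#' @param chromosomes A data frame with columns `name` and `length` (bp).
#'   Defaults to a desk-scale stand-in for the *Brassica napus* genome:
#'   three 10-Mb chromosomes, the third named "A03" so that default fixtures
#'   mirror the chromosome carrying the yellow-virescent-leaf locus.
#' @param recomb_rate Recombination rate in centimorgan per megabase, applied
#'   uniformly along every chromosome. Default 2.5 cM/Mb, in the range implied
#'   by published *B. napus* genetic maps (roughly 2000-2500 cM over ~850 Mb).
#' @return An object of class `genome_spec`.
#' @export
#' @examples
#' genome_spec()
#' genome_spec(tibble::tibble(name = "chr1", length = 5e6), recomb_rate = 4)
genome_spec <- function(chromosomes = NULL, recomb_rate = 2.5) {
  if (is.null(chromosomes)) {
    chromosomes <- tibble(name = c("A01", "A02", "A03"), length = rep(1e7, 3))
  }
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("name", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `name` and `length`")
  }
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name)) abort("chromosome names must be unique")
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be > 0")
  assert_fraction(recomb_rate, "recomb_rate", lo = 0, hi = Inf)
  structure(
    list(chromosomes = chromosomes[c("name", "length")],
         recomb_rate = as.numeric(recomb_rate)),
    class = "genome_spec"
  )
}

#' Describe the cross that produced the segregating population
#'
#' @param kind `"F2"` (selfed F1) or `"BC1"` (F1 backcrossed to the mutant
#'   parent).
#' @param population_size Number of individuals genotyped/phenotyped.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(kind = c("F2", "BC1"), population_size = 927) {
  kind <- match.arg(kind)
  assert_count(population_size, "population_size")
  structure(list(kind = kind, population_size = as.integer(population_size)),
            class = "cross_design")
}

#' Place the single recessive causal locus
#'
#' @param chromosome Chromosome name.
#' @param position 1-based bp position.
#' @return An object of class `causal_locus`. Inheritance is always recessive:
#'   only dosage-2 (homozygous mutant) individuals show the mutant phenotype.
#' @export
causal_locus <- function(chromosome = "A03", position = 2.5e6) {
  assert_count(position, "position")
  structure(list(chromosome = as.character(chromosome),
                 position = as.integer(position),
                 inheritance = "recessive"),
            class = "causal_locus")
}

#' Describe the phenotype-selected bulks
#'
#' @param bulk_size Individuals per pool (both pools use the same size;
#'   default 30, the study design this generator emulates).
#' @return An object of class `bulk_spec`. The mutant-phenotype pool is the
#'   "Y" (yellow) pool, the wild-type pool the "G" (green) pool.
#' @export
bulk_spec <- function(bulk_size = 30) {
  assert_count(bulk_size, "bulk_size")
  structure(list(bulk_size = as.integer(bulk_size)), class = "bulk_spec")
}

#' Describe the pooled-sequencing read model
#'
#' @param mean_depth Expected reads per site per pool (default 25, between
#'   the ~27x and ~30x pool depths typical of a BSA-seq experiment).
#' @param error_rate Per-read probability of reporting the wrong allele
#'   (default 0.001).
#' @param depth_model `"poisson"` (per-site depth ~ Poisson(mean_depth)) or
#'   `"fixed"` (every site sequenced at exactly `mean_depth`).
#' @return An object of class `seq_spec`.
#' @export
seq_spec <- function(mean_depth = 25, error_rate = 0.001,
                     depth_model = c("poisson", "fixed")) {
  depth_model <- match.arg(depth_model)
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("`mean_depth` must be > 0")
  }
  assert_fraction(error_rate, "error_rate", 0, 0.5 - 1e-12)
  structure(list(mean_depth = as.numeric(mean_depth),
                 error_rate = as.numeric(error_rate),
                 depth_model = depth_model),
            class = "seq_spec")
}

#' Default marker loci: one SNP every `spacing` bp along every chromosome
#'
#' @param genome A [genome_spec()].
#' @param spacing Distance between consecutive loci in bp (default 10 kb,
#'   i.e. ~1000 loci per 10-Mb chromosome).
#' @return A tibble with columns `chrom`, `pos`, sorted.
#' @export
default_loci <- function(genome, spacing = 1e4) {
  stopifnot(inherits(genome, "genome_spec"))
  purrr::map2_dfr(genome$chromosomes$name, genome$chromosomes$length,
    function(nm, len) tibble(chrom = nm, pos = seq(spacing, len, by = spacing)))
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds one mapping with keys `genome` (`chromosomes`: list of
#' `name`/`length`; `recomb_rate`), `cross` (`kind`, `population_size`),
#' `causal` (`chromosome`, `position`), `bulks` (`bulk_size`), `sequencing`
#' (`mean_depth`, `error_rate`, `depth_model`) and `seed`. Missing keys fall
#' back to the package defaults.
#'
#' @param path Path to the YAML file.
#' @return A named list of spec objects plus the integer `seed`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  genome <- if (is.null(cfg$genome)) genome_spec() else {
    chroms <- if (is.null(cfg$genome$chromosomes)) NULL else
      purrr::map_dfr(cfg$genome$chromosomes, as_tibble)
    genome_spec(chroms, cfg$genome$recomb_rate %||% 2.5)
  }
  cross <- cross_design(cfg$cross$kind %||% "F2",
                        cfg$cross$population_size %||% 927)
  causal <- causal_locus(cfg$causal$chromosome %||% "A03",
                         cfg$causal$position %||% 2.5e6)
  bulks <- bulk_spec(cfg$bulks$bulk_size %||% 30)
  seqs <- seq_spec(cfg$sequencing$mean_depth %||% 25,
                   cfg$sequencing$error_rate %||% 0.001,
                   cfg$sequencing$depth_model %||% "poisson")
  list(genome = genome, cross = cross, causal = causal, bulks = bulks,
       sequencing = seqs, seed = as.integer(cfg$seed %||% 1L))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosome(s), %.1f Mb total, %.2f cM/Mb\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              x$recomb_rate))
  invisible(x)
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("<cross_design> %s, n = %d\n", x$kind, x$population_size))
  invisible(x)
}
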