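# Synthetic bulk-segregant experiments: gamete formation under the Haldane
# model (Poisson crossovers, no interference), recessive phenotype assignment,
# phenotype-selected bulks, and binomial read sampling of the pools.

#' Simulate a segregating population at a set of marker loci
#'
#' Gametes are formed per chromosome with a crossover count drawn from a
#' Poisson distribution with mean equal to the chromosome's map length in
#' Morgans (`recomb_rate` x physical length), crossover positions uniform,
#' and no interference -- the Haldane model. An F2 individual is the sum of
#' two independent F1 gametes; a BC1 individual (backcross to the mutant
#' parent) is one F1 gamete plus a constant mutant-parent gamete, so its
#' dosage is always 1 or 2.
#'
#' @param genome A [genome_spec()].
#' @param design A [cross_design()].
#' @param loci Tibble of marker positions (`chrom`, `pos`), sorted by
#'   position within each chromosome.
#' @param causal A [causal_locus()]; must be one of `loci` if phenotypes are
#'   to be assigned later.
#' @param seed Integer seed; the same seed reproduces the same population.
#' @return An object of class `bsa_population`: a list with `loci` (tibble),
#'   `dosage` (integer matrix, individuals x loci, copies of the
#'   mutant-parent allele in 0/1/2), `phenotype` (filled by
#'   [assign_phenotypes()]), and `design`.
#' @export
#' @examples
#' g <- genome_spec()
#' pop <- simulate_population(g, cross_design("F2", 50), default_loci(g),
#'                            causal_locus(), seed = 1)
#' table(pop$dosage[, 1])
simulate_population <- function(genome, design, loci, causal, seed) {
  stopifnot(inherits(genome, "genome_spec"), inherits(design, "cross_design"))
  loci <- as_tibble(loci)
  if (nrow(loci) == 0) abort("`loci` is empty: nothing to simulate")
  if (!all(c("chrom", "pos") %in% names(loci))) {
    abort("`loci` needs columns `chrom` and `pos`")
  }
  chroms <- genome$chromosomes
  bad_chrom <- setdiff(unique(loci$chrom), chroms$name)
  if (length(bad_chrom)) {
    abort(sprintf("loci reference unknown chromosome(s): %s",
                  paste(bad_chrom, collapse = ", ")))
  }
  lens <- setNames(chroms$length, chroms$name)
  if (any(loci$pos < 1 | loci$pos > lens[loci$chrom])) {
    abort("locus position outside chromosome bounds")
  }
  loci <- arrange(loci, match(.data$chrom, chroms$name), .data$pos)
  if (!is.null(causal)) {
    stopifnot(inherits(causal, "causal_locus"))
    if (causal$position > lens[[causal$chromosome]] %||% 0) {
      abort("causal locus outside chromosome bounds")
    }
  }

  n <- design$population_size
  n_gam <- if (design$kind == "F2") 2L else 1L
  dosage <- matrix(0L, nrow = n, ncol = nrow(loci))

  withr::with_seed(as.integer(seed), {
    for (cn in unique(loci$chrom)) {
      idx <- which(loci$chrom == cn)
      pos <- loci$pos[idx]
      morgans <- genome$recomb_rate * (lens[[cn]] / 1e6) / 100
      block <- matrix(0L, nrow = n, ncol = length(idx))
      for (g in seq_len(n_gam)) {
        block <- block + .simulate_gametes(n, pos, lens[[cn]], morgans)
      }
      if (design$kind == "BC1") block <- block + 1L  # mutant-parent gamete
      dosage[, idx] <- block
    }
  })

  structure(
    list(loci = loci, dosage = dosage, phenotype = rep(NA_character_, n),
         design = design),
    class = "bsa_population"
  )
}

# One F1 gamete per row: at each locus, 0 = wild-type allele, 1 = mutant
# allele. Crossover breakpoints partition the chromosome into alternating
# parental segments.
.simulate_gametes <- function(n, pos, chrom_len, morgans) {
  out <- matrix(0L, nrow = n, ncol = length(pos))
  k <- rpois(n, morgans)
  start <- rbinom(n, 1L, 0.5)
  for (i in seq_len(n)) {
    if (k[i] == 0L) {
      out[i, ] <- start[i]
    } else {
      xo <- sort(runif(k[i], 0, chrom_len))
      out[i, ] <- (start[i] + findInterval(pos, xo)) %% 2L
    }
  }
  out
}

#' Assign phenotypes under a single recessive locus
#'
#' With complete penetrance (the default), an individual shows the mutant
#' phenotype if and only if it carries two copies of the mutant-parent allele
#' at the causal locus; heterozygotes and wild-type homozygotes are
#' wild-type. An optional misclassification rate flips each phenotype call
#' independently, emulating phenotyping error (default 0: visual phenotype
#' classes are assumed clean).
#'
#' @param pop A `bsa_population` from [simulate_population()].
#' @param causal A [causal_locus()]; must coincide with one of `pop$loci`.
#' @param misclass_rate Probability a phenotype is recorded wrongly.
#' @param seed Seed used only when `misclass_rate > 0`.
#' @return `pop` with `phenotype` filled ("mutant" / "wildtype").
#' @export
assign_phenotypes <- function(pop, causal, misclass_rate = 0, seed = 1L) {
  stopifnot(inherits(pop, "bsa_population"), inherits(causal, "causal_locus"))
  j <- which(pop$loci$chrom == causal$chromosome &
               pop$loci$pos == causal$position)
  if (length(j) != 1) {
    abort(sprintf("causal locus %s:%d is not one of the simulated loci",
                  causal$chromosome, causal$position))
  }
  ph <- ifelse(pop$dosage[, j] == 2L, "mutant", "wildtype")
  if (misclass_rate > 0) {
    assert_fraction(misclass_rate, "misclass_rate")
    flip <- withr::with_seed(as.integer(seed),
                             runif(length(ph)) < misclass_rate)
    ph[flip] <- ifelse(ph[flip] == "mutant", "wildtype", "mutant")
  }
  pop$phenotype <- ph
  pop$causal_index <- j
  pop
}

#' Select the phenotype-extreme bulks
#'
#' Samples `bulk_size` individuals uniformly without replacement from each
#' phenotype class: the mutant-phenotype individuals form the Y (yellow)
#' pool, the wild-type individuals the G (green) pool.
#'
#' @param pop A phenotyped `bsa_population`.
#' @param spec A [bulk_spec()].
#' @param seed Integer seed.
#' @return A list with integer index vectors `g` and `y` (disjoint).
#' @export
select_bulks <- function(pop, spec, seed) {
  stopifnot(inherits(pop, "bsa_population"), inherits(spec, "bulk_spec"))
  if (all(is.na(pop$phenotype))) abort("phenotypes not assigned yet")
  mut <- which(pop$phenotype == "mutant")
  wt <- which(pop$phenotype == "wildtype")
  for (cls in list(list("mutant", mut), list("wildtype", wt))) {
    if (length(cls[[2]]) < spec$bulk_size) {
      abort(sprintf(
        "not enough %s individuals for a bulk of %d (have %d, short by %d)",
        cls[[1]], spec$bulk_size, length(cls[[2]]),
        spec$bulk_size - length(cls[[2]])))
    }
  }
  seeds <- split_seed(seed, 2)
  y <- withr::with_seed(seeds[1], sample(mut, spec$bulk_size))
  g <- withr::with_seed(seeds[2], sample(wt, spec$bulk_size))
  list(g = sort(g), y = sort(y))
}

#' Simulate pooled sequencing read depths over the bulks and parents
#'
#' Per site and pool, total depth follows the depth model; the number of
#' mutant-allele (alt) reads is Binomial(depth, f(1-e) + (1-f)e) where f is
#' the mutant-allele frequency among the pool's individuals at that site and
#' e the per-read error rate. Parents are emitted homozygous (f = 0 for the
#' wild-type parent P1, f = 1 for the mutant parent P2) under the same model.
#'
#' @param pop A `bsa_population`.
#' @param bulks Bulk index sets from [select_bulks()].
#' @param seqspec A [seq_spec()].
#' @param seed Integer seed.
#' @param ref_allele,alt_allele Allele labels written to the table; the alt
#'   allele is the mutant-parent allele by construction (C->T mirrors the
#'   EMS transition spectrum).
#' @return A [variant_table()] tibble with per-sample ref/alt depths.
#' @export
simulate_read_depths <- function(pop, bulks, seqspec, seed,
                                 ref_allele = "C", alt_allele = "T") {
  stopifnot(inherits(pop, "bsa_population"), inherits(seqspec, "seq_spec"))
  n_sites <- nrow(pop$loci)
  f_g <- colMeans(pop$dosage[bulks$g, , drop = FALSE]) / 2
  f_y <- colMeans(pop$dosage[bulks$y, , drop = FALSE]) / 2
  eps <- seqspec$error_rate

  draw_pool <- function(f) {
    depth <- if (seqspec$depth_model == "fixed") {
      rep(as.integer(round(seqspec$mean_depth)), n_sites)
    } else {
      rpois(n_sites, seqspec$mean_depth)
    }
    alt <- rbinom(n_sites, depth, f * (1 - eps) + (1 - f) * eps)
    list(ref = depth - alt, alt = alt)
  }

  withr::with_seed(as.integer(seed), {
    p1 <- draw_pool(rep(0, n_sites))
    p2 <- draw_pool(rep(1, n_sites))
    g <- draw_pool(f_g)
    y <- draw_pool(f_y)
  })

  variant_table(tibble(
    chrom = pop$loci$chrom, pos = pop$loci$pos,
    ref = ref_allele, alt = alt_allele,
    p1_ref = p1$ref, p1_alt = p1$alt,
    p2_ref = p2$ref, p2_alt = p2$alt,
    g_ref = g$ref, g_alt = g$alt,
    y_ref = y$ref, y_alt = y$alt
  ))
}

#' Run a whole synthetic bulk-segregant experiment
#'
#' Convenience wrapper chaining [simulate_population()],
#' [assign_phenotypes()], [select_bulks()] and [simulate_read_depths()],
#' with per-stage sub-seeds derived from one master seed.
#'
#' @param genome,design,causal,bulks,sequencing Spec objects (defaults
#'   reproduce the emulated study design: F2 of 927, bulks of 30, ~25x
#'   pooled depth, recessive locus at A03:2,500,000 on a 3 x 10 Mb genome).
#' @param loci Marker loci tibble; default one SNP per 10 kb.
#' @param seed Master integer seed.
#' @return A list with `variants` (a [variant_table()]), `truth` (tibble:
#'   causal chromosome/position and bulk memberships), `population`, and
#'   `bulk_idx`.
#' @export
#' @examples
#' \donttest{
#' ex <- simulate_bsa_experiment(design = cross_design("F2", 200), seed = 7)
#' ex$truth
#' }
simulate_bsa_experiment <- function(genome = genome_spec(),
                                    design = cross_design(),
                                    causal = causal_locus(),
                                    bulks = bulk_spec(),
                                    sequencing = seq_spec(),
                                    loci = NULL,
                                    seed = 1L) {
  loci <- loci %||% default_loci(genome)
  seeds <- split_seed(seed, 3)
  pop <- simulate_population(genome, design, loci, causal, seed = seeds[1])
  pop <- assign_phenotypes(pop, causal)
  idx <- select_bulks(pop, bulks, seed = seeds[2])
  vt <- simulate_read_depths(pop, idx, sequencing, seed = seeds[3])
  truth <- tibble(
    chrom = causal$chromosome, pos = causal$position,
    g_bulk = paste(idx$g, collapse = ","),
    y_bulk = paste(idx$y, collapse = ",")
  )
  list(variants = vt, truth = truth, population = pop, bulk_idx = idx)
}

#' Write the simulation truth file
#'
#' @param truth The `truth` tibble from [simulate_bsa_experiment()].
#' @param path Output TSV path.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @export
print.bsa_population <- function(x, ...) {
  ph <- if (all(is.na(x$phenotype))) "unphenotyped" else
    paste(sum(x$phenotype == "mutant"), "mutant /",
          sum(x$phenotype == "wildtype"), "wildtype")
  cat(sprintf("<bsa_population> %s, %d individuals x %d loci (%s)\n",
              x$design$kind, nrow(x$dosage), ncol(x$dosage), ph))
  invisible(x)
}
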