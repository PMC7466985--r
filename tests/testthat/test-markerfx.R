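# Fine mapping, coding-effect annotation, and CAPS scanning.

make_marker_genotypes <- function(geno_matrix, pos, chrom = "A03") {
  # geno_matrix: individuals x markers with values in
  # {hom_mutant, het, hom_wildtype, NA}
  n <- nrow(geno_matrix); m <- ncol(geno_matrix)
  out <- tidyr::expand_grid(individual = seq_len(n), mk = seq_len(m)) |>
    dplyr::mutate(marker = sprintf("M%02d", mk), chrom = chrom,
                  pos = pos[mk],
                  genotype = geno_matrix[cbind(individual, mk)]) |>
    dplyr::select(!"mk")
  class(out) <- c("marker_genotypes", class(out))
  out
}

test_that("recombinants only at the outer markers span the whole panel", {
  gm <- matrix("hom_mutant", nrow = 5, ncol = 5)
  gm[1, 1] <- "het"; gm[2, 5] <- "hom_wildtype"
  mk <- make_marker_genotypes(gm, pos = c(1e5, 2e5, 3e5, 4e5, 5e5))
  iv <- map_interval(mk)
  expect_identical(iv$left, "M01")
  expect_identical(iv$right, "M05")
  expect_identical(iv$span, 4e5)
  expect_false(iv$open_left || iv$open_right)
})

test_that("innermost recombinant markers flank the co-segregating core", {
  gm <- matrix("hom_mutant", nrow = 6, ncol = 7)
  gm[1:3, 1] <- "het"; gm[4, 2] <- "hom_wildtype"   # recombinants left
  gm[5, 6] <- "het"; gm[1:2, 7] <- "het"            # recombinants right
  mk <- make_marker_genotypes(gm, pos = (1:7) * 1e5)
  iv <- map_interval(mk)
  expect_identical(iv$left, "M02")
  expect_identical(iv$right, "M06")
  expect_identical(iv$span, 4e5)
  expect_identical(iv$recombinants$n_recombinant,
                   c(3L, 1L, 0L, 0L, 0L, 1L, 2L))
})

test_that("zero recombinants everywhere leaves both flanks open", {
  gm <- matrix("hom_mutant", nrow = 4, ncol = 3)
  gm[2, 2] <- NA  # missing genotypes are ignored, not recombinant
  mk <- make_marker_genotypes(gm, pos = c(1e5, 2e5, 3e5))
  iv <- map_interval(mk)
  expect_true(iv$open_left && iv$open_right)
  expect_identical(iv$left, "M01")
  expect_identical(iv$right, "M03")
  expect_error(map_interval(mk[0, ]), "no marker")
})

test_that("map_interval is monotone in markers and individuals", {
  gm <- matrix("hom_mutant", nrow = 8, ncol = 6)
  gm[1, 1] <- "het"; gm[2, 2] <- "het"; gm[3, 6] <- "het"
  pos <- (1:6) * 1e5
  mk_all <- make_marker_genotypes(gm, pos)
  iv_all <- map_interval(mk_all)
  # dropping a marker can only keep or widen the interval
  mk_fewer <- make_marker_genotypes(gm[, -2], pos[-2])
  iv_fewer <- map_interval(mk_fewer)
  expect_lte(iv_fewer$start, iv_all$start)
  expect_gte(iv_fewer$end, iv_all$end)
  # dropping an individual can only keep or widen it
  mk_ind <- make_marker_genotypes(gm[-2, ], pos)
  iv_ind <- map_interval(mk_ind)
  expect_lte(iv_ind$start, iv_all$start)
  expect_gte(iv_ind$end, iv_all$end)
})

test_that("simulated fine-mapping panels contain the causal locus", {
  g <- genome_spec(tibble::tibble(name = "A03", length = 1e7),
                   recomb_rate = 2.5)
  causal <- causal_locus("A03", 5e6)
  marker_pos <- tibble::tibble(chrom = "A03",
                               pos = seq(3e6, 7e6, length.out = 20))
  loci <- dplyr::distinct(dplyr::bind_rows(
    marker_pos, tibble::tibble(chrom = "A03", pos = 5e6)))
  contained <- vapply(1:50, function(s) {
    pop <- simulate_population(g, cross_design("F2", 400), loci, causal,
                               seed = s)
    pop <- assign_phenotypes(pop, causal)
    mk <- genotype_markers(pop, marker_pos)
    iv <- map_interval(mk)
    iv$start <= 5e6 && iv$end >= 5e6
  }, logical(1))
  expect_gte(mean(contained), 0.98)
})

test_that("codon-level classification follows the standard genetic code", {
  gm <- gene_model("toy", "+", tibble::tibble(start = 1, end = 9),
                   cds = "ATGCAACAG")
  ns <- annotate_snp_effect(gm, 2, 1, "C", "T")   # CAA -> TAA
  expect_identical(ns$class, "nonsense")
  expect_identical(ns$alt_residue, "*")
  expect_identical(ns$residues_lost, 2L)          # residues 2,3 of 3 lost
  syn <- annotate_snp_effect(gm, 3, 3, "G", "A")  # CAG -> CAA, Gln -> Gln
  expect_identical(syn$class, "synonymous")
  expect_true(is.na(syn$residues_lost))
  mis <- annotate_snp_effect(gm, 2, 2, "A", "G")  # CAA -> CGA, Gln -> Arg
  expect_identical(mis$class, "missense")
  expect_error(annotate_snp_effect(gm, 2, 1, "G", "T"), "mismatch")
  expect_error(annotate_snp_effect(gm, 9, 1, "C", "T"), "beyond")
})

test_that("a premature stop late in a 100-codon CDS truncates 11 residues", {
  # mirror of the mapped mutation's scale: C -> T creating a stop at codon
  # 90 of a 100-codon protein removes residues 90..100
  cds <- random_cds(100, seed = 5)
  codon90 <- substr(cds, 268, 270)
  # force codon 90 to CAA so the C -> T transition gives TAA
  substr(cds, 268, 270) <- "CAA"
  gm <- gene_model("CHLH-like", "+",
                   tibble::tibble(start = 1, end = 300), cds = cds)
  eff <- annotate_snp_effect(gm, 90, 1, "C", "T")
  expect_identical(eff$class, "nonsense")
  expect_identical(eff$residues_lost, 11L)
  # independent check: full-CDS translation oracle
  alt_cds <- cds
  substr(alt_cds, 268, 268) <- "T"
  ref_aa <- translate_oracle(cds)
  alt_aa <- translate_oracle(alt_cds)
  stop_at <- as.integer(regexpr("*", alt_aa, fixed = TRUE))
  expect_identical(nchar(ref_aa) - (stop_at - 1L), 11L)
})

test_that("effect classes agree with full-CDS translation on 1000 mutations", {
  cds <- random_cds(120, seed = 8)
  gm <- gene_model("rand", "+", tibble::tibble(start = 1, end = 360),
                   cds = cds)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(17, {
    for (i in 1:1000) {
      p <- sample.int(360, 1)
      ref <- substr(cds, p, p)
      alt <- sample(setdiff(bases, ref), 1)
      eff <- annotate_snp_effect(gm, (p - 1) %/% 3 + 1, (p - 1) %% 3 + 1,
                                 ref, alt)
      alt_cds <- cds
      substr(alt_cds, p, p) <- alt
      ref_aa <- translate_oracle(cds)
      alt_aa <- translate_oracle(alt_cds)
      ci <- (p - 1) %/% 3 + 1
      expected <- if (substr(alt_aa, ci, ci) == "*") "nonsense"
        else if (alt_aa == ref_aa) "synonymous" else "missense"
      expect_identical(eff$class, expected)
      if (expected == "nonsense") {
        expect_identical(eff$residues_lost,
                         as.integer(nchar(ref_aa) - (ci - 1)))
      }
    }
  })
})

test_that("genomic positions project through exons on both strands", {
  # two exons 101-106 and 201-206; CDS = 12 bases
  exons <- tibble::tibble(start = c(101, 201), end = c(106, 206))
  gm_plus <- gene_model("p", "+", exons, cds = "ATGGCCCAATGA")
  expect_identical(project_to_cds(gm_plus, 101), 1L)
  expect_identical(project_to_cds(gm_plus, 106), 6L)
  expect_identical(project_to_cds(gm_plus, 201), 7L)
  expect_true(is.na(project_to_cds(gm_plus, 150)))   # intron
  # minus strand: genomic 206 is CDS base 1
  gm_minus <- gene_model("m", "-", exons, cds = "ATGGCCCAATGA")
  expect_identical(project_to_cds(gm_minus, 206), 1L)
  expect_identical(project_to_cds(gm_minus, 101), 12L)
  # intronic variant annotates as non-coding rather than erroring
  eff <- annotate_variant(gm_plus, 150, "A", "G")
  expect_identical(eff$class, "non-coding")
  # minus-strand annotation complements the alleles: genomic C->T at 204 is
  # CDS position 3 (G -> A on the coding strand), ATG -> ATA missense
  eff2 <- annotate_variant(gm_minus, 204, "C", "T")
  expect_identical(eff2$class, "missense")
})

test_that("gene_model rejects inconsistent structures", {
  expect_error(gene_model("x", "+", tibble::tibble(start = 1, end = 7),
                          cds = "ATGCCCA"), "divisible")
  expect_error(gene_model("x", "+", tibble::tibble(start = 1, end = 6),
                          cds = "ATGCCCGGG"), "does not match")
  expect_error(gene_model("x", "+", tibble::tibble(start = 1, end = 9),
                          cds = "ATGTAACCC"), "internal stop")
  expect_error(gene_model("x", "+",
                          tibble::tibble(start = c(1, 4), end = c(6, 9)),
                          cds = "ATGCCCGGG"), "overlap")
})

test_that("the C-to-T transition that creates CCTAGG is a Bln I gain", {
  res <- caps_scan("AAACCCAGGAAA", 6, "C", "T")
  expect_identical(res$classification, "gain")
  expect_true(res$palindromic)
  expect_identical(res$alt_sites, 4L)
  expect_identical(res$ref_sites, integer(0))
  # symmetry: swapping ref/alt turns the gain into a loss
  rev <- caps_scan("AAACCTAGGAAA", 6, "T", "C")
  expect_identical(rev$classification, "loss")
  # a substitution far from any site is "none"
  none <- caps_scan("AAACCTAGGAAATTT", 12, "A", "G")
  expect_identical(none$classification, "none")
  expect_error(caps_scan("AAA", 2, "T", "C"), "mismatch")
  expect_error(caps_scan("AAA", 9, "A", "G"), "beyond")
})

test_that("non-palindromic recognitions scan both orientations", {
  # recognition GGTCTC (BsaI-like) is not palindromic; its reverse
  # complement GAGACC must also be found
  expect_false(is_palindromic("GGTCTC"))
  expect_true(is_palindromic("CCTAGG"))
  expect_true(is_palindromic("GAATTC"))
  res <- caps_scan("TTGAGACCTT", 3, "G", "G" ,
                   enzyme = list(name = "BsaI", recognition = "GGTCTC"))
  expect_identical(res$ref_sites, 3L)
})

test_that("caps_scan matches the naive sliding-scan oracle", {
  withr::with_seed(23, {
    for (i in 1:50) {
      seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                   collapse = "")
      for (recog in c("CCTAGG", "CTNAG", "GANTC", "AA")) {
        pos <- sample.int(80, 1)
        ref <- substr(seq, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        res <- caps_scan(seq, pos, ref, alt,
                         enzyme = list(name = "e", recognition = recog))
        alt_seq <- seq
        substr(alt_seq, pos, pos) <- alt
        oracle_ref <- naive_site_scan(recog, seq)
        oracle_alt <- naive_site_scan(recog, alt_seq)
        if (!is_palindromic(recog)) {
          rc <- paste(rev(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                                 strsplit(recog, "")[[1]])), collapse = "")
          oracle_ref <- sort(unique(c(oracle_ref, naive_site_scan(rc, seq))))
          oracle_alt <- sort(unique(c(oracle_alt,
                                      naive_site_scan(rc, alt_seq))))
        }
        expect_identical(res$ref_sites, oracle_ref)
        expect_identical(res$alt_sites, oracle_alt)
      }
    }
  })
})

test_that("overlapping occurrences of a repetitive recognition all count", {
  res <- caps_scan("AAAAA", 3, "A", "A",
                   enzyme = list(name = "e", recognition = "AA"))
  expect_identical(res$ref_sites, 1:4)
})

test_that("the bundled enzyme table carries Bln I / AvrII", {
  enz <- load_enzymes()
  expect_true(all(c("name", "recognition") %in% names(enz)))
  expect_identical(enz$recognition[enz$name == "BlnI"], "CCTAGG")
  expect_identical(enz$recognition[enz$name == "AvrII"], "CCTAGG")
})
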