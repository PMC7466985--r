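# Shared fixture builders. Everything is generated in code; no stored data.

tiny_genome <- function(n_chrom = 2, len = 1e6, rate = 2.5) {
  genome_spec(tibble::tibble(name = paste0("chr", seq_len(n_chrom)),
                             length = rep(len, n_chrom)),
              recomb_rate = rate)
}

# a hand-written variant table with easily checked depths
toy_variant_table <- function() {
  variant_table(tibble::tibble(
    chrom = c("A03", "A03", "A01"),
    pos = c(100L, 200L, 50L),
    ref = c("C", "G", "A"),
    alt = c("T", "A", "ACT"),
    p1_ref = c(20L, 18L, 25L), p1_alt = c(0L, 1L, 0L),
    p2_ref = c(0L, 2L, 1L),    p2_alt = c(22L, 19L, 24L),
    g_ref = c(14L, 10L, 12L),  g_alt = c(6L, 10L, 8L),
    y_ref = c(1L, 0L, 2L),     y_alt = c(19L, 21L, 18L)
  ))
}

# content comparison of variant tables irrespective of bookkeeping attributes
vt_df <- function(x) {
  attr(x, "skipped") <- NULL
  attr(x, "dropped") <- NULL
  as.data.frame(x)
}

# small complete experiment for integration-style tests
quick_experiment <- function(seed = 1, n = 240, depth = 25) {
  simulate_bsa_experiment(
    genome = genome_spec(),
    design = cross_design("F2", n),
    causal = causal_locus("A03", 2.5e6),
    bulks = bulk_spec(30),
    sequencing = seq_spec(mean_depth = depth),
    seed = seed
  )
}

# random CDS of n_codons sense codons (no stop anywhere), ATG start
random_cds <- function(n_codons, seed = 1) {
  stops <- c("TAA", "TAG", "TGA")
  withr::with_seed(seed, {
    codons <- character(n_codons)
    codons[1] <- "ATG"
    bases <- c("A", "C", "G", "T")
    for (i in seq(2, n_codons)) {
      repeat {
        cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
        if (!cd %in% stops) break
      }
      codons[i] <- cd
    }
    paste(codons, collapse = "")
  })
}

# independent full-CDS translation oracle (seqinr, not Biostrings)
translate_oracle <- function(cds) {
  paste(seqinr::translate(seqinr::s2c(cds)), collapse = "")
}

# naive sliding-scan oracle for recognition-site occurrences, with manual
# IUPAC expansion; counts overlapping occurrences on the forward strand
naive_site_scan <- function(recognition, seq) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  k <- nchar(recognition)
  rec <- strsplit(toupper(recognition), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(s) - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1] %in% iupac[[rec[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}
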