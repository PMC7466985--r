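# The variant exchange table: per-site ref/alt allele depths for the two
# parents (P1 = wild-type, P2 = mutant) and the two phenotype-selected pools
# (G = wild-type-like, Y = mutant-like). 1-based VCF coordinates throughout.

VT_COLS <- c("chrom", "pos", "ref", "alt",
             "p1_ref", "p1_alt", "p2_ref", "p2_alt",
             "g_ref", "g_alt", "y_ref", "y_alt")

#' Build a variant table
#'
#' @param x A data frame with columns `chrom`, `pos`, `ref`, `alt` and the
#'   eight per-sample depth columns `p1_ref`, `p1_alt`, `p2_ref`, `p2_alt`,
#'   `g_ref`, `g_alt`, `y_ref`, `y_alt`. Counts must be non-negative,
#'   positions >= 1, alleles non-empty (single-base SNPs and multi-base
#'   indel alleles are both accepted).
#' @return A tibble of class `bsa_variant_table`, sorted by
#'   `(chrom, pos, alt)` with duplicate `(chrom, pos, alt)` records rejected.
#' @export
variant_table <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(VT_COLS, names(x))
  if (length(missing_cols)) {
    abort(paste("variant table is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  x <- x[VT_COLS]
  depth_cols <- VT_COLS[-(1:4)]
  if (any(vapply(x[depth_cols], function(v) any(v < 0, na.rm = TRUE),
                 logical(1)))) {
    abort("allele depths must be non-negative")
  }
  if (any(x$pos < 1)) abort("positions must be >= 1 (1-based coordinates)")
  if (any(!nzchar(x$ref)) || any(!nzchar(x$alt))) {
    abort("alleles must be non-empty strings")
  }
  x <- arrange(x, .data$chrom, .data$pos, .data$alt)
  if (anyDuplicated(x[c("chrom", "pos", "alt")])) {
    abort("duplicate (chrom, pos, alt) records")
  }
  x[depth_cols] <- lapply(x[depth_cols], as.integer)
  x$pos <- as.integer(x$pos)
  class(x) <- c("bsa_variant_table", class(x))
  x
}

#' Read a variant table from VCF or TSV
#'
#' VCF input (uncompressed or bgzipped v4.2) is parsed with \pkg{vcfR};
#' per-sample allele depths come from the `AD` FORMAT field. Records lacking
#' `AD`, with missing values, or with more than one ALT allele are skipped;
#' the number skipped per reason is reported and attached as the
#' `"skipped"` attribute. The TSV dialect is the table's own column layout
#' (header `chrom pos ref alt p1_ref ... y_alt`).
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`; default guessed from the extension.
#' @param samples For VCF input, a named character vector mapping the roles
#'   `p1`, `p2`, `g`, `y` to sample names in the file. Defaults to samples
#'   named `P1`, `P2`, `G_pool`, `Y_pool`.
#' @return A `bsa_variant_table`, sorted.
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv"),
                               samples = c(p1 = "P1", p2 = "P2",
                                           g = "G_pool", y = "Y_pool")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = "c", ref = "c", alt = "c",
                           .default = "i"))
    return(variant_table(x))
  }
  .read_vcf_table(path, samples)
}

.read_vcf_table <- function(path, samples) {
  need <- c("p1", "p2", "g", "y")
  if (!all(need %in% names(samples))) {
    abort("`samples` must name all of p1, p2, g, y")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  have <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(unname(samples[need]), have)
  if (length(missing_samples)) {
    abort(sprintf("sample(s) not present in VCF: %s",
                  paste(missing_samples, collapse = ", ")))
  }

  n <- nrow(fix)
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) ad <- matrix(NA_character_, nrow = n, ncol = length(have),
                                dimnames = list(NULL, have))
  ad <- ad[, unname(samples[need]), drop = FALSE]
  ok_ad <- apply(ad, 1, function(r) all(!is.na(r) & grepl("^\\d+,\\d+$", r)))
  keep <- !multi & ok_ad

  skipped <- c(multiallelic = sum(multi), no_allele_depth = sum(!ok_ad & !multi))
  if (any(skipped > 0)) {
    inform(sprintf("skipped %d record(s): %d multi-allelic, %d without usable AD",
                   sum(!keep), skipped[["multiallelic"]],
                   skipped[["no_allele_depth"]]))
  }

  split_ad <- function(col, part) {
    if (!any(keep)) return(integer(0))
    vapply(strsplit(ad[keep, col], ",", fixed = TRUE),
           function(p) as.integer(p[part]), integer(1))
  }
  x <- tibble(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
    p1_ref = split_ad(samples[["p1"]], 1), p1_alt = split_ad(samples[["p1"]], 2),
    p2_ref = split_ad(samples[["p2"]], 1), p2_alt = split_ad(samples[["p2"]], 2),
    g_ref = split_ad(samples[["g"]], 1), g_alt = split_ad(samples[["g"]], 2),
    y_ref = split_ad(samples[["y"]], 1), y_alt = split_ad(samples[["y"]], 2)
  )
  out <- variant_table(x)
  attr(out, "skipped") <- skipped
  out
}

#' Write a variant table to VCF or TSV
#'
#' The VCF writer emits a minimal v4.2 file: `CHROM POS ID REF ALT QUAL
#' FILTER INFO FORMAT` with `FORMAT=AD` and the four samples `P1 P2 G_pool
#' Y_pool`. `read_variant_table(write_variant_table(t))` reproduces `t`
#' exactly in both formats.
#'
#' @param table A `bsa_variant_table`.
#' @param path Output file.
#' @param format `"vcf"` or `"tsv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(table, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  table <- variant_table(table)
  if (format == "tsv") {
    readr::write_tsv(as_tibble(table)[VT_COLS], path)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamapr",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", "G_pool", "Y_pool"), collapse = "\t")
  )
  ad <- function(r, a) paste0(table[[r]], ",", table[[a]])
  body <- if (nrow(table) == 0) character(0) else paste(
    table$chrom, table$pos, ".", table$ref, table$alt, ".", "PASS", ".", "AD",
    ad("p1_ref", "p1_alt"), ad("p2_ref", "p2_alt"),
    ad("g_ref", "g_alt"), ad("y_ref", "y_alt"),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Polarize alleles to the mutant parent
#'
#' Retains only sites where the two parents are opposite homozygotes (each
#' parent's minor-allele read fraction at most `hom_threshold`) and flips
#' ref/alt labels -- swapping every sample's counts -- where needed so that
#' the alt allele is always the mutant parent's (P2) allele. After
#' polarization the SNP-index of a pool is directly the mutant-allele read
#' fraction. Idempotent.
#'
#' @param table A `bsa_variant_table`.
#' @param hom_threshold Maximum minor-allele read fraction for a parent to
#'   be called homozygous (default 0.1).
#' @param snps_only If `TRUE`, drop sites whose alleles are not both single
#'   nucleotides (indel alleles are otherwise carried through unchanged).
#' @return A polarized `bsa_variant_table`; the number of sites dropped per
#'   reason is attached as attribute `"dropped"`.
#' @export
polarize <- function(table, hom_threshold = 0.1, snps_only = FALSE) {
  table <- variant_table(table)
  assert_fraction(hom_threshold, "hom_threshold", 0, 0.5)
  n0 <- nrow(table)
  if (snps_only) {
    table <- filter(table, nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  }
  n_indel <- n0 - nrow(table)

  frac <- function(alt, ref) {
    d <- alt + ref
    ifelse(d == 0, NA_real_, alt / d)
  }
  f1 <- frac(table$p1_alt, table$p1_ref)
  f2 <- frac(table$p2_alt, table$p2_ref)
  hom_ref <- function(f) !is.na(f) & f <= hom_threshold
  hom_alt <- function(f) !is.na(f) & f >= 1 - hom_threshold
  keep_as_is <- hom_ref(f1) & hom_alt(f2)   # alt already = P2 allele
  flip <- hom_alt(f1) & hom_ref(f2)         # P2 carries the ref allele
  keep <- keep_as_is | flip
  n_not_opposite <- sum(!keep)

  out <- table[keep, ]
  fl <- flip[keep]
  if (any(fl)) {
    swp <- function(a, b) {
      tmp <- out[[a]][fl]
      out[[a]][fl] <<- out[[b]][fl]
      out[[b]][fl] <<- tmp
    }
    swp("ref", "alt")
    swp("p1_ref", "p1_alt"); swp("p2_ref", "p2_alt")
    swp("g_ref", "g_alt"); swp("y_ref", "y_alt")
  }
  dropped <- c(not_opposite_homozygous = n_not_opposite, indel = n_indel)
  if (sum(dropped) > 0) {
    inform(sprintf(
      "polarize: dropped %d site(s) (%d not opposite-homozygous, %d indel)",
      sum(dropped), n_not_opposite, n_indel))
  }
  out <- variant_table(out)
  attr(out, "dropped") <- dropped
  out
}
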