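# Coding-effect annotation of single-base substitutions: gene models with
# exon structure and CDS, genomic -> CDS projection, and codon-level
# classification (synonymous / missense / nonsense) via the standard genetic
# code.

#' Build a gene model
#'
#' @param gene_id Identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble (`start`, `end`, 1-based inclusive genomic
#'   coordinates) of the coding exons, non-overlapping. They are stored
#'   sorted by `start`; their summed length must equal `nchar(cds)`.
#' @param cds Coding sequence, 5'->3' on the coding strand; length divisible
#'   by 3 and no internal stop codon. A terminal stop codon is optional; the
#'   protein length excludes it.
#' @return An object of class `gene_model` with `protein_length` filled in.
#' @export
#' @examples
#' gene_model("toy", "+", tibble::tibble(start = 101, end = 112),
#'            cds = "ATGGCCCAATGA")
gene_model <- function(gene_id, strand = c("+", "-"), exons, cds) {
  strand <- match.arg(strand)
  exons <- as_tibble(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- arrange(exons, .data$start)
  if (any(exons$end < exons$start)) abort("exon end before start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons overlap")
  }
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  if (sum(exons$end - exons$start + 1) != nchar(cds)) {
    abort("summed exon length does not match CDS length")
  }
  aa <- .translate_cds(cds)
  internal_stop <- regexpr("\\*", substr(aa, 1, nchar(aa) - 1))
  if (internal_stop > 0) {
    abort(sprintf("CDS has an internal stop at codon %d", internal_stop))
  }
  protein_length <- nchar(aa) - (substr(aa, nchar(aa), nchar(aa)) == "*")
  structure(
    list(gene_id = gene_id, strand = strand, exons = exons, cds = cds,
         protein_length = as.integer(protein_length)),
    class = "gene_model"
  )
}

.translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

#' Project a genomic position onto CDS coordinates
#'
#' @param model A [gene_model()].
#' @param genomic_pos 1-based genomic position.
#' @return The 1-based CDS position, or `NA` when the position falls outside
#'   the model's exons (intron/UTR/intergenic).
#' @export
project_to_cds <- function(model, genomic_pos) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  hit <- which(genomic_pos >= ex$start & genomic_pos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] - ex$start[seq_len(hit - 1)] + 1) else 0
  plus_pos <- before + (genomic_pos - ex$start[hit]) + 1L
  if (model$strand == "+") as.integer(plus_pos)
  else as.integer(nchar(model$cds) - plus_pos + 1L)
}

#' Classify a single-base substitution within a codon
#'
#' Translates the reference and substituted codon with the standard genetic
#' code and classifies the change as synonymous, missense, or nonsense. For
#' nonsense changes `residues_lost = protein_length - (codon_index - 1)`:
#' the truncated protein keeps codons `1 .. codon_index - 1`.
#'
#' @param model A [gene_model()].
#' @param codon_index 1-based codon number within the CDS.
#' @param offset Position of the substituted base within the codon (1-3).
#' @param ref_base,alt_base Reference and substituted nucleotides on the
#'   coding strand. `ref_base` must match the CDS (guards coordinate bugs).
#' @return A one-row tibble of class `variant_effect`: `gene_id`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_residue`, `alt_residue`,
#'   `class`, `residues_lost` (NA unless nonsense).
#' @export
#' @examples
#' gm <- gene_model("toy", "+", tibble::tibble(start = 1, end = 9),
#'                  cds = "ATGCAAAAA")
#' annotate_snp_effect(gm, codon_index = 2, offset = 1,
#'                     ref_base = "C", alt_base = "T")  # CAA -> TAA, nonsense
annotate_snp_effect <- function(model, codon_index, offset, ref_base,
                                alt_base) {
  stopifnot(inherits(model, "gene_model"))
  n_codons <- nchar(model$cds) / 3
  assert_count(codon_index, "codon_index")
  if (codon_index > n_codons) {
    abort(sprintf("codon_index %d beyond the %d-codon CDS",
                  codon_index, n_codons))
  }
  if (!offset %in% 1:3) abort("`offset` must be 1, 2 or 3 within the codon")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!ref_base %in% c("A", "C", "G", "T") ||
      !alt_base %in% c("A", "C", "G", "T")) {
    abort("ref/alt bases must be one of A, C, G, T")
  }
  cds_pos <- (codon_index - 1) * 3 + offset
  have <- substr(model$cds, cds_pos, cds_pos)
  if (have != ref_base) {
    abort(sprintf("ref base mismatch at CDS position %d: expected %s, CDS has %s",
                  cds_pos, ref_base, have))
  }
  ref_codon <- substr(model$cds, (codon_index - 1) * 3 + 1, codon_index * 3)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_res <- unname(code[[ref_codon]])
  alt_res <- unname(code[[alt_codon]])
  cls <- if (alt_res == "*" && ref_res != "*") "nonsense"
         else if (alt_res == ref_res) "synonymous"
         else "missense"
  out <- tibble(
    gene_id = model$gene_id, codon_index = as.integer(codon_index),
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_residue = ref_res, alt_residue = alt_res, class = cls,
    residues_lost = if (cls == "nonsense") {
      as.integer(model$protein_length - (codon_index - 1))
    } else NA_integer_
  )
  class(out) <- c("variant_effect", class(out))
  out
}

#' Annotate a genomic substitution against a gene model
#'
#' Projects the genomic position through the exon structure (reverse
#' complementing on the minus strand) and dispatches to
#' [annotate_snp_effect()]. Positions outside the coding exons return class
#' `"non-coding"`.
#'
#' @param model A [gene_model()].
#' @param genomic_pos 1-based genomic position of the substitution.
#' @param ref_base,alt_base Alleles on the forward genomic strand.
#' @return A one-row `variant_effect` tibble.
#' @export
annotate_variant <- function(model, genomic_pos, ref_base, alt_base) {
  cds_pos <- project_to_cds(model, genomic_pos)
  if (is.na(cds_pos)) {
    out <- tibble(gene_id = model$gene_id, codon_index = NA_integer_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  ref_residue = NA_character_, alt_residue = NA_character_,
                  class = "non-coding", residues_lost = NA_integer_)
    class(out) <- c("variant_effect", class(out))
    return(out)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (model$strand == "-") {
    ref_base <- comp[[toupper(ref_base)]]
    alt_base <- comp[[toupper(alt_base)]]
  }
  annotate_snp_effect(model,
                      codon_index = (cds_pos - 1) %/% 3 + 1,
                      offset = (cds_pos - 1) %% 3 + 1,
                      ref_base, alt_base)
}
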