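# CAPS marker detection: does a substitution create (gain) or destroy
# (loss) a restriction-enzyme recognition site in the amplicon? Recognition
# sequences may carry IUPAC ambiguity codes; palindromic recognitions
# (their own reverse complement) need only a single-strand scan, which is
# detected automatically.

#' Load a restriction-enzyme table
#'
#' The package ships a small TSV (`name`, `recognition`) including Bln I /
#' AvrII (CCTAGG); users can point at their own table in the same format.
#'
#' @param path TSV path; default the bundled table.
#' @return A tibble with columns `name`, `recognition`.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "bsamapr")) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Is a recognition sequence its own reverse complement?
#'
#' @param recognition IUPAC nucleotide string.
#' @return `TRUE` for palindromic recognitions such as CCTAGG or GAATTC.
#' @export
is_palindromic <- function(recognition) {
  s <- Biostrings::DNAString(toupper(recognition))
  as.character(Biostrings::reverseComplement(s)) == as.character(s)
}

# all start positions (1-based) of `recognition` in `seq`, honouring IUPAC
# codes in the recognition; overlapping occurrences counted
.match_starts <- function(recognition, seq) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(recognition)),
                                   Biostrings::DNAString(toupper(seq)),
                                   fixed = FALSE)
  Biostrings::start(hits)
}

#' Scan for restriction-site gain or loss at a substitution
#'
#' Applies the substitution to the reference amplicon and finds every
#' occurrence of the enzyme's recognition sequence in both alleles
#' (including the reverse-complement orientation when the recognition is
#' not palindromic). The variant is classified by the occurrences that
#' overlap the substituted base: a `gain` CAPS marker when the alt allele
#' has such an occurrence that the ref allele lacks, `loss` for the
#' converse, `none` otherwise.
#'
#' @param ref_seq Reference amplicon sequence.
#' @param position 1-based position of the substitution within `ref_seq`.
#' @param ref_base,alt_base The substituted alleles; `ref_base` must match
#'   `ref_seq` at `position`.
#' @param enzyme A list or one-row data frame with `name` and `recognition`
#'   (default Bln I, CCTAGG).
#' @return An object of class `caps_result`: a list with `enzyme`,
#'   `recognition`, `palindromic`, `ref_sites`, `alt_sites` (all start
#'   positions), `ref_sites_at_variant`, `alt_sites_at_variant`, and
#'   `classification`.
#' @export
#' @examples
#' caps_scan("AAACCCAGGAAA", 6, "C", "T")  # CCCAGG -> CCTAGG: Bln I gain
caps_scan <- function(ref_seq, position, ref_base, alt_base,
                      enzyme = list(name = "BlnI", recognition = "CCTAGG")) {
  ref_seq <- toupper(ref_seq)
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  assert_count(position, "position")
  if (position > nchar(ref_seq)) abort("variant position beyond the sequence")
  have <- substr(ref_seq, position, position)
  if (have != ref_base) {
    abort(sprintf("ref base mismatch at %d: expected %s, sequence has %s",
                  position, ref_base, have))
  }
  alt_seq <- ref_seq
  substr(alt_seq, position, position) <- alt_base
  recog <- toupper(enzyme$recognition)
  pal <- is_palindromic(recog)

  find_all <- function(seq) {
    starts <- .match_starts(recog, seq)
    if (!pal) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(recog)))
      starts <- sort(unique(c(starts, .match_starts(rc, seq))))
    }
    starts
  }
  ref_sites <- find_all(ref_seq)
  alt_sites <- find_all(alt_seq)
  k <- nchar(recog)
  overlaps <- function(starts) {
    starts[position >= starts & position <= starts + k - 1]
  }
  ref_ov <- overlaps(ref_sites)
  alt_ov <- overlaps(alt_sites)
  classification <- if (length(setdiff(alt_ov, ref_ov)) >
                        length(setdiff(ref_ov, alt_ov))) "gain"
    else if (length(setdiff(ref_ov, alt_ov)) >
             length(setdiff(alt_ov, ref_ov))) "loss"
    else "none"

  structure(
    list(enzyme = enzyme$name, recognition = recog, palindromic = pal,
         ref_sites = ref_sites, alt_sites = alt_sites,
         ref_sites_at_variant = ref_ov, alt_sites_at_variant = alt_ov,
         classification = classification),
    class = "caps_result"
  )
}

#' @export
print.caps_result <- function(x, ...) {
  cat(sprintf(
    "<caps_result> %s (%s%s): %s  [ref sites: %d, alt sites: %d]\n",
    x$enzyme, x$recognition, if (x$palindromic) ", palindromic" else "",
    x$classification, length(x$ref_sites), length(x$alt_sites)))
  invisible(x)
}
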