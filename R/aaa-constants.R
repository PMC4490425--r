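# Genetic-code bookkeeping shared by every module. All sequence handling is on
# the DNA alphabet; reports may re-render codons with U for presentation.

DNA_BASES <- c("A", "C", "G", "T")

#' The 64 codons in fixed lexicographic (DNA) order
#' @keywords internal
#' @noRd
ALL_CODONS <- sort(names(Biostrings::GENETIC_CODE))

# codon -> one-letter amino acid, "*" for stop (standard genetic code)
CODON_AA <- {
  x <- as.character(Biostrings::GENETIC_CODE)
  names(x) <- names(Biostrings::GENETIC_CODE)
  x[ALL_CODONS]
}

STOP_CODONS <- ALL_CODONS[CODON_AA == "*"]            # TAA TAG TGA
SENSE_CODONS <- ALL_CODONS[CODON_AA != "*"]           # 61

# amino-acid families over sense codons, plus the stop family kept apart
AA_FAMILIES <- split(SENSE_CODONS, CODON_AA[SENSE_CODONS])
FAMILY_SIZE <- vapply(AA_FAMILIES, length, integer(1))

# the 59 codons belonging to degenerate (size >= 2) sense families:
# everything except ATG (Met) and TGG (Trp)
DEGENERATE_CODONS <- sort(unlist(AA_FAMILIES[FAMILY_SIZE >= 2], use.names = FALSE))

#' Translate a vector of codons to one-letter amino acids
#'
#' Standard genetic code; stop codons translate to `"*"`.
#'
#' @param codons character vector of DNA codons (e.g. `"ATG"`).
#' @return character vector of one-letter amino-acid codes.
#' @examples
#' translate_codons(c("ATG", "GAA", "TAA"))
#' @export
translate_codons <- function(codons) {
  aa <- CODON_AA[codons]
  if (anyNA(aa)) stop("unknown codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  unname(aa)
}

#' Render DNA codons in the RNA alphabet
#'
#' @param x character vector of DNA strings.
#' @return the same strings with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", x)

# split one CDS string into its codons
.codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
}

# codons of every gene as a list, names kept
.corpus_codons <- function(corpus) {
  out <- lapply(corpus$cds, .codon_split)
  names(out) <- corpus$id
  out
}
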