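#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper; IUPAC ambiguity codes are
#' complemented by [Biostrings::reverseComplement()] rules.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ATTA")  # "TAAT"
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalize a DNA sequence to the {A,C,G,T,N} alphabet
#'
#' Uppercases and maps every non-ACGT character (including IUPAC
#' ambiguity codes and gaps) to N. N never matches any scanner pattern
#' and breaks homopolymer/ATC runs.
#'
#' @param seq character scalar.
#' @return normalized character scalar.
#' @export
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  gsub("[^ACGT]", "N", s)
}

# interval midpoint under the 0-based half-open convention; even lengths
# round down
interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
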