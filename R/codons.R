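#' Sense codons of the standard genetic code
#'
#' @description The 61 codons (DNA alphabet, alphabetical order) that encode an
#'   amino acid under the standard genetic code. All codon-level tables in this
#'   package are indexed by this set; stop codons are tracked separately under
#'   the pseudo-codon \code{"STOP"}.
#'
#' @return Character vector of 61 codons.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' Stop codons of the standard genetic code
#' @return Character vector of 3 codons (DNA alphabet).
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == "*"])
}

#' Translate codons to one-letter amino acids
#'
#' @param codons character vector of trinucleotides (DNA alphabet, uppercase).
#' @return Character vector of one-letter amino-acid codes; \code{"*"} for stop
#'   codons, \code{NA} for codons containing ambiguity characters.
#' @export
codon_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# Split a CDS string into codons. Assumes nchar divisible by 3 (callers warn).
split_codons <- function(cds_seq) {
  n <- nchar(cds_seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds_seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# DNA/RNA normalisation helpers ------------------------------------------

normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

normalize_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

rna_complement <- function(bases) {
  map <- c(A = "U", C = "G", G = "C", U = "A")
  unname(map[bases])
}
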