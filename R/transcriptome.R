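#' Load a transcriptome from FASTA plus a CDS coordinate table
#'
#' Reads transcript sequences and their coding-region coordinates into the
#' validated \code{transcriptome} container used throughout the package. All
#' coordinates are 0-based, half-open; sequences are uppercased and RNA
#' \code{U} is normalised to \code{T}.
#'
#' @param fasta_path path to a transcript FASTA file.
#' @param cds_table_path path to a tab-separated table with columns
#'   \code{transcript_id}, \code{cds_start}, \code{cds_end} (0-based,
#'   half-open offsets into the transcript sequence).
#' @return A \code{transcriptome}: data frame with columns
#'   \code{transcript_id}, \code{sequence}, \code{cds_start}, \code{cds_end}.
#' @details A CDS whose length is not divisible by 3, does not begin with ATG
#'   or does not end with a stop codon triggers a warning but the record is
#'   kept. Missing ids or non-ACGTN characters are hard errors.
#' @export
load_transcriptome <- function(fasta_path, cds_table_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)  # tolerate RNA input
  cds <- utils::read.delim(cds_table_path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end")
  if (!all(need %in% names(cds))) {
    stop("CDS table must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(cds$transcript_id, names(seqs))
  if (length(missing)) {
    stop("CDS ids absent from FASTA: ", paste(missing, collapse = ", "))
  }
  sequence <- normalize_dna(as.character(seqs[cds$transcript_id]))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("non-ACGTN characters in transcripts: ",
         paste(cds$transcript_id[bad], collapse = ", "))
  }
  new_transcriptome(data.frame(
    transcript_id = cds$transcript_id,
    sequence = sequence,
    cds_start = as.integer(cds$cds_start),
    cds_end = as.integer(cds$cds_end),
    stringsAsFactors = FALSE
  ))
}

new_transcriptome <- function(df) {
  if (anyDuplicated(df$transcript_id)) {
    stop("duplicated transcript ids")
  }
  if (any(df$cds_start < 0L) || any(df$cds_end > nchar(df$sequence)) ||
      any(df$cds_end <= df$cds_start)) {
    stop("CDS coordinates outside transcript bounds")
  }
  len <- df$cds_end - df$cds_start
  if (any(len %% 3L != 0L)) {
    warning("CDS length not divisible by 3 for: ",
            paste(df$transcript_id[len %% 3L != 0L], collapse = ", "))
  }
  cds <- substring(df$sequence, df$cds_start + 1L, df$cds_end)
  if (any(substr(cds, 1L, 3L) != "ATG")) {
    warning("CDS does not begin with ATG for: ",
            paste(df$transcript_id[substr(cds, 1L, 3L) != "ATG"], collapse = ", "))
  }
  last <- substring(cds, pmax(nchar(cds) - 2L, 1L), nchar(cds))
  ok_stop <- last %in% stop_codons() | len %% 3L != 0L
  if (!all(ok_stop)) {
    warning("CDS does not end with a stop codon for: ",
            paste(df$transcript_id[!ok_stop], collapse = ", "))
  }
  class(df) <- c("transcriptome", "data.frame")
  df
}

#' Write a transcriptome to FASTA and CDS table
#'
#' @param transcriptome a \code{transcriptome}.
#' @param fasta_path,cds_table_path output paths.
#' @return Invisibly, the input.
#' @export
write_transcriptome <- function(transcriptome, fasta_path, cds_table_path) {
  seqs <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(seqs) <- transcriptome$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(
    transcriptome[, c("transcript_id", "cds_start", "cds_end")],
    cds_table_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(transcriptome)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome:", nrow(x), "transcripts;",
      "median CDS", stats::median((x$cds_end - x$cds_start) %/% 3L), "codons\n")
  invisible(x)
}

# CDS codon list per transcript (named list of character vectors).
transcript_codons <- function(transcriptome) {
  cds <- substring(transcriptome$sequence, transcriptome$cds_start + 1L,
                   transcriptome$cds_end)
  out <- lapply(cds, split_codons)
  names(out) <- transcriptome$transcript_id
  out
}
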