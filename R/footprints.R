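new_footprint_set <- function(df, library) {
  library <- match.arg(library, c("input", "ip"))
  if (nrow(df)) {
    if (any(df$count < 1L)) stop("footprint counts must be >= 1")
    key <- paste(df$transcript_id, df$five_prime_pos, df$length)
    if (anyDuplicated(key)) stop("duplicate footprint species after aggregation")
  }
  df$five_prime_pos <- as.integer(df$five_prime_pos)
  df$length <- as.integer(df$length)
  df$count <- as.integer(df$count)
  class(df) <- c("footprint_set", "data.frame")
  attr(df, "library") <- library
  df
}

#' @export
print.footprint_set <- function(x, ...) {
  cat("footprint_set [", attr(x, "library"), "]: ", nrow(x), " species, ",
      sum(x$count), " footprints\n", sep = "")
  invisible(x)
}

#' Read a footprint table
#'
#' Reads a tab-separated footprint table (\code{transcript_id},
#' \code{five_prime_pos} 0-based, \code{length}, \code{count}) into a
#' \code{footprint_set}. Duplicate (transcript, position, length) species are
#' aggregated by summing counts.
#'
#' @param path path to the TSV.
#' @param library library label, \code{"input"} or \code{"ip"}.
#' @return A \code{footprint_set}.
#' @export
read_footprints <- function(path, library = c("input", "ip")) {
  library <- match.arg(library)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "five_prime_pos", "length", "count")
  if (!all(need %in% names(df))) {
    stop("footprint table must have columns: ", paste(need, collapse = ", "))
  }
  aggregate_footprints(df[need], library)
}

aggregate_footprints <- function(df, library) {
  if (nrow(df)) {
    key <- paste(df$transcript_id, df$five_prime_pos, df$length, sep = "\r")
    if (anyDuplicated(key)) {
      cnt <- tapply(df$count, key, sum)
      first <- !duplicated(key)
      df <- df[first, ]
      df$count <- as.integer(cnt[paste(df$transcript_id, df$five_prime_pos,
                                       df$length, sep = "\r")])
    }
    df <- df[order(df$transcript_id, df$five_prime_pos, df$length), ]
    rownames(df) <- NULL
  }
  new_footprint_set(df, library)
}

#' Write a footprint table
#' @param footprints a \code{footprint_set}.
#' @param path output TSV path.
#' @return Invisibly, the input.
#' @export
write_footprints <- function(footprints, path) {
  utils::write.table(as.data.frame(footprints)[, c("transcript_id",
                     "five_prime_pos", "length", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(footprints)
}

#' Read footprints from a transcriptome-aligned BAM file
#'
#' Primary, sense-strand alignments only; antisense and secondary records are
#' dropped with a tally. Read length is the aligned query width; the 5'
#' position is converted to the 0-based transcript coordinate.
#'
#' @param path BAM path (index not required).
#' @param library library label.
#' @return A \code{footprint_set} with attribute \code{dropped}
#'   (named counts of excluded records).
#' @export
read_footprints_bam <- function(path, library = c("input", "ip")) {
  library <- match.arg(library)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("rname", "pos", "qwidth", "strand")
  )
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  sense <- b$strand == "+"
  dropped <- c(antisense = sum(!sense))
  df <- data.frame(transcript_id = as.character(b$rname[sense]),
                   five_prime_pos = b$pos[sense] - 1L,
                   length = b$qwidth[sense],
                   count = 1L, stringsAsFactors = FALSE)
  out <- aggregate_footprints(df, library)
  attr(out, "dropped") <- dropped
  out
}

#' Filter footprints by read length
#'
#' Retains only the read lengths with strong triplet periodicity
#' (29, 30, 32 and 35 nt by default); counts are untouched.
#'
#' @param footprints a \code{footprint_set}.
#' @param allowed integer vector of allowed read lengths.
#' @return A \code{footprint_set} with attribute \code{excluded_by_length}
#'   (total count removed).
#' @export
filter_by_length <- function(footprints, allowed = c(29L, 30L, 32L, 35L)) {
  keep <- footprints$length %in% allowed
  out <- footprints[keep, ]
  rownames(out) <- NULL
  class(out) <- class(footprints)
  attr(out, "library") <- attr(footprints, "library")
  attr(out, "excluded_by_length") <- sum(footprints$count[!keep])
  if (!nrow(out)) warning("no footprints left after length filtering")
  out
}

#' P-site offset assignment
#'
#' Maps a footprint 5' end to the transcript coordinate of the first
#' nucleotide of the P-site codon: the 13th nucleotide (1-based) for 29 and
#' 30 nt footprints, the 14th for 32 and 35 nt footprints.
#'
#' @param five_prime_pos 0-based transcript coordinate(s) of the 5' end.
#' @param length read length(s); must be 29, 30, 32 or 35.
#' @return Integer vector of 0-based P-site codon start coordinates.
#' @export
assign_psite <- function(five_prime_pos, length) {
  offsets <- psite_offsets()
  bad <- !(as.character(length) %in% names(offsets))
  if (any(bad)) {
    stop("unsupported read length(s) ", paste(unique(length[bad]), collapse = ", "),
         "; P-site offsets are defined for ", paste(names(offsets), collapse = ", "))
  }
  unname(as.integer(five_prime_pos) + offsets[as.character(length)])
}

#' Annotate footprints with E/P/A-site codons
#'
#' Applies the P-site offset rule, derives the P-site codon index within the
#' CDS, and extracts the E-, P- and A-site codons. Footprints whose P site is
#' outside the CDS or out of frame are flagged (not dropped); an E or A site
#' falling outside the CDS is flagged per site.
#'
#' @param footprints a \code{footprint_set} (lengths must be supported).
#' @param transcriptome a \code{transcriptome} covering all transcript ids.
#' @return An \code{annotated_footprints} data frame: footprint key columns
#'   plus \code{p_start}, \code{frame}, \code{p_site_codon_index},
#'   \code{e_codon}, \code{p_codon}, \code{a_codon} and logical flags
#'   \code{p_in_cds}, \code{in_frame}, \code{e_in_cds}, \code{a_in_cds}.
#'   Attribute \code{qc} tallies footprint counts by exclusion category.
#' @export
annotate_footprints <- function(footprints, transcriptome) {
  miss <- setdiff(unique(footprints$transcript_id), transcriptome$transcript_id)
  if (length(miss)) stop("transcripts absent from transcriptome: ",
                         paste(miss, collapse = ", "))
  idx <- match(footprints$transcript_id, transcriptome$transcript_id)
  cds_start <- transcriptome$cds_start[idx]
  cds_end <- transcriptome$cds_end[idx]
  seqs <- transcriptome$sequence[idx]

  p_start <- assign_psite(footprints$five_prime_pos, footprints$length)
  rel <- p_start - cds_start
  frame <- ((rel %% 3L) + 3L) %% 3L
  in_frame <- frame == 0L
  p_in_cds <- rel >= 0L & (p_start + 3L) <= cds_end
  p_idx <- ifelse(p_in_cds & in_frame, rel %/% 3L, NA_integer_)

  codon_at <- function(start) {
    ok <- start >= cds_start & (start + 3L) <= cds_end
    out <- rep(NA_character_, length(start))
    out[ok] <- substring(seqs[ok], start[ok] + 1L, start[ok] + 3L)
    list(codon = out, in_cds = ok)
  }
  p <- codon_at(p_start)
  e <- codon_at(p_start - 3L)
  a <- codon_at(p_start + 3L)

  out <- data.frame(
    transcript_id = footprints$transcript_id,
    five_prime_pos = footprints$five_prime_pos,
    length = footprints$length,
    count = footprints$count,
    p_start = p_start,
    frame = frame,
    p_site_codon_index = p_idx,
    e_codon = e$codon, p_codon = p$codon, a_codon = a$codon,
    p_in_cds = p_in_cds, in_frame = in_frame,
    e_in_cds = e$in_cds & p_in_cds & in_frame,
    a_in_cds = a$in_cds & p_in_cds & in_frame,
    stringsAsFactors = FALSE
  )
  attr(out, "library") <- attr(footprints, "library")
  attr(out, "qc") <- c(
    total = sum(out$count),
    out_of_cds = sum(out$count[!out$p_in_cds]),
    out_of_frame = sum(out$count[out$p_in_cds & !out$in_frame]),
    usable = sum(out$count[out$p_in_cds & out$in_frame])
  )
  class(out) <- c("annotated_footprints", "data.frame")
  out
}

#' Triplet-periodicity QC
#'
#' For each read length, the fraction of footprint counts whose 5' end falls
#' in CDS frame 0/1/2, plus a meta-profile of counts by 5'-end position
#' relative to the CDS start.
#'
#' @param footprints a \code{footprint_set}.
#' @param transcriptome a \code{transcriptome}.
#' @param window positions relative to CDS start retained in the meta-profile.
#' @return A \code{periodicity_qc} list with elements \code{frames} (one row
#'   per read length with in-CDS counts; lengths with no in-CDS footprints are
#'   absent) and \code{profile}.
#' @export
metacodon_periodicity <- function(footprints, transcriptome,
                                  window = c(-30L, 90L)) {
  idx <- match(footprints$transcript_id, transcriptome$transcript_id)
  rel <- footprints$five_prime_pos - transcriptome$cds_start[idx]
  in_cds <- rel >= 0L & footprints$five_prime_pos <
    transcriptome$cds_end[idx]
  frames <- NULL
  for (L in sort(unique(footprints$length))) {
    sel <- footprints$length == L & in_cds
    if (!any(sel)) next
    tot <- sum(footprints$count[sel])
    fr <- vapply(0:2, function(f)
      sum(footprints$count[sel][rel[sel] %% 3L == f]) / tot, numeric(1))
    frames <- rbind(frames, data.frame(length = L, frame0 = fr[1],
                                       frame1 = fr[2], frame2 = fr[3],
                                       n = tot))
  }
  in_win <- rel >= window[1] & rel <= window[2]
  profile <- if (any(in_win)) {
    stats::aggregate(count ~ length + rel_pos,
                     data.frame(length = footprints$length[in_win],
                                rel_pos = rel[in_win],
                                count = footprints$count[in_win]),
                     FUN = sum)
  } else {
    data.frame(length = integer(0), rel_pos = integer(0), count = integer(0))
  }
  structure(list(frames = frames, profile = profile),
            class = "periodicity_qc")
}

#' @export
print.periodicity_qc <- function(x, ...) {
  cat("triplet periodicity (fraction of 5' ends per CDS frame):\n")
  print(x$frames, row.names = FALSE)
  invisible(x)
}

#' @export
plot.periodicity_qc <- function(x, ...) {
  fr <- as.matrix(x$frames[, c("frame0", "frame1", "frame2")])
  rownames(fr) <- paste0(x$frames$length, " nt")
  graphics::barplot(t(fr), beside = TRUE, ylim = c(0, 1),
                    legend.text = c("frame 0", "frame 1", "frame 2"),
                    ylab = "fraction of footprints", ...)
  invisible(x)
}

#' Count codons at a ribosomal site
#'
#' Count-weighted codon tallies at the E-, P- or A-site over annotated
#' footprints; flagged footprints (P site out of CDS or out of frame, or the
#' queried site outside the CDS) are excluded and tallied, and stop codons
#' are reported separately from the 61 sense codons.
#'
#' @param annotated an \code{annotated_footprints} data frame.
#' @param site one of \code{"E"}, \code{"P"}, \code{"A"}.
#' @return List with \code{counts} (named vector over the 61 sense codons),
#'   \code{stop_count}, and \code{excluded_count}.
#' @export
site_codon_counts <- function(annotated, site = c("P", "E", "A")) {
  site <- match.arg(site)
  codon <- switch(site, E = annotated$e_codon, P = annotated$p_codon,
                  A = annotated$a_codon)
  ok <- annotated$p_in_cds & annotated$in_frame &
    switch(site, E = annotated$e_in_cds, P = TRUE, A = annotated$a_in_cds) &
    !is.na(codon)
  sense <- sense_codons()
  tall <- tapply(annotated$count[ok], factor(codon[ok], levels = c(sense, stop_codons())),
                 sum, default = 0L)
  list(counts = tall[sense],
       stop_count = sum(tall[stop_codons()]),
       excluded_count = sum(annotated$count[!ok]))
}
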