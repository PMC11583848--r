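#' Estimate per-codon A-site dwell times from input footprints
#'
#' Ratio estimator: per-codon occupancy (the count-weighted share of
#' annotated A-site codons in the input library) over a coverage-matched
#' expectation (each transcript's internal-codon composition weighted by that
#' transcript's footprint density, so per-transcript abundance cancels).
#' Start-proximal codons, the stop codon and the two ORF-terminal codons are
#' excluded, mirroring the positions a P-site can legitimately occupy. An
#' external per-codon dwell table can be supplied downstream wherever a
#' \code{dwell_table} is accepted.
#'
#' @param annotated_input \code{annotated_footprints} for the input library.
#' @param transcriptome a \code{transcriptome}.
#' @return A \code{dwell_table} data frame: \code{codon}, \code{occupancy},
#'   \code{expected}, \code{dwell} (occupancy/expected; \code{NA} for codons
#'   never eligible). Occupancy and expectation each sum to 1.
#' @export
estimate_dwell_times <- function(annotated_input, transcriptome) {
  sense <- sense_codons()
  occ_counts <- site_codon_counts(annotated_input, "A")$counts
  if (sum(occ_counts) == 0) stop("no annotated A-site codons in input")
  occupancy <- occ_counts / sum(occ_counts)

  # A-site-eligible codon composition per transcript (indices 3 .. n-2)
  codons <- transcript_codons(transcriptome)
  n_cod <- lengths(codons)
  comp <- matrix(0, nrow = length(codons), ncol = length(sense),
                 dimnames = list(names(codons), sense))
  for (i in seq_along(codons)) {
    if (n_cod[i] < 6L) next
    cc <- codons[[i]][seq(4L, n_cod[i] - 1L)]  # 0-based 3 .. n-2
    tb <- table(cc[cc %in% sense])
    comp[i, names(tb)] <- tb
  }
  ok <- annotated_input$p_in_cds & annotated_input$in_frame
  tx_counts <- tapply(annotated_input$count[ok],
                      annotated_input$transcript_id[ok], sum, default = 0)
  dens <- rep(0, length(codons))
  names(dens) <- names(codons)
  dens[names(tx_counts)] <- tx_counts
  n_eligible <- pmax(n_cod - 5L, 0L)
  w <- ifelse(n_eligible > 0, dens / n_eligible, 0)
  expected_counts <- colSums(comp * w)
  expected <- expected_counts / sum(expected_counts)

  out <- data.frame(codon = sense,
                    occupancy = unname(occupancy[sense]),
                    expected = unname(expected[sense]),
                    dwell = ifelse(expected[sense] > 0,
                                   unname(occupancy[sense] / expected[sense]),
                                   NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' @export
print.dwell_table <- function(x, n = 10, ...) {
  cat("A-site dwell times; top", n, "by dwell:\n")
  ord <- order(-x$dwell)
  print(as.data.frame(x)[ord[seq_len(min(n, nrow(x)))], ], row.names = FALSE)
  invisible(x)
}

#' P-site-conditioned correlation of A-site enrichment with dwell time
#'
#' Partitions footprints by P-site codon class before recomputing the A-site
#' enrichment table on each partition, then correlates per-codon log2 A-site
#' enrichment with log2 dwell time (Pearson). A codon-label permutation null
#' provides a 95\% band for the correlation under no dwell dependence.
#'
#' @param test a \code{footprint_test}.
#' @param annotated_ip,annotated_input \code{annotated_footprints}.
#' @param dwell_table a \code{dwell_table} (estimated or external, columns
#'   \code{codon} and \code{dwell}).
#' @param p_site_filter \code{"all"}, \code{"arg"} (P-site codon is CGG, CGA
#'   or AGG), \code{"complement"}, or a character vector of P-site codons.
#' @param numerator passed to \code{\link{site_codon_enrichment}}; the
#'   whole-IP-library numerator (default) keeps the partition statistic
#'   defined even where FDR selection leaves no enriched footprints.
#' @param n_perm permutations for the null band.
#' @param perm_seed seed for the permutation null.
#' @return List: \code{r}, \code{p}, \code{n}, \code{null_lower},
#'   \code{null_upper} (2.5/97.5 permutation percentiles), \code{filter}.
#' @export
conditional_enrichment_dwell_correlation <- function(test, annotated_ip,
                                                     annotated_input,
                                                     dwell_table,
                                                     p_site_filter = "all",
                                                     numerator = c("ip", "enriched"),
                                                     n_perm = 1000L,
                                                     perm_seed = 1L) {
  numerator <- match.arg(numerator)
  arg_set <- c("CGG", "CGA", "AGG")
  sel_codons <- if (identical(p_site_filter, "all")) NULL
    else if (identical(p_site_filter, "arg")) arg_set
    else if (identical(p_site_filter, "complement")) setdiff(sense_codons(), arg_set)
    else p_site_filter
  subset_annot <- function(a) {
    if (is.null(sel_codons)) a
    else a[!is.na(a$p_codon) & a$p_codon %in% sel_codons, ]
  }
  tab <- site_codon_enrichment(test, subset_annot(annotated_ip),
                               subset_annot(annotated_input),
                               site = "A", numerator = numerator)
  dw <- dwell_table$dwell[match(tab$codon, dwell_table$codon)]
  ok <- is.finite(tab$ratio) & tab$ratio > 0 & is.finite(dw) & dw > 0
  if (sum(ok) < 3L) stop("partition too small: fewer than 3 defined codons")
  x <- log2(tab$ratio[ok])
  y <- log2(dw[ok])
  ct <- stats::cor.test(x, y)
  set.seed(perm_seed)
  r_null <- replicate(n_perm, stats::cor(x, sample(y)))
  band <- stats::quantile(r_null, c(0.025, 0.975), names = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       null_lower = band[1], null_upper = band[2],
       filter = if (is.null(sel_codons)) "all" else p_site_filter)
}
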