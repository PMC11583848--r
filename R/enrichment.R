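#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Exact two-sided p for the table \code{rbind(c(a, b), c(c, d))}: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (with the usual
#' \code{1 + 1e-7} relative tolerance for floating-point ties, as in
#' \code{stats::fisher.test}). In the footprint-enrichment setting the row
#' totals are the library totals, so the hypergeometric support has at most
#' \code{a + c + 1} points and the computation stays cheap for deep
#' libraries and many species.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + c          # species total across libraries
  n <- b + d
  k <- a + b          # library-1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

#' Fisher's exact enrichment test over footprint species
#'
#' Tests every footprint species (transcript, 5' position, length) for
#' enrichment in the IP library relative to input: for each species the 2x2
#' table \code{[[ip_count, ip_total - ip_count], [input_count, input_total -
#' input_count]]} gets a two-sided Fisher's exact p-value,
#' Benjamini-Hochberg adjustment is applied across all species, and a species
#' is called enriched when \code{q < alpha} and its IP proportion exceeds its
#' input proportion. The species universe is the union of both libraries
#' (absent species count 0).
#'
#' @param ip,input \code{footprint_set}s for the IP and input libraries.
#' @param alpha FDR threshold (default 0.01).
#' @return A \code{footprint_test} data frame with the table counts, library
#'   totals, \code{p_value}, \code{q_value} and \code{enriched}.
#' @export
test_footprint_enrichment <- function(ip, input, alpha = 0.01) {
  ip_total <- sum(ip$count)
  input_total <- sum(input$count)
  if (ip_total == 0 || input_total == 0) stop("zero library total")
  key_ip <- paste(ip$transcript_id, ip$five_prime_pos, ip$length, sep = "\r")
  key_in <- paste(input$transcript_id, input$five_prime_pos, input$length,
                  sep = "\r")
  keys <- union(key_ip, key_in)
  a <- integer(length(keys))
  b <- integer(length(keys))
  a[match(key_ip, keys)] <- ip$count
  b[match(key_in, keys)] <- input$count

  # p depends only on (ip_count, input_count): compute once per unique pair
  pair <- paste(a, b)
  u <- !duplicated(pair)
  pu <- mapply(function(x, y) fisher_exact_p(x, ip_total - x, y, input_total - y),
               a[u], b[u])
  p <- unname(pu[match(pair, pair[u])])
  q <- stats::p.adjust(p, method = "BH")

  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    transcript_id = vapply(parts, `[[`, character(1), 1L),
    five_prime_pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
    length = as.integer(vapply(parts, `[[`, character(1), 3L)),
    ip_count = a, input_count = b,
    ip_total = ip_total, input_total = input_total,
    p_value = p, q_value = q,
    enriched = q < alpha & a / ip_total > b / input_total,
    stringsAsFactors = FALSE
  )
  class(out) <- c("footprint_test", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.footprint_test <- function(x, ...) {
  cat("footprint enrichment test:", nrow(x), "species;",
      sum(x$enriched), "enriched at FDR <", attr(x, "alpha"), "\n")
  invisible(x)
}

# Percentage-ratio table from numerator/denominator codon count vectors
# (named over sense codons).
pct_ratio_table <- function(num_counts, den_counts) {
  pct_num <- if (sum(num_counts) > 0) 100 * num_counts / sum(num_counts)
             else rep(NA_real_, length(num_counts))
  pct_den <- if (sum(den_counts) > 0) 100 * den_counts / sum(den_counts)
             else rep(NA_real_, length(den_counts))
  ratio <- ifelse(den_counts > 0, pct_num / pct_den, NA_real_)
  list(pct_num = pct_num, pct_den = pct_den, ratio = ratio)
}

# Map enriched flags from a footprint_test onto annotated footprints.
join_enriched <- function(annotated, test) {
  key_a <- paste(annotated$transcript_id, annotated$five_prime_pos,
                 annotated$length, sep = "\r")
  key_t <- paste(test$transcript_id, test$five_prime_pos, test$length,
                 sep = "\r")
  flag <- test$enriched[match(key_a, key_t)]
  flag[is.na(flag)] <- FALSE
  flag
}

#' Per-codon site enrichment table
#'
#' The percentage of enriched footprints bearing each codon at the E-, P- or
#' A-site divided by the percentage of input footprints bearing that codon at
#' the same site. Percentages are count-weighted; codons never observed in
#' the input at the site are reported as undefined (\code{NA}), not infinite.
#'
#' @param test a \code{footprint_test} from
#'   \code{\link{test_footprint_enrichment}}.
#' @param annotated_ip,annotated_input \code{annotated_footprints} for the IP
#'   and input libraries.
#' @param site \code{"E"}, \code{"P"} or \code{"A"}.
#' @param numerator \code{"enriched"} computes the numerator percentage over
#'   the FDR-enriched IP footprints (the selective-profiling statistic);
#'   \code{"ip"} uses the whole IP library, an unbiased variant used for
#'   recovery and calibration checks.
#' @param min_input_count codons with fewer input counts at the site are
#'   flagged \code{low_support} (ratio still reported).
#' @return A \code{site_enrichment} data frame: \code{codon},
#'   \code{n_enriched}, \code{n_input}, \code{pct_enriched},
#'   \code{pct_input}, \code{ratio}, \code{low_support}.
#' @export
site_codon_enrichment <- function(test, annotated_ip, annotated_input,
                                  site = c("P", "E", "A"),
                                  numerator = c("enriched", "ip"),
                                  min_input_count = 50L) {
  site <- match.arg(site)
  numerator <- match.arg(numerator)
  num_annot <- if (numerator == "enriched") {
    sel <- join_enriched(annotated_ip, test)
    if (!any(sel)) warning("no enriched footprints: ratios undefined")
    annotated_ip[sel, ]
  } else {
    annotated_ip
  }
  num <- site_codon_counts(num_annot, site)$counts
  den <- site_codon_counts(annotated_input, site)$counts
  pr <- pct_ratio_table(num, den)
  out <- data.frame(codon = names(num),
                    n_enriched = as.integer(num),
                    n_input = as.integer(den),
                    pct_enriched = unname(pr$pct_num),
                    pct_input = unname(pr$pct_den),
                    ratio = unname(pr$ratio),
                    low_support = as.integer(den) < min_input_count,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_enrichment", "data.frame")
  attr(out, "site") <- site
  attr(out, "numerator") <- numerator
  out
}

#' @export
print.site_enrichment <- function(x, n = 10, ...) {
  cat("codon enrichment at the ", attr(x, "site"), "-site (numerator: ",
      attr(x, "numerator"), "); top ", n, " by ratio:\n", sep = "")
  ord <- order(-x$ratio)
  print(as.data.frame(x)[ord[seq_len(min(n, nrow(x)))], ], row.names = FALSE)
  invisible(x)
}

#' Amino-acid and tripeptide enrichment
#'
#' Applies the percentage-ratio statistic to the amino acids encoded at each
#' ribosomal site and to the (E, P, A) amino-acid triples of the nascent
#' peptide. Footprints with any site outside the CDS or encoding a stop are
#' excluded.
#'
#' @inheritParams site_codon_enrichment
#' @return List with \code{tripeptides} (ranked data frame: \code{tripeptide}
#'   as \code{"E-P-A"}, counts, percentages, \code{ratio}), \code{site_aa}
#'   (list of per-site amino-acid tables), and \code{logo_matrix} (3 x 20
#'   matrix of per-site amino-acid enrichment ratios, rows E/P/A, suitable
#'   for logo rendering).
#' @export
tripeptide_enrichment <- function(test, annotated_ip, annotated_input,
                                  numerator = c("enriched", "ip")) {
  numerator <- match.arg(numerator)
  num_annot <- if (numerator == "enriched") {
    annotated_ip[join_enriched(annotated_ip, test), ]
  } else annotated_ip

  aa_levels <- sort(unique(unname(
    Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])))
  triple_counts <- function(annot) {
    ok <- annot$p_in_cds & annot$in_frame & annot$e_in_cds & annot$a_in_cds
    aa <- cbind(codon_to_aa(annot$e_codon[ok]), codon_to_aa(annot$p_codon[ok]),
                codon_to_aa(annot$a_codon[ok]))
    keep <- !apply(is.na(aa) | aa == "*", 1L, any)
    list(trip = tapply(annot$count[ok][keep],
                       paste(aa[keep, 1], aa[keep, 2], aa[keep, 3], sep = "-"),
                       sum),
         site = lapply(1:3, function(j)
           tapply(annot$count[ok][keep], factor(aa[keep, j], levels = aa_levels),
                  sum, default = 0L)))
  }
  num <- triple_counts(num_annot)
  den <- triple_counts(annotated_input)

  trips <- union(names(num$trip), names(den$trip))
  nt <- stats::setNames(rep(0L, length(trips)), trips)
  dt <- nt
  nt[names(num$trip)] <- num$trip
  dt[names(den$trip)] <- den$trip
  pr <- pct_ratio_table(nt, dt)
  tripeptides <- data.frame(tripeptide = trips,
                            n_enriched = as.integer(nt), n_input = as.integer(dt),
                            pct_enriched = unname(pr$pct_num),
                            pct_input = unname(pr$pct_den),
                            ratio = unname(pr$ratio), stringsAsFactors = FALSE)
  tripeptides <- tripeptides[order(-tripeptides$ratio, -tripeptides$pct_enriched), ]
  rownames(tripeptides) <- NULL

  site_names <- c("E", "P", "A")
  site_aa <- lapply(1:3, function(j) {
    pr <- pct_ratio_table(num$site[[j]], den$site[[j]])
    data.frame(aa = aa_levels, n_enriched = as.integer(num$site[[j]]),
               n_input = as.integer(den$site[[j]]),
               pct_enriched = unname(pr$pct_num),
               pct_input = unname(pr$pct_den),
               ratio = unname(pr$ratio), stringsAsFactors = FALSE)
  })
  names(site_aa) <- site_names
  logo <- t(vapply(site_aa, function(df) stats::setNames(df$ratio, df$aa),
                   numeric(length(aa_levels))))
  list(tripeptides = tripeptides, site_aa = site_aa, logo_matrix = logo)
}

#' Weighted codon score per transcript
#'
#' The score of an mRNA is the sum of the per-codon weights over its ORF,
#' normalised to the total number of ORF codons. With weights set to the
#' P-site enrichment ratios of CGG, CGA and AGG this is the weighted
#' arginine-codon score used to stratify transcripts for stability analysis.
#'
#' @param transcriptome a \code{transcriptome}.
#' @param weights named numeric vector of codon weights (codons not named
#'   weigh 0). Codons containing ambiguity characters contribute 0.
#' @return Data frame with \code{transcript_id}, \code{score},
#'   \code{n_codons}, and one \code{n_<codon>} tally column per weighted
#'   codon.
#' @export
weighted_codon_score <- function(transcriptome, weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be a named codon vector")
  }
  codons <- transcript_codons(transcriptome)
  n_codons <- lengths(codons)
  w_sum <- vapply(codons, function(cc) {
    w <- weights[cc]
    sum(w, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(transcript_id = transcriptome$transcript_id,
                    score = unname(w_sum / n_codons),
                    n_codons = unname(n_codons),
                    stringsAsFactors = FALSE)
  for (cd in names(weights)) {
    out[[paste0("n_", cd)]] <-
      vapply(codons, function(cc) sum(cc == cd), integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Correlate site enrichment with an external per-codon metric
#'
#' Correlates (log2-transformed, by default) per-codon enrichment ratios with
#' an external per-codon metric such as the tRNA adaptation index or the
#' codon stability coefficient.
#'
#' @param site_table a \code{site_enrichment} table.
#' @param metric named numeric vector over codons.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param log2_ratio log2-transform the ratios first (default TRUE; codons
#'   with ratio 0 or undefined are dropped).
#' @return List with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
correlate_codon_metric <- function(site_table, metric,
                                   method = c("pearson", "spearman"),
                                   log2_ratio = TRUE) {
  method <- match.arg(method)
  m <- metric[site_table$codon]
  r <- site_table$ratio
  ok <- is.finite(m) & is.finite(r) & (!log2_ratio | r > 0)
  if (sum(ok) < 3L) stop("fewer than 3 codons with defined ratio and metric")
  x <- if (log2_ratio) log2(r[ok]) else r[ok]
  ct <- stats::cor.test(x, m[ok], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), method = method)
}
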