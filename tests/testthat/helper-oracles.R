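# Independent oracles, built before the implementations they check.

# Brute-force two-sided Fisher p: enumerate every 2x2 table with the margins
# of rbind(c(a, b), c(c, d)), compute each table's probability from binomial
# coefficients, and sum the probabilities not exceeding the observed one
# (same 1 + 1e-7 tie tolerance as the classical test).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k1 <- a + c
  n <- r1 + r2
  lo <- max(0L, k1 - r2)
  hi <- min(k1, r1)
  log_p <- vapply(lo:hi, function(x) {
    lchoose(r1, x) + lchoose(r2, k1 - x) - lchoose(n, k1)
  }, numeric(1))
  p_obs <- exp(log_p[(lo:hi) == a])
  sum(exp(log_p)[exp(log_p) <= p_obs * (1 + 1e-7)])
}

# Exact one-sided Wilcoxon rank-sum p by enumerating all assignments of
# ranks to the stratum. No ties assumed.
oracle_wilcoxon_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  all_sets <- utils::combn(length(x) + length(y), length(x))
  w_all <- apply(all_sets, 2L, function(ix) {
    sum(rank(c(x, y))[ix]) - length(x) * (length(x) + 1) / 2
  })
  if (alternative == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# One shared deep simulation with the graded arginine recruitment weights,
# reused across enrichment/dwell tests to keep the suite fast.
arg_sim_cache <- new.env(parent = emptyenv())
arg_weight_sim <- function() {
  if (!is.null(arg_sim_cache$sim)) return(arg_sim_cache$sim)
  cfg <- simulation_config(seed = 2024,
                           recruitment_weights = c(CGG = 4, CGA = 3, AGG = 2))
  tx <- generate_transcriptome(cfg)
  fin <- simulate_footprints(tx, cfg, "input")
  fip <- simulate_footprints(tx, cfg, "ip")
  ain <- annotate_footprints(fin, tx)
  aip <- annotate_footprints(fip, tx)
  ft <- test_footprint_enrichment(fip, fin)
  arg_sim_cache$sim <- list(cfg = cfg, tx = tx, fin = fin, fip = fip,
                            ain = ain, aip = aip, ft = ft)
  arg_sim_cache$sim
}

# Minimal hand-built annotated-footprint rows for direct formula checks.
make_annot <- function(e, p, a, count = 1L, transcript_id = "t1") {
  n <- max(length(e), length(p), length(a), length(count))
  data.frame(transcript_id = rep_len(transcript_id, n),
             five_prime_pos = seq_len(n), length = 29L,
             count = rep_len(count, n), p_start = seq_len(n) + 12L,
             frame = 0L, p_site_codon_index = 1L,
             e_codon = rep_len(e, n), p_codon = rep_len(p, n),
             a_codon = rep_len(a, n),
             p_in_cds = TRUE, in_frame = TRUE, e_in_cds = TRUE,
             a_in_cds = TRUE, stringsAsFactors = FALSE)
}

# footprint_test stub marking the first n_enriched rows of an annotated set
# as enriched.
make_test_stub <- function(annot, enriched_rows) {
  data.frame(transcript_id = annot$transcript_id,
             five_prime_pos = annot$five_prime_pos,
             length = annot$length,
             ip_count = annot$count, input_count = 0L,
             ip_total = sum(annot$count), input_total = 1L,
             p_value = 0, q_value = 0,
             enriched = seq_len(nrow(annot)) %in% enriched_rows,
             stringsAsFactors = FALSE)
}
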