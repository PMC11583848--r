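test_that("two-sided Fisher p matches the enumeration oracle and fisher.test", {
  expect_equal(fisher_exact_p(1, 9, 1, 9), 1.0)
  set.seed(1)
  for (i in 1:50) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    c <- sample(0:25, 1); d <- sample(0:25, 1)
    expect_equal(fisher_exact_p(a, b, c, d), oracle_fisher_p(a, b, c, d),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_p(a, b, c, d),
                 stats::fisher.test(rbind(c(a, b), c(c, d)))$p.value,
                 tolerance = 1e-9)
  }
  # deep-margin case out of reach of naive enumeration cost
  expect_equal(fisher_exact_p(5, 95, 1, 999),
               stats::fisher.test(rbind(c(5, 95), c(1, 999)))$p.value,
               tolerance = 1e-9)
})

test_that("enrichment calls are directional and BH-consistent", {
  cfg <- simulation_config(seed = 13, depth_input = 3e4, depth_ip = 3e4,
                           recruitment_weights = c(CGG = 6))
  tx <- generate_transcriptome(cfg)
  fin <- simulate_footprints(tx, cfg, "input")
  fip <- simulate_footprints(tx, cfg, "ip")
  ft <- test_footprint_enrichment(fip, fin)
  expect_true(all(ft$q_value >= ft$p_value - 1e-12))
  with_enr <- ft[ft$enriched, ]
  expect_true(all(with_enr$ip_count / with_enr$ip_total >
                    with_enr$input_count / with_enr$input_total))
  # q-values are monotone in p-value order
  ord <- order(ft$p_value)
  expect_true(all(diff(ft$q_value[ord]) >= -1e-12))
  # swapping the libraries empties the intersection of enriched sets
  ft_sw <- test_footprint_enrichment(fin, fip)
  key <- function(x) paste(x$transcript_id, x$five_prime_pos, x$length)
  expect_length(intersect(key(ft[ft$enriched, ]), key(ft_sw[ft_sw$enriched, ])), 0)
  expect_error(test_footprint_enrichment(fip[0, ], fin), "zero library total")
})

test_that("site enrichment reproduces the percentage-ratio formula", {
  # 10 enriched footprints all P-site CGG; 100 input footprints, 10 CGG
  aip <- make_annot(e = "GCT", p = "CGG", a = "AAA", count = rep(1L, 10))
  input_p <- c(rep("CGG", 10), rep("AAA", 45), rep("GGG", 45))
  ain <- make_annot(e = "GCT", p = input_p, a = "AAA",
                    count = rep(1L, 100))
  ain$five_prime_pos <- 100L + seq_len(100)
  ft <- make_test_stub(aip, enriched_rows = 1:10)
  se <- site_codon_enrichment(ft, aip, ain, "P")
  expect_equal(se$ratio[se$codon == "CGG"], 100 / 10)
  # undefined, not infinite, for codons unseen in the input
  expect_true(is.na(se$ratio[se$codon == "TTT"]))
  # identical distributions give ratio 1 everywhere observed
  se_null <- site_codon_enrichment(make_test_stub(ain, 1:100), ain, ain, "P")
  expect_equal(se_null$ratio[!is.na(se_null$ratio)], rep(1, 3))
  # normalization invariant
  sim <- arg_weight_sim()
  se_sim <- site_codon_enrichment(sim$ft, sim$aip, sim$ain, "P")
  expect_equal(sum(se_sim$ratio * se_sim$pct_input, na.rm = TRUE), 100,
               tolerance = 1e-6)
})

test_that("injected recruitment weights are recovered by the P-site table", {
  sim <- arg_weight_sim()
  se <- site_codon_enrichment(sim$ft, sim$aip, sim$ain, "P")
  r <- setNames(se$ratio, se$codon)
  expect_true(r["CGG"] > r["CGA"] & r["CGA"] > r["AGG"] &
                r["AGG"] > max(r[setdiff(names(r), c("CGG", "CGA", "AGG"))]))
  # unbiased whole-library numerator recovers the multiplier scale
  se_ip <- site_codon_enrichment(sim$ft, sim$aip, sim$ain, "P",
                                 numerator = "ip")
  w <- setNames(rep(1, 61), se_ip$codon)
  w[c("CGG", "CGA", "AGG")] <- c(4, 3, 2)
  renorm <- sum(w) / 61  # acceptance renormalisation constant
  expect_equal(se_ip$ratio[se_ip$codon == "CGG"], 4 / renorm, tolerance = 0.1)
})

test_that("tripeptide enrichment follows the same percentage-ratio statistic", {
  # every enriched footprint encodes L-R-D; input uniform over three triples
  aip <- make_annot(e = "CTG", p = "CGG", a = "GAT", count = rep(1L, 6))
  ain <- rbind(make_annot(e = "CTG", p = "CGG", a = "GAT", count = rep(1L, 5)),
               make_annot(e = "GCT", p = "AAA", a = "GGG", count = rep(1L, 5)),
               make_annot(e = "TTT", p = "CCC", a = "GAA", count = rep(1L, 5)))
  ain$five_prime_pos <- seq_len(nrow(ain))
  tp <- tripeptide_enrichment(make_test_stub(aip, 1:6), aip, ain)
  lrd <- tp$tripeptides[tp$tripeptides$tripeptide == "L-R-D", ]
  expect_equal(lrd$ratio, 3.0)
  expect_equal(tp$tripeptides$ratio[tp$tripeptides$tripeptide != "L-R-D"],
               c(0, 0))
  # logo matrix rows are E/P/A over the 20 amino acids
  expect_equal(dim(tp$logo_matrix), c(3L, 20L))
  expect_equal(rownames(tp$logo_matrix), c("E", "P", "A"))
})

test_that("P-site amino-acid ratio is the input-weighted mix of codon ratios", {
  sim <- arg_weight_sim()
  se <- site_codon_enrichment(sim$ft, sim$aip, sim$ain, "P")
  tp <- tripeptide_enrichment(sim$ft, sim$aip, sim$ain)
  aa <- codon_to_aa(se$codon)
  # identity holds exactly when both statistics share the same footprint
  # universe; footprints whose E or A site leaves the CDS or hits a stop are
  # excluded from tripeptide counting, so compare within tolerance
  for (res in c("R", "L", "K")) {
    sel <- aa == res & !is.na(se$ratio)
    mix <- sum(se$ratio[sel] * se$pct_input[sel]) / sum(se$pct_input[sel])
    got <- tp$site_aa$P$ratio[tp$site_aa$P$aa == res]
    expect_equal(got, mix, tolerance = 0.05)
  }
  # with P-site recruitment on arginine codons, top tripeptides centre on R
  top <- tp$tripeptides[tp$tripeptides$n_input > 0, ][1:10, ]
  centre <- vapply(strsplit(top$tripeptide, "-"), `[`, character(1), 2L)
  expect_true(mean(centre == "R") >= 0.9)
})

test_that("weighted codon scores follow the sum-over-ORF definition", {
  tx <- suppressWarnings(ptmd:::new_transcriptome(data.frame(
    transcript_id = c("s1", "s2"),
    sequence = c("ATGCGGCGAAAA", "ATGTTTAAATAG"),
    cds_start = 0L, cds_end = 12L, stringsAsFactors = FALSE)))
  w <- c(CGG = 4, CGA = 3, AGG = 2)
  sc <- weighted_codon_score(tx, w)
  expect_equal(sc$score, c((4 + 3) / 4, 0))
  expect_equal(sc$n_CGG, c(1L, 0L))
  # linearity in the weights
  sc10 <- weighted_codon_score(tx, w * 10)
  expect_equal(sc10$score, sc$score * 10)
})

test_that("metric correlation behaves at its boundaries", {
  sim <- arg_weight_sim()
  se <- site_codon_enrichment(sim$ft, sim$aip, sim$ain, "A", numerator = "ip")
  metric <- setNames(log2(se$ratio), se$codon)
  self <- correlate_codon_metric(se, metric)
  expect_equal(self$r, 1.0, tolerance = 1e-12)
  # an independent metric stays inside the permutation null band
  set.seed(5)
  indep <- setNames(rnorm(61), se$codon)
  got <- correlate_codon_metric(se, indep)
  r_null <- replicate(2000, {
    cor(log2(se$ratio[is.finite(se$ratio) & se$ratio > 0]),
        sample(indep[is.finite(se$ratio) & se$ratio > 0]))
  })
  expect_lt(abs(got$r), quantile(abs(r_null), 0.999))
  # pearson and spearman agree in sign on a monotone relationship
  sp <- correlate_codon_metric(se, metric, method = "spearman")
  expect_gt(sp$r * self$r, 0)
  expect_error(correlate_codon_metric(se[1:2, ], metric), "fewer than 3")
})
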