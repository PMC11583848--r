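write_tiny_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

write_cds_table <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("transcriptome loading slices the CDS and normalises the alphabet", {
  fa <- write_tiny_fasta(list(t1 = "AAATGGCTTAAGG"))
  cds <- write_cds_table(data.frame(transcript_id = "t1", cds_start = 2,
                                    cds_end = 11))
  tx <- load_transcriptome(fa, cds)
  expect_equal(substring(tx$sequence, tx$cds_start + 1, tx$cds_end),
               "ATGGCTTAA")
  # U-containing FASTA gives the identical transcriptome
  fa_u <- write_tiny_fasta(list(t1 = "AAAUGGCUUAAGG"))
  expect_equal(load_transcriptome(fa_u, cds), tx)
  # non-multiple-of-3 CDS warns but is kept
  cds10 <- write_cds_table(data.frame(transcript_id = "t1", cds_start = 2,
                                      cds_end = 12))
  expect_warning(tx10 <- load_transcriptome(fa, cds10), "divisible by 3")
  expect_equal(nrow(tx10), 1L)
  # missing id is a hard error naming the id
  cds_bad <- write_cds_table(data.frame(transcript_id = "t9", cds_start = 0,
                                        cds_end = 9))
  expect_error(load_transcriptome(fa, cds_bad), "t9")
})

test_that("length filtering keeps only the periodic lengths", {
  fp <- data.frame(transcript_id = "t1", five_prime_pos = 1:4,
                   length = c(28L, 29L, 31L, 35L), count = c(10L, 10L, 5L, 2L))
  fp <- ptmd:::new_footprint_set(fp, "input")
  kept <- filter_by_length(fp)
  expect_equal(kept$length, c(29L, 35L))
  expect_equal(kept$count, c(10L, 2L))
  expect_equal(attr(kept, "excluded_by_length"), 15L)
  # allowing every length is the identity
  all_kept <- filter_by_length(fp, allowed = 17:35)
  expect_equal(all_kept$count, fp$count)
  expect_equal(all_kept$length, fp$length)
  expect_equal(attr(all_kept, "excluded_by_length"), 0L)
  expect_warning(empty <- filter_by_length(fp[0, ]), "no footprints")
  expect_equal(nrow(empty), 0L)
})

test_that("P-site offsets follow the 13th/14th-nucleotide rule", {
  expect_equal(assign_psite(100L, 29L), 112L)
  expect_equal(assign_psite(100L, 30L), 112L)
  expect_equal(assign_psite(0L, 32L), 13L)
  expect_equal(assign_psite(0L, 35L), 13L)
  expect_error(assign_psite(0L, 31L), "unsupported read length")
})

test_that("annotation derives codon indices and flags boundary sites", {
  seqs <- paste0(strrep("A", 13), "ATG", "GCT", "CGG", "AAA", "TGA",
                 strrep("A", 15))
  tx <- suppressWarnings(ptmd:::new_transcriptome(data.frame(
    transcript_id = "t1", sequence = seqs, cds_start = 13L, cds_end = 28L,
    stringsAsFactors = FALSE)))
  # length 29, 5' end at CDS start: P codon index 4 (the stop here)
  fp <- ptmd:::new_footprint_set(data.frame(
    transcript_id = "t1", five_prime_pos = c(13L, 0L), length = c(29L, 32L),
    count = c(1L, 1L)), "input")
  annot <- annotate_footprints(fp, tx)
  expect_equal(annot$p_start, c(25L, 13L))
  expect_equal(annot$p_site_codon_index, c(4L, 0L))
  # P at codon 0: E site upstream of the CDS is flagged, A site fine
  expect_false(annot$e_in_cds[2])
  expect_true(annot$a_in_cds[2])
  expect_equal(annot$p_codon, c("TGA", "ATG"))
})

test_that("annotated P-site codons always match the transcript sequence", {
  sim <- arg_weight_sim()
  aip <- sim$aip
  idx <- match(aip$transcript_id, sim$tx$transcript_id)
  direct <- substring(sim$tx$sequence[idx], aip$p_start + 1, aip$p_start + 3)
  expect_identical(direct, aip$p_codon)
})

test_that("annotation conserves counts across exclusion categories", {
  tx <- suppressWarnings(ptmd:::new_transcriptome(data.frame(
    transcript_id = "t1",
    sequence = paste0(strrep("G", 13), "ATGCCTGGTTAA", strrep("C", 20)),
    cds_start = 13L, cds_end = 25L, stringsAsFactors = FALSE)))
  fp <- ptmd:::new_footprint_set(data.frame(
    transcript_id = "t1",
    five_prime_pos = c(1L, 2L, 20L),  # in-frame, out-of-frame, out-of-CDS P
    length = 29L, count = c(2L, 3L, 5L)), "input")
  annot <- annotate_footprints(fp, tx)
  qc <- attr(annot, "qc")
  expect_equal(unname(qc["total"]),
               unname(qc["usable"] + qc["out_of_cds"] + qc["out_of_frame"]))
  expect_equal(unname(qc["total"]), 10)
})

test_that("triplet periodicity reflects frame structure", {
  cfg <- simulation_config(seed = 21, depth_input = 3e4)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg, "input")
  qc <- metacodon_periodicity(fp, tx)
  # offsets put 29/30 nt 5' ends in frame 0 and 32/35 nt ends in frame 2
  expect_true(all(qc$frames$frame0[qc$frames$length %in% c(29, 30)] == 1))
  expect_true(all(qc$frames$frame2[qc$frames$length %in% c(32, 35)] == 1))

  # uniform random placement: each frame near 1/3
  set.seed(4)
  n <- 3000L
  idx <- sample(nrow(tx), n, replace = TRUE)
  pos <- vapply(idx, function(i)
    sample(seq(tx$cds_start[i], tx$cds_end[i] - 29L), 1L), integer(1))
  rnd <- ptmd:::aggregate_footprints(data.frame(
    transcript_id = tx$transcript_id[idx], five_prime_pos = pos,
    length = 29L, count = 1L), "input")
  fr <- metacodon_periodicity(rnd, tx)$frames
  sd3 <- 3 * sqrt((1 / 3) * (2 / 3) / fr$n[1])
  expect_true(all(abs(unlist(fr[, c("frame0", "frame1", "frame2")]) - 1 / 3)
                  < sd3))

  # periodicity decays monotonically with frame jitter
  jitter_score <- vapply(c(0, 0.25, 0.5), function(eps) {
    set.seed(11)
    shift <- sample(c(0L, 1L, 2L), nrow(fp), replace = TRUE,
                    prob = c(1 - eps, eps / 2, eps / 2))
    j <- ptmd:::aggregate_footprints(data.frame(
      transcript_id = fp$transcript_id,
      five_prime_pos = fp$five_prime_pos + shift,
      length = fp$length, count = fp$count), "input")
    max(unlist(metacodon_periodicity(j, tx)$frames[1, c("frame0", "frame1",
                                                        "frame2")]))
  }, numeric(1))
  expect_true(all(diff(jitter_score) < 0))
})

test_that("site codon counts are count-weighted with stops kept apart", {
  annot <- make_annot(e = "GCT", p = "CGG", a = "TAA", count = 3L)
  res <- site_codon_counts(annot, "P")
  expect_equal(unname(res$counts["CGG"]), 3)
  expect_equal(sum(res$counts), 3)
  # the A-site stop is tallied separately, not among the 61 sense codons
  res_a <- site_codon_counts(annot, "A")
  expect_equal(sum(res_a$counts), 0)
  expect_equal(res_a$stop_count, 3)
})

test_that("BAM and TSV inputs yield identical annotated footprints", {
  skip_if_not_installed("Rsamtools")
  cfg <- simulation_config(seed = 31, n_transcripts = 4, depth_input = 500)
  tx <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tx, cfg, "input")

  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", tx$transcript_id,
                      nchar(tx$sequence)))
  rows <- unlist(lapply(seq_len(nrow(fp)), function(i) {
    sprintf("r%d_%d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
            i, seq_len(fp$count[i]), fp$transcript_id[i],
            fp$five_prime_pos[i] + 1L, fp$length[i],
            strrep("A", fp$length[i]))
  }))
  writeLines(c(header, rows), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  from_bam <- read_footprints_bam(bam, "input")
  tsv <- tempfile(fileext = ".tsv")
  write_footprints(fp, tsv)
  from_tsv <- read_footprints(tsv, "input")
  expect_equal(as.data.frame(annotate_footprints(from_bam, tx)),
               as.data.frame(annotate_footprints(from_tsv, tx)))
})
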