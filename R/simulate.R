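#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every knob of the generative model: a transcriptome
#' with uniform per-transcript abundance, ribosome footprints whose placement
#' follows per-codon A-site dwell times and whose immunoprecipitation (IP)
#' acceptance follows per-codon P-site recruitment weights, exponential decay
#' time courses in two genetic conditions, and read lengths drawn from the
#' four periodic length classes.
#'
#' @param seed integer seed; all generators are deterministic given the
#'   configuration (library- and condition-specific streams are derived from
#'   it by fixed offsets).
#' @param n_transcripts number of transcripts.
#' @param cds_length_range integer length-2 vector, minimum and maximum ORF
#'   length in codons (including the start and stop codon); minimum 5 so that
#'   E/P/A sites exist away from the ORF ends.
#' @param codon_frequency named probability vector over the 61 sense codons
#'   used to draw internal ORF codons (default uniform).
#' @param recruitment_weights named positive vector over sense codons: the
#'   multiplicative IP-acceptance weight of the P-site codon (default all 1,
#'   the null model).
#' @param dwell_times named positive vector over sense codons: relative A-site
#'   dwell time, proportional to the chance a ribosome is captured with that
#'   codon in the A-site (default all 1).
#' @param read_length_probs named probability vector over read lengths
#'   29/30/32/35.
#' @param depth_input,depth_ip total footprint counts per library.
#' @param decay_timepoints chase timepoints in hours (default 0,1,2,4,8,12).
#' @param halflife_model list linking codon content to true half-lives:
#'   \code{base_halflife} (h), \code{sdlog} (lognormal spread of control
#'   half-lives), \code{stabilization_factor} (multiplier applied in the
#'   perturbed condition), \code{stabilized_n} (how many top-scoring
#'   transcripts are stabilised; \code{NULL} to use
#'   \code{stabilized_fraction}), \code{stabilized_fraction}, and
#'   \code{score_weights} (named codon weights defining the score used to
#'   pick stabilised transcripts; default CGG=4, CGA=3, AGG=2).
#' @param noise_model list; either \code{list(type = "binomial", n_reads)}
#'   (labeled fractions resampled as binomial proportions) or
#'   \code{list(type = "gaussian", sd)}.
#' @param replicates number of replicates per decay timepoint.
#' @param utr5_range,utr3_range UTR length ranges in nt (5' UTR at least 15 nt
#'   so every supported read length fits upstream of an internal P-site).
#' @param ip_dwell_coupling \code{NULL} (IP acceptance independent of the
#'   A-site), \code{"all"}, or a character vector of P-site codons for which
#'   IP acceptance is additionally proportional to the A-site dwell time.
#' @return A validated \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 16L,
                              cds_length_range = c(100L, 200L),
                              codon_frequency = NULL,
                              recruitment_weights = NULL,
                              dwell_times = NULL,
                              read_length_probs = c(`29` = 0.4, `30` = 0.3,
                                                    `32` = 0.2, `35` = 0.1),
                              depth_input = 2e5,
                              depth_ip = 2e5,
                              decay_timepoints = c(0, 1, 2, 4, 8, 12),
                              halflife_model = list(),
                              noise_model = list(type = "binomial", n_reads = 1000L),
                              replicates = 2L,
                              utr5_range = c(15L, 30L),
                              utr3_range = c(15L, 30L),
                              ip_dwell_coupling = NULL) {
  sense <- sense_codons()
  fill_codon_map <- function(x, default, what) {
    if (is.null(x)) {
      x <- stats::setNames(rep(default, length(sense)), sense)
    } else {
      full <- stats::setNames(rep(default, length(sense)), sense)
      unknown <- setdiff(names(x), sense)
      if (length(unknown)) stop("unknown codons in ", what, ": ",
                                paste(unknown, collapse = ", "))
      full[names(x)] <- x
      x <- full
    }
    x
  }
  codon_frequency <- fill_codon_map(codon_frequency, 1 / length(sense),
                                    "codon_frequency")
  codon_frequency <- codon_frequency / sum(codon_frequency)
  recruitment_weights <- fill_codon_map(recruitment_weights, 1,
                                        "recruitment_weights")
  dwell_times <- fill_codon_map(dwell_times, 1, "dwell_times")

  hm <- utils::modifyList(list(base_halflife = 4, sdlog = 0.35,
                               stabilization_factor = 2,
                               stabilized_n = NULL, stabilized_fraction = 0.1,
                               score_weights = c(CGG = 4, CGA = 3, AGG = 2)),
                          halflife_model)

  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              cds_length_range = as.integer(cds_length_range),
              codon_frequency = codon_frequency,
              recruitment_weights = recruitment_weights,
              dwell_times = dwell_times,
              read_length_probs = read_length_probs,
              depth_input = depth_input, depth_ip = depth_ip,
              decay_timepoints = decay_timepoints, halflife_model = hm,
              noise_model = noise_model, replicates = as.integer(replicates),
              utr5_range = as.integer(utr5_range),
              utr3_range = as.integer(utr3_range),
              ip_dwell_coupling = ip_dwell_coupling)
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  sense <- sense_codons()
  if (abs(sum(cfg$codon_frequency) - 1) > 1e-9) {
    stop("codon_frequency must sum to 1")
  }
  if (!setequal(names(cfg$codon_frequency), sense)) {
    stop("codon_frequency must cover the 61 sense codons")
  }
  if (any(cfg$recruitment_weights <= 0) || any(cfg$dwell_times <= 0)) {
    stop("recruitment_weights and dwell_times must be positive")
  }
  if (abs(sum(cfg$read_length_probs) - 1) > 1e-9) {
    stop("read_length_probs must sum to 1")
  }
  if (!all(names(cfg$read_length_probs) %in% c("29", "30", "32", "35"))) {
    stop("read lengths must be among 29, 30, 32, 35")
  }
  if (cfg$cds_length_range[1] < 5L) {
    stop("minimum CDS length is 5 codons")
  }
  if (cfg$cds_length_range[2] < cfg$cds_length_range[1]) {
    stop("cds_length_range must be nondecreasing")
  }
  hm <- cfg$halflife_model
  if (hm$base_halflife <= 0 || hm$stabilization_factor <= 0) {
    stop("half-life model parameters must be positive")
  }
  if (cfg$utr5_range[1] < 15L) stop("5' UTR must be at least 15 nt")
  if (cfg$utr3_range[1] < 15L) stop("3' UTR must be at least 15 nt")
  class(cfg) <- "simulation_config"
  cfg
}

random_nt <- function(n_each) {
  total <- sum(n_each)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  vapply(split(chars, rep(seq_along(n_each), n_each)),
         paste0, character(1), collapse = "")
}

#' Generate a synthetic transcriptome
#'
#' Each transcript carries a random-sequence 5' UTR, an ORF that begins with
#' ATG, continues with internal codons drawn from the configured codon
#' frequencies and ends with a stop codon, and a random 3' UTR. CDS
#' coordinates are recorded 0-based, half-open.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A \code{transcriptome} with an attribute \code{codon_lengths}
#'   (ORF length in codons per transcript).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  sample_range <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, n,
                                                replace = TRUE) - 1L
  lens <- sample_range(config$cds_length_range)
  utr5 <- sample_range(config$utr5_range)
  utr3 <- sample_range(config$utr3_range)
  internal <- lens - 2L
  body <- sample(names(config$codon_frequency), sum(internal), replace = TRUE,
                 prob = config$codon_frequency)
  body <- vapply(split(body, rep(seq_len(n), internal)),
                 paste0, character(1), collapse = "")
  stops <- sample(stop_codons(), n, replace = TRUE)
  utr5_seq <- random_nt(utr5)
  utr3_seq <- random_nt(utr3)
  sequence <- paste0(utr5_seq, "ATG", body, stops, utr3_seq)
  tx <- new_transcriptome(data.frame(
    transcript_id = sprintf("tx%04d", seq_len(n)),
    sequence = sequence,
    cds_start = utr5,
    cds_end = utr5 + 3L * lens,
    stringsAsFactors = FALSE
  ))
  attr(tx, "codon_lengths") <- lens
  tx
}

# Table of eligible P-site positions: one row per internal P-site codon
# (indices 2 .. n-3, 0-based) with its E/P/A codons and transcript coordinate
# of the P-site codon start. Shared by the footprint simulator and tests.
eligible_positions <- function(transcriptome) {
  codons <- transcript_codons(transcriptome)
  n_cod <- lengths(codons)
  keep <- n_cod >= 6L
  idx_list <- lapply(n_cod[keep] - 3L, function(hi) seq(2L, hi))
  n_pos <- lengths(idx_list)
  tx_row <- rep(which(keep), n_pos)
  p_idx <- unlist(idx_list, use.names = FALSE)
  all_cod <- codons[keep]
  flat <- unlist(all_cod, use.names = FALSE)
  offs <- rep(cumsum(c(0L, n_cod[keep][-length(all_cod)])), n_pos)
  data.frame(
    transcript_id = transcriptome$transcript_id[tx_row],
    p_codon_index = p_idx,
    e_codon = flat[offs + p_idx],
    p_codon = flat[offs + p_idx + 1L],
    a_codon = flat[offs + p_idx + 2L],
    p_start = transcriptome$cds_start[tx_row] + 3L * p_idx,
    stringsAsFactors = FALSE
  )
}

# P-site offset (nt from 5' end to the first nt of the P-site codon, 0-based)
# per supported read length: 13th nt (1-based) for 29/30, 14th for 32/35.
psite_offsets <- function() {
  c(`29` = 12L, `30` = 12L, `32` = 13L, `35` = 13L)
}

#' Simulate a footprint library
#'
#' Generative model: a ribosome position (an internal P-site codon, excluding
#' the first and last two codons of each ORF) is drawn with probability
#' proportional to the A-site codon's dwell time under uniform per-transcript
#' abundance; for the IP library the draw is additionally weighted by the
#' P-site codon's recruitment weight (rejection sampling, renormalised to the
#' requested depth). A read length is then drawn from
#' \code{read_length_probs} and the 5' end placed so the P-site codon starts
#' at the canonical offset for that length.
#'
#' @param transcriptome a \code{transcriptome} (UTRs must accommodate the
#'   read-length offsets; \code{\link{generate_transcriptome}} guarantees this).
#' @param config a \code{\link{simulation_config}}.
#' @param library \code{"input"} or \code{"ip"}.
#' @return A \code{footprint_set}: data frame (\code{transcript_id},
#'   \code{five_prime_pos}, \code{length}, \code{count}) with attributes
#'   \code{library}, \code{psite_tally} and \code{asite_tally} (the
#'   generator's internal per-codon tallies, for cross-checks).
#' @export
simulate_footprints <- function(transcriptome, config,
                                library = c("input", "ip")) {
  stopifnot(inherits(config, "simulation_config"))
  library <- match.arg(library)
  depth <- if (library == "input") config$depth_input else config$depth_ip
  set.seed(config$seed + if (library == "input") 101L else 202L)
  if (depth <= 0) {
    warning("requested depth 0: returning empty footprint set")
    return(new_footprint_set(data.frame(transcript_id = character(0),
                                        five_prime_pos = integer(0),
                                        length = integer(0),
                                        count = integer(0)), library))
  }
  pos <- eligible_positions(transcriptome)
  w <- config$dwell_times[pos$a_codon]
  if (library == "ip") {
    w <- w * config$recruitment_weights[pos$p_codon]
    coupling <- config$ip_dwell_coupling
    if (!is.null(coupling)) {
      hit <- if (identical(coupling, "all")) rep(TRUE, nrow(pos))
             else pos$p_codon %in% coupling
      w[hit] <- w[hit] * config$dwell_times[pos$a_codon[hit]]
    }
  }
  counts <- as.vector(stats::rmultinom(1, size = depth, prob = w))

  # thin each position's count into the four read-length classes
  probs <- config$read_length_probs
  lens <- as.integer(names(probs))
  remaining <- counts
  rem_p <- 1
  pieces <- vector("list", length(lens))
  for (j in seq_along(lens)) {
    cj <- if (j == length(lens)) remaining else
      stats::rbinom(length(remaining), remaining, probs[j] / rem_p)
    keep <- cj > 0L
    if (any(keep)) {
      pieces[[j]] <- data.frame(
        transcript_id = pos$transcript_id[keep],
        five_prime_pos = pos$p_start[keep] - psite_offsets()[as.character(lens[j])],
        length = lens[j],
        count = cj[keep],
        stringsAsFactors = FALSE
      )
    }
    remaining <- remaining - cj
    rem_p <- rem_p - probs[j]
  }
  fp <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  fp <- fp[order(fp$transcript_id, fp$five_prime_pos, fp$length), ]
  rownames(fp) <- NULL
  out <- new_footprint_set(fp, library)
  attr(out, "psite_tally") <- tapply(counts, pos$p_codon, sum, default = 0L)
  attr(out, "asite_tally") <- tapply(counts, pos$a_codon, sum, default = 0L)
  out
}

#' Simulate a decay time course
#'
#' True control half-lives are lognormal around \code{base_halflife}; in the
#' perturbed condition the top-scoring transcripts (weighted codon score under
#' \code{halflife_model$score_weights}) have their half-life multiplied by
#' \code{stabilization_factor}, emulating stabilisation of
#' high-arginine-score transcripts upon loss of the decay factor. The labeled
#' fraction decays as \eqn{y(t) = e^{-kt}}, \eqn{k = \ln 2 / t_{1/2}}, and is
#' observed under the configured noise model, clipped to [0, 1]. A half-life
#' of \code{Inf} is the stable-transcript sentinel (\eqn{y \equiv 1}).
#'
#' @param transcriptome a \code{transcriptome}.
#' @param config a \code{\link{simulation_config}}.
#' @param condition \code{"control"} or \code{"perturbed"}.
#' @return Data frame (\code{transcript_id}, \code{condition},
#'   \code{timepoint_h}, \code{labeled_fraction}, \code{replicate}) with
#'   attribute \code{true_half_life} (named vector).
#' @export
simulate_decay <- function(transcriptome, config,
                           condition = c("control", "perturbed")) {
  stopifnot(inherits(config, "simulation_config"))
  condition <- match.arg(condition)
  hm <- config$halflife_model
  n <- nrow(transcriptome)

  set.seed(config$seed + 303L)  # half-lives shared between conditions
  t_half <- hm$base_halflife * exp(stats::rnorm(n, 0, hm$sdlog))
  names(t_half) <- transcriptome$transcript_id
  if (condition == "perturbed") {
    scores <- weighted_codon_score(transcriptome, hm$score_weights)$score
    n_stab <- if (!is.null(hm$stabilized_n)) min(hm$stabilized_n, n)
              else round(hm$stabilized_fraction * n)
    if (n_stab > 0) {
      top <- order(scores, decreasing = TRUE)[seq_len(n_stab)]
      t_half[top] <- t_half[top] * hm$stabilization_factor
    }
  }
  if (any(t_half <= 0)) stop("nonpositive half-life in model")

  set.seed(config$seed + if (condition == "control") 313L else 414L)
  k <- log(2) / t_half
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      timepoint_h = config$decay_timepoints,
                      transcript_id = names(t_half),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- exp(-k[grid$transcript_id] * grid$timepoint_h)
  nm <- config$noise_model
  obs <- switch(nm$type,
    binomial = stats::rbinom(length(y), nm$n_reads, y) / nm$n_reads,
    gaussian = y + stats::rnorm(length(y), 0, nm$sd),
    none = y,
    stop("unknown noise model type: ", nm$type)
  )
  out <- data.frame(transcript_id = grid$transcript_id,
                    condition = condition,
                    timepoint_h = grid$timepoint_h,
                    labeled_fraction = pmin(pmax(obs, 0), 1),
                    replicate = grid$replicate,
                    stringsAsFactors = FALSE)
  attr(out, "true_half_life") <- t_half
  out
}
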