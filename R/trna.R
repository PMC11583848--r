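#' Generate synthetic tRNA records with prescribed D-arm features
#'
#' Builds cloverleaf tRNA sequences (RNA alphabet) realising requested
#' identities at Sprinzl positions 13, 22 and 46, a D-loop alpha element of
#' the requested length (the nucleotides preceding the conserved GG motif),
#' and a given anticodon. Each record carries a dot-bracket secondary
#' structure so it round-trips through \code{\link{parse_trna}}.
#'
#' @param features data frame with columns \code{id}, \code{pos13},
#'   \code{pos22}, \code{pos46} (single RNA bases), \code{alpha_len}
#'   (>= 1), \code{anticodon} (trinucleotide, RNA alphabet, 5'->3').
#' @return A \code{trna_set} data frame: \code{id}, \code{sequence},
#'   \code{structure}, \code{anticodon}, \code{pos13}, \code{pos22},
#'   \code{pos46}, \code{alpha_len}.
#' @export
generate_trna_set <- function(features) {
  need <- c("id", "pos13", "pos22", "pos46", "alpha_len", "anticodon")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  if (any(features$alpha_len < 1L)) {
    stop("alpha element length must be >= 1 (the GG motif must be preceded by at least one nucleotide)")
  }
  bases <- c("A", "C", "G", "U")
  p13 <- normalize_rna(features$pos13)
  p22 <- normalize_rna(features$pos22)
  p46 <- normalize_rna(features$pos46)
  ac <- normalize_rna(features$anticodon)
  if (!all(c(p13, p22, p46) %in% bases)) stop("positions 13/22/46 must be A, C, G or U")
  if (any(nchar(ac) != 3L) || any(grepl("[^ACGU]", ac))) {
    stop("anticodon must be an ACGU trinucleotide")
  }
  rows <- lapply(seq_len(nrow(features)), function(i) {
    alpha <- strrep("A", features$alpha_len[i])
    acc5 <- "GCGGAUU"; acc3 <- "AAUCCGC"
    dstem5 <- paste0("GCU", p13[i])
    dloop <- paste0(alpha, "GG", "CA")
    dstem3 <- paste0(p22[i], "AGC")
    ac5 <- "CCAGA"; ac3 <- "UCUGG"
    acloop <- paste0("CU", ac[i], "AA")
    var <- paste0("AU", p46[i], "UC")
    t5 <- "GCGGG"; t3 <- "CCCGC"; tloop <- "UUCGAAU"
    seqs <- paste0(acc5, "UA", dstem5, dloop, dstem3, "A",
                   ac5, acloop, ac3, var, t5, tloop, t3, acc3, "ACCA")
    dots <- function(n) strrep(".", n)
    struct <- paste0("(((((((", "..", "((((", dots(nchar(dloop)), "))))", ".",
                     "(((((", dots(7L), ")))))", dots(5L),
                     "(((((", dots(7L), ")))))", ")))))))", "....")
    data.frame(id = features$id[i], sequence = seqs, structure = struct,
               anticodon = ac[i], pos13 = p13[i], pos22 = p22[i],
               pos46 = p46[i], alpha_len = as.integer(features$alpha_len[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trna_set", "data.frame")
  out
}

# Pair table from a dot-bracket string; returns integer vector (0 = unpaired).
dotbracket_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pair <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  pair
}

# Split a pair table into helices: list of (i5 = 5' strand indices,
# i3 = 3' strand indices), ordered by 5' start.
pair_helices <- function(pair) {
  helices <- list()
  cur <- NULL
  for (i in seq_along(pair)) {
    j <- pair[i]
    if (j > i) {
      if (!is.null(cur) && i == cur$last_i + 1L && j == cur$last_j - 1L) {
        cur$i5 <- c(cur$i5, i); cur$i3 <- c(j, cur$i3)
        cur$last_i <- i; cur$last_j <- j
      } else {
        if (!is.null(cur)) helices[[length(helices) + 1L]] <- cur
        cur <- list(i5 = i, i3 = j, last_i = i, last_j = j)
      }
    }
  }
  if (!is.null(cur)) helices[[length(helices) + 1L]] <- cur
  helices
}

#' Parse a tRNA cloverleaf into D-arm features
#'
#' Locates the acceptor, D, anticodon and T stems from a dot-bracket
#' cloverleaf annotation (paired-region order), then extracts the identities
#' at Sprinzl positions 13 (last nucleotide of the D-stem 5' strand), 22 (its
#' pairing partner), and 46 (third nucleotide of the variable region), the
#' D-loop alpha-element length (nucleotides preceding the first GG in the
#' D-loop), and the anticodon (central three nucleotides of the anticodon
#' loop). Modified-base letters should be reduced to parent bases upstream;
#' \code{T} is treated as \code{U}.
#'
#' @param sequence tRNA sequence (RNA or DNA alphabet).
#' @param structure dot-bracket string of the same length.
#' @param id record id.
#' @return One-row \code{trna_set}-style data frame with additional columns
#'   \code{parse_ok}, \code{type_II} (long variable arm) and \code{note}.
#'   Records failing structure parsing return \code{parse_ok = FALSE} with
#'   feature columns \code{NA} rather than erroring.
#' @export
parse_trna <- function(sequence, structure, id = "trna") {
  seqs <- normalize_rna(sequence)
  if (nchar(seqs) != nchar(structure)) stop("sequence/structure length mismatch")
  chars <- strsplit(seqs, "")[[1]]
  fail <- function(note) {
    data.frame(id = id, sequence = seqs, structure = structure,
               anticodon = NA_character_, pos13 = NA_character_,
               pos22 = NA_character_, pos46 = NA_character_,
               alpha_len = NA_integer_, parse_ok = FALSE, type_II = NA,
               note = note, stringsAsFactors = FALSE)
  }
  pair <- tryCatch(dotbracket_pairs(structure), error = function(e) NULL)
  if (is.null(pair)) return(fail("unbalanced structure"))
  helices <- pair_helices(pair)
  if (length(helices) < 4L) return(fail("fewer than 4 helices"))
  note <- character(0)
  type_II <- length(helices) > 4L
  if (type_II) note <- c(note, "extra helix: type-II variable arm assumed")
  dh <- helices[[2L]]
  ach <- helices[[3L]]
  th <- helices[[length(helices)]]

  pos13_i <- dh$i5[length(dh$i5)]
  pos22_i <- pair[pos13_i]
  dloop <- if (pos22_i - pos13_i > 1L)
    paste0(chars[(pos13_i + 1L):(pos22_i - 1L)], collapse = "") else ""
  gg <- gregexpr("GG", dloop, fixed = TRUE)[[1L]]
  if (gg[1L] == -1L) return(fail("no GG motif in D-loop"))
  if (length(gg) > 1L) {
    note <- c(note, "multiple GG dinucleotides in D-loop: first used")
    warning("multiple GG dinucleotides in D-loop of ", id, "; first used")
  }
  alpha_len <- gg[1L] - 1L
  if (alpha_len < 1L) return(fail("GG motif not preceded by any nucleotide"))

  ac_start <- ach$i5[length(ach$i5)] + 1L
  ac_end <- pair[ach$i5[length(ach$i5)]] - 1L
  acloop <- chars[ac_start:ac_end]
  if (length(acloop) != 7L) note <- c(note, "anticodon loop not 7 nt")
  mid <- ac_start + (length(acloop) - 3L) %/% 2L
  anticodon <- paste0(chars[mid:(mid + 2L)], collapse = "")

  var_start <- pair[ach$i5[1L]] + 1L   # after anticodon-stem 3' strand
  var_end <- th$i5[1L] - 1L            # before T-stem 5' strand
  var_len <- var_end - var_start + 1L
  if (var_len > 9L && !type_II) {
    type_II <- TRUE
    note <- c(note, "long variable region: type-II assumed")
  }
  pos46 <- if (var_len >= 3L) chars[var_start + 2L] else NA_character_
  if (var_len < 3L) note <- c(note, "variable region shorter than 3 nt")
  if (type_II) warning("type-II variable arm in ", id, "; parsed with warning")

  data.frame(id = id, sequence = seqs, structure = structure,
             anticodon = anticodon, pos13 = chars[pos13_i],
             pos22 = chars[pos22_i], pos46 = pos46,
             alpha_len = as.integer(alpha_len), parse_ok = TRUE,
             type_II = type_II,
             note = paste(note, collapse = "; "), stringsAsFactors = FALSE)
}

#' Classify tRNAs for P-site tRNA-mediated decay propensity
#'
#' Three-outcome model over D-arm features: a tRNA whose D-loop alpha element
#' is extended (two or more nucleotides before the GG motif) sterically
#' blocks decay-factor accommodation in the E site (\code{"blocking"});
#' otherwise a U13:A22:A46 base triplet stabilises binding
#' (\code{"promoting"}); all remaining tRNAs are \code{"neutral"}. Blocking
#' takes precedence if both features co-occur.
#'
#' @param trna_set a \code{trna_set} data frame (from
#'   \code{\link{generate_trna_set}}, \code{\link{parse_trna}} rows, or
#'   \code{\link{read_trna_table}}).
#' @return The input with added columns \code{has_U13A22A46},
#'   \code{has_alpha_insertion}, \code{trans_hoogsteen_GA} (G13:A22, seen in
#'   type-II tRNAs; classified neutral with this distinguishing flag) and
#'   \code{class} (\code{"promoting"}, \code{"neutral"}, \code{"blocking"},
#'   or \code{NA} for unparsed records).
#' @export
classify_ptmd <- function(trna_set) {
  p13 <- normalize_rna(trna_set$pos13)
  p22 <- normalize_rna(trna_set$pos22)
  p46 <- normalize_rna(trna_set$pos46)
  has_triplet <- p13 == "U" & p22 == "A" & p46 == "A"
  has_alpha <- trna_set$alpha_len >= 2L
  cls <- ifelse(has_alpha, "blocking",
                ifelse(has_triplet, "promoting", "neutral"))
  cls[is.na(trna_set$alpha_len)] <- NA_character_
  trna_set$has_U13A22A46 <- has_triplet
  trna_set$has_alpha_insertion <- has_alpha
  trna_set$trans_hoogsteen_GA <- p13 == "G" & p22 == "A"
  trna_set$class <- cls
  trna_set
}

# Codons (DNA alphabet) decoded by an anticodon under standard Crick wobble
# at position 34: G34 reads C/U, U34 reads A/G, C34 reads G, A34 reads U.
decoded_codons <- function(anticodon) {
  ac <- strsplit(normalize_rna(anticodon), "")[[1]]
  if (length(ac) != 3L) stop("anticodon must be 3 nt")
  first2 <- paste0(rna_complement(ac[3L]), rna_complement(ac[2L]))
  third <- switch(ac[1L],
                  G = c("C", "U"), U = c("A", "G"), C = "G", A = "U",
                  stop("anticodon wobble base must be A, C, G or U"))
  normalize_dna(paste0(first2, third))
}

#' Assign a decay-propensity class to each codon
#'
#' Each sense codon inherits the class of the tRNA(s) that decode it under
#' standard Crick wobble pairing at anticodon position 34. Codons decoded by
#' tRNAs of different classes are flagged ambiguous and resolved by the
#' priority blocking > promoting > neutral.
#'
#' @param trna_set a classified \code{trna_set} (see
#'   \code{\link{classify_ptmd}}); unparsed records are ignored.
#' @param require_complete error if any of the 61 sense codons is not decoded
#'   by at least one tRNA (default TRUE).
#' @return Data frame \code{codon}, \code{class}, \code{ambiguous},
#'   \code{n_trnas}.
#' @export
classify_codons <- function(trna_set, require_complete = TRUE) {
  if (!"class" %in% names(trna_set)) stop("run classify_ptmd() first")
  ok <- !is.na(trna_set$class)
  codon_class <- list()
  for (i in which(ok)) {
    for (cd in decoded_codons(trna_set$anticodon[i])) {
      codon_class[[cd]] <- c(codon_class[[cd]], trna_set$class[i])
    }
  }
  sense <- sense_codons()
  missing <- setdiff(sense, names(codon_class))
  if (length(missing) && require_complete) {
    stop("codons not decoded by any tRNA: ", paste(missing, collapse = ", "))
  }
  priority <- c("blocking", "promoting", "neutral")
  rows <- lapply(sense, function(cd) {
    cls <- codon_class[[cd]]
    if (is.null(cls)) {
      return(data.frame(codon = cd, class = NA_character_, ambiguous = NA,
                        n_trnas = 0L, stringsAsFactors = FALSE))
    }
    u <- unique(cls)
    amb <- length(u) > 1L
    chosen <- priority[priority %in% u][1L]
    if (amb) {
      message("codon ", cd, " decoded by tRNAs of classes ",
              paste(u, collapse = "/"), "; assigned ", chosen)
    }
    data.frame(codon = cd, class = chosen, ambiguous = amb,
               n_trnas = length(cls), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-transcript decay-propensity codon densities
#'
#' Fraction of ORF codons in each tRNA class per transcript. Stop codons and
#' codons without an assigned class count in the denominator only, so the
#' three densities sum to at most 1.
#'
#' @param transcriptome a \code{transcriptome}.
#' @param codon_classes output of \code{\link{classify_codons}}.
#' @return Data frame \code{transcript_id}, \code{n_codons},
#'   \code{promoting_density}, \code{neutral_density},
#'   \code{blocking_density}.
#' @export
transcript_ptmd_profile <- function(transcriptome, codon_classes) {
  cls <- stats::setNames(codon_classes$class, codon_classes$codon)
  codons <- transcript_codons(transcriptome)
  dens <- function(cc, what) sum(cls[cc] == what, na.rm = TRUE) / length(cc)
  data.frame(
    transcript_id = transcriptome$transcript_id,
    n_codons = unname(lengths(codons)),
    promoting_density = vapply(codons, dens, numeric(1), "promoting",
                               USE.NAMES = FALSE),
    neutral_density = vapply(codons, dens, numeric(1), "neutral",
                             USE.NAMES = FALSE),
    blocking_density = vapply(codons, dens, numeric(1), "blocking",
                              USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Read / write tRNA feature tables
#'
#' @param path TSV with columns \code{id}, \code{sequence},
#'   \code{anticodon}, \code{pos13}, \code{pos22}, \code{pos46},
#'   \code{alpha_len} (and optionally \code{structure}).
#' @return A \code{trna_set} data frame.
#' @export
read_trna_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "anticodon", "pos13", "pos22", "pos46",
            "alpha_len")
  if (!all(need %in% names(df))) {
    stop("tRNA table must have columns: ", paste(need, collapse = ", "))
  }
  for (col in c("sequence", "anticodon", "pos13", "pos22", "pos46")) {
    df[[col]] <- normalize_rna(df[[col]])
  }
  bad <- !(df$pos13 %in% c("A", "C", "G", "U"))
  if (any(bad)) stop("invalid pos13 for: ", paste(df$id[bad], collapse = ", "))
  class(df) <- c("trna_set", "data.frame")
  df
}

#' @rdname read_trna_table
#' @param trna_set a \code{trna_set}.
#' @export
write_trna_table <- function(trna_set, path) {
  utils::write.table(as.data.frame(trna_set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(trna_set)
}
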