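#' Fit a first-order decay to a labeled-fraction time course
#'
#' Log-linear least squares for the single-exponential model
#' \eqn{y(t) = e^{-kt}}: values are normalised to the mean of the t = 0
#' observations, points at or below \code{floor} are dropped before taking
#' logs, and \eqn{k} is minus the slope of \code{lm(log(y) ~ t)}. The
#' half-life is \eqn{t_{1/2} = \ln 2 / k}. A nonpositive estimated rate, or
#' too few usable points, flags the fit rather than erroring.
#'
#' @param timepoints numeric vector of times (hours).
#' @param values labeled fractions (or relative abundances) at those times.
#' @param floor values at or below this are excluded from the log fit.
#' @return A \code{halflife_fit} list: \code{k} (/h), \code{t_half} (h),
#'   \code{r_squared}, \code{n_used}, \code{status} (one of \code{"ok"},
#'   \code{"stable"}, \code{"unfit"}).
#' @export
fit_half_life <- function(timepoints, values, floor = 0.01) {
  stopifnot(length(timepoints) == length(values))
  ok0 <- is.finite(values) & is.finite(timepoints)
  timepoints <- timepoints[ok0]
  values <- values[ok0]
  res_unfit <- structure(list(k = NA_real_, t_half = NA_real_,
                              r_squared = NA_real_, n_used = 0L,
                              status = "unfit"), class = "halflife_fit")
  if (any(timepoints == 0)) {
    y0 <- mean(values[timepoints == 0])
    if (!is.finite(y0) || y0 <= floor) return(res_unfit)
    values <- values / y0
  } else {
    warning("no t = 0 observation: values used unnormalised")
  }
  use <- values > floor
  res <- list(k = NA_real_, t_half = NA_real_, r_squared = NA_real_,
              n_used = sum(use), status = "unfit")
  class(res) <- "halflife_fit"
  if (sum(use) < 3L || length(unique(timepoints[use])) < 2L) return(res)
  ly <- log(values[use])
  t <- timepoints[use]
  if (stats::sd(ly) == 0) {
    res$k <- 0
    res$t_half <- Inf
    res$r_squared <- NA_real_
    res$status <- "stable"
    return(res)
  }
  fit <- stats::lm(ly ~ t)
  k <- -unname(stats::coef(fit)[2L])
  res$k <- k
  # summary() warns on noise-free series; a perfect fit is legitimate here
  res$r_squared <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(k) || k <= 0) {
    res$t_half <- Inf
    res$status <- "stable"
  } else {
    res$t_half <- log(2) / k
    res$status <- "ok"
  }
  res
}

#' @export
print.halflife_fit <- function(x, ...) {
  cat(sprintf("half-life fit [%s]: t1/2 = %.3g h (k = %.3g /h, R2 = %.3f, n = %d)\n",
              x$status, x$t_half, x$k, x$r_squared, x$n_used))
  invisible(x)
}

#' Fit half-lives for a table of decay measurements
#'
#' Fits \code{\link{fit_half_life}} per transcript and condition. Replicates
#' are averaged per timepoint before fitting (the default); failed fits are
#' flagged, never dropped.
#'
#' @param measurements data frame with columns \code{transcript_id},
#'   \code{condition}, \code{timepoint_h}, \code{labeled_fraction} and
#'   optionally \code{replicate}.
#' @param floor passed to \code{\link{fit_half_life}}.
#' @param average_replicates average replicates per timepoint before fitting
#'   (otherwise all points enter the fit).
#' @return A \code{halflife_table} data frame: \code{transcript_id},
#'   \code{condition}, \code{k}, \code{t_half}, \code{r_squared},
#'   \code{n_points}, \code{status}.
#' @export
fit_decay_table <- function(measurements, floor = 0.01,
                            average_replicates = TRUE) {
  need <- c("transcript_id", "condition", "timepoint_h", "labeled_fraction")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  grp <- interaction(measurements$transcript_id, measurements$condition,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(measurements, grp), function(d) {
    if (average_replicates) {
      y <- tapply(d$labeled_fraction, d$timepoint_h, mean)
      t <- as.numeric(names(y))
      y <- as.numeric(y)
    } else {
      t <- d$timepoint_h
      y <- d$labeled_fraction
    }
    fit <- fit_half_life(t, y, floor = floor)
    data.frame(transcript_id = d$transcript_id[1L],
               condition = d$condition[1L],
               k = fit$k, t_half = fit$t_half, r_squared = fit$r_squared,
               n_points = fit$n_used, status = fit$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("halflife_table", "data.frame")
  out
}

#' Half-life log2 fold-changes between conditions
#'
#' @param table_control,table_perturbed \code{halflife_table}s (one condition
#'   each). Transcripts not fit successfully (\code{status != "ok"}) in
#'   either condition are excluded and tallied.
#' @return Data frame \code{transcript_id}, \code{t_half_control},
#'   \code{t_half_perturbed}, \code{log2_fc}, with attribute
#'   \code{excluded} (count).
#' @export
half_life_fold_change <- function(table_control, table_perturbed) {
  m <- merge(table_control[, c("transcript_id", "t_half", "status")],
             table_perturbed[, c("transcript_id", "t_half", "status")],
             by = "transcript_id", suffixes = c("_control", "_perturbed"))
  ok <- m$status_control == "ok" & m$status_perturbed == "ok"
  out <- data.frame(transcript_id = m$transcript_id[ok],
                    t_half_control = m$t_half_control[ok],
                    t_half_perturbed = m$t_half_perturbed[ok],
                    log2_fc = log2(m$t_half_perturbed[ok] / m$t_half_control[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- sum(!ok)
  out
}

#' Score-stratified one-sided Wilcoxon CDF comparison
#'
#' Compares half-life fold-changes of a transcript stratum against a
#' background set with a one-sided Wilcoxon rank-sum test, as in
#' cumulative-distribution comparisons of stabilisation between gene sets.
#' Ids present in both sets are removed from the background (the exclusion
#' rule used when a codon-defined set overlaps the high-score set). The test
#' is exact when both groups have at most 12 untied values, otherwise the
#' normal approximation with midranks and continuity correction is used.
#'
#' @param fold_changes named numeric vector (names are transcript ids), e.g.
#'   the \code{log2_fc} column of \code{\link{half_life_fold_change}} named
#'   by transcript.
#' @param stratum_ids,background_ids character vectors of transcript ids.
#' @param alternative \code{"greater"} (stratum shifted up; default) or
#'   \code{"less"}.
#' @return A \code{ptmd_rank_test} list: \code{W}, \code{p},
#'   \code{n_stratum}, \code{n_background}, \code{alternative},
#'   \code{ecdf} (data frame of ECDF coordinates per group).
#' @export
stratified_cdf_test <- function(fold_changes, stratum_ids, background_ids,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(names(fold_changes))) stop("fold_changes must be named by id")
  background_ids <- setdiff(background_ids, stratum_ids)
  x <- fold_changes[intersect(stratum_ids, names(fold_changes))]
  y <- fold_changes[intersect(background_ids, names(fold_changes))]
  if (!length(x)) stop("empty stratum")
  if (!length(y)) stop("empty background")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 12L && length(y) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  ecdf_df <- function(v, group) {
    v <- sort(v)
    data.frame(group = group, value = v,
               cum_fraction = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  }
  out <- list(W = unname(wt$statistic), p = wt$p.value,
              n_stratum = length(x), n_background = length(y),
              alternative = alternative,
              ecdf = rbind(ecdf_df(x, "stratum"), ecdf_df(y, "background")))
  class(out) <- "ptmd_rank_test"
  out
}

#' @export
print.ptmd_rank_test <- function(x, ...) {
  cat(sprintf("one-sided Wilcoxon rank-sum (%s): W = %g, p = %.3g (n = %d vs %d)\n",
              x$alternative, x$W, x$p, x$n_stratum, x$n_background))
  invisible(x)
}

#' @export
plot.ptmd_rank_test <- function(x, xlab = "log2 fold-change of half-life",
                                ylab = "cumulative fraction", ...) {
  e <- x$ecdf
  graphics::plot(NA, xlim = range(e$value), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (g in unique(e$group)) {
    d <- e[e$group == g, ]
    graphics::lines(stats::stepfun(d$value, c(0, d$cum_fraction)),
                    do.points = FALSE,
                    col = if (g == "stratum") "firebrick" else "grey30")
  }
  graphics::legend("bottomright", legend = unique(e$group),
                   col = c("firebrick", "grey30"), lty = 1, bty = "n")
  invisible(x)
}

#' Fit reporter decay time courses
#'
#' Exponential half-life fits for doxycycline-chase reporter measurements
#' (relative abundances, typically at 0, 2, 4 and 6 h), one fit per reporter
#' and condition.
#'
#' @param timecourse data frame with columns \code{reporter},
#'   \code{condition}, \code{timepoint_h}, \code{rel_abundance} and
#'   optionally \code{replicate}.
#' @inheritParams fit_decay_table
#' @return A \code{halflife_table}-style data frame keyed by \code{reporter}
#'   and \code{condition}.
#' @export
fit_reporter_decay <- function(timecourse, floor = 0.01,
                               average_replicates = TRUE) {
  need <- c("reporter", "condition", "timepoint_h", "rel_abundance")
  if (!all(need %in% names(timecourse))) {
    stop("timecourse must have columns: ", paste(need, collapse = ", "))
  }
  m <- data.frame(transcript_id = timecourse$reporter,
                  condition = timecourse$condition,
                  timepoint_h = timecourse$timepoint_h,
                  labeled_fraction = timecourse$rel_abundance,
                  stringsAsFactors = FALSE)
  out <- fit_decay_table(m, floor = floor,
                         average_replicates = average_replicates)
  names(out)[names(out) == "transcript_id"] <- "reporter"
  out
}

#' Read / write decay measurement tables
#' @param path TSV path with columns \code{transcript_id}, \code{condition},
#'   \code{timepoint_h}, \code{labeled_fraction}, \code{replicate}.
#' @return Data frame of measurements.
#' @export
read_decay_measurements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "condition", "timepoint_h", "labeled_fraction")
  if (!all(need %in% names(df))) {
    stop("decay table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_decay_measurements
#' @param measurements data frame of decay measurements.
#' @export
write_decay_measurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(measurements)
}
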