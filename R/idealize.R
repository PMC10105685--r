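# collapse consecutive events of equal level, summing durations
collapse_events <- function(level, duration) {
  if (length(level) == 0) return(list(level = level, duration = duration))
  r <- rle(level)
  g <- rep(seq_along(r$lengths), r$lengths)
  list(level = r$values,
       duration = as.numeric(tapply(duration, g, sum)))
}

make_idealization <- function(level, duration, unitary, baseline,
                              sample_rate, dead_time = 0) {
  ev <- data.frame(level = as.integer(level),
                   start = c(0, cumsum(duration))[seq_along(duration)],
                   duration = duration)
  structure(list(events = ev, unitary = unitary, baseline = baseline,
                 sample_rate = sample_rate, dead_time = dead_time,
                 record_length = sum(duration)),
            class = "ip3r_idealization")
}

#' Half-amplitude threshold idealization of a current trace
#'
#' Classifies each sample into a conductance level k when the deflection
#' from baseline crosses the (k - 1/2) unitary-amplitude thresholds, then
#' merges runs of equal level into contiguous events (the classic
#' half-amplitude threshold-crossing technique; a single threshold per
#' level, no hysteresis - noise chatter is handled by dead-time censoring,
#' see \code{\link{apply_dead_time}}).
#'
#' @param trace \code{current_trace} (or bare numeric vector; then supply
#'   \code{sample_rate}).
#' @param unitary unitary current amplitude, pA (non-zero); its sign sets the
#'   opening polarity.
#' @param baseline closed-level current, pA.
#' @param n_levels maximum number of stacked open levels to resolve.
#' @param dead_time optional censoring dead time, s; if non-NULL,
#'   \code{\link{apply_dead_time}} is applied before returning.
#' @param sample_rate required when \code{trace} is a bare vector.
#' @return object of class \code{ip3r_idealization}: events table
#'   (level/start/duration), unitary amplitude, baseline, record length.
#' @export
idealize_trace <- function(trace, unitary, baseline = 0, n_levels = 1,
                           dead_time = NULL, sample_rate = NULL) {
  if (inherits(trace, "current_trace")) {
    x <- trace$samples
    sample_rate <- trace$sample_rate
  } else {
    x <- as.numeric(trace)
    if (is.null(sample_rate)) stop("sample_rate required for bare vectors", call. = FALSE)
  }
  stopifnot(is.finite(unitary), unitary != 0, n_levels >= 1)
  defl <- (x - baseline) * sign(unitary)
  if (max(defl) < 0.5 * abs(unitary) && max(-defl) > 0.5 * abs(unitary)) {
    warning("trace deflections oppose the sign of `unitary`; ",
            "check polarity (pass unitary with the opposite sign)")
  }
  lev <- pmin(as.integer(n_levels), pmax(0L, as.integer(floor(defl / abs(unitary) + 0.5))))
  r <- rle(lev)
  ideal <- make_idealization(r$values, r$lengths / sample_rate,
                             unitary, baseline, sample_rate)
  if (!is.null(dead_time) && dead_time > 0) {
    ideal <- apply_dead_time(ideal, dead_time)
  }
  ideal
}

#' Censor events briefer than a dead time
#'
#' Repeatedly removes the briefest event shorter than \code{dead_time},
#' reassigning its epoch to the preceding event (or the following one for a
#' leading event) and concatenating flanking events that end up at equal
#' level. Total record length is conserved exactly and the operation is
#' idempotent. This implements the exclusion of events under 300 us from
#' filtered records.
#'
#' @param ideal \code{ip3r_idealization}.
#' @param dead_time minimum retained event duration, s (>= 0).
#' @return censored \code{ip3r_idealization} (with \code{dead_time} recorded).
#' @export
apply_dead_time <- function(ideal, dead_time = 300e-6) {
  stopifnot(inherits(ideal, "ip3r_idealization"), dead_time >= 0)
  lev <- ideal$events$level
  dur <- ideal$events$duration
  if (dead_time > 0) {
    repeat {
      if (length(lev) <= 1) break
      short <- which(dur < dead_time)
      if (length(short) == 0) break
      j <- short[which.min(dur[short])]
      lev[j] <- if (j > 1) lev[j - 1] else lev[j + 1]
      merged <- collapse_events(lev, dur)
      lev <- merged$level
      dur <- merged$duration
    }
  }
  out <- make_idealization(lev, dur, ideal$unitary, ideal$baseline,
                           ideal$sample_rate, dead_time)
  out
}

#' Estimate the number of channels in a record
#'
#' The channel count is taken as the maximal number of simultaneously
#' stacked openings observed (the maximum idealized level). Use
#' \code{\link{amplitude_modes}} on the raw trace to corroborate the count
#' from the peaks of the all-points amplitude histogram.
#'
#' @param ideal \code{ip3r_idealization}.
#' @return integer channel count; 0 with a warning when the record contains
#'   no openings (count indeterminate).
#' @export
estimate_n_channels <- function(ideal) {
  stopifnot(inherits(ideal, "ip3r_idealization"))
  if (nrow(ideal$events) == 0) stop("empty idealization", call. = FALSE)
  m <- max(ideal$events$level)
  if (m == 0) warning("record has no openings; channel count indeterminate")
  as.integer(m)
}

#' Modes of the all-points amplitude histogram
#'
#' Companion diagnostic for channel counting: counts the modes of a
#' kernel-smoothed amplitude density that rise above a fraction of the
#' tallest mode. Well-separated conductance levels produce one mode per
#' occupied level (closed + each open level).
#'
#' @param trace \code{current_trace} or numeric vector of samples (pA).
#' @param unitary unitary amplitude, pA; sets the smoothing bandwidth.
#' @param min_height modes lower than \code{min_height} times the tallest
#'   mode are ignored.
#' @return number of detected modes.
#' @export
amplitude_modes <- function(trace, unitary, min_height = 0.001) {
  x <- if (inherits(trace, "current_trace")) trace$samples else as.numeric(trace)
  d <- stats::density(x, bw = abs(unitary) / 8, n = 1024)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] >= min_height * max(y[peaks]))
}

#' Gating statistics from an idealized record
#'
#' Computes nPo (level-weighted open time over record length), the number of
#' open events, the stacked-opening channel-count estimate, and - for
#' effectively single-channel records (maximum level 1) - the arithmetic
#' mean open and closed times. For multi-channel records MOT/MCT are
#' reported as NA (dwell attribution across stacked channels is not
#' attempted, mirroring the restriction of kinetic analysis to
#' single-channel records). Optionally attaches an exponential-mixture
#' maximum-likelihood dwell fit (\code{\link{fit_dwell_exp}}).
#'
#' @param ideal \code{ip3r_idealization}.
#' @param fit_dwells also fit exponential mixtures to open/closed dwells.
#' @param min_record_s records shorter than this (default 180 s, i.e. 3 min)
#'   trigger a warning, not an error.
#' @return object of class \code{ip3r_channel_stats}: list with \code{npo},
#'   \code{mot}, \code{mct} (s), \code{n_open_events},
#'   \code{n_channels_est}, \code{record_length} and optional
#'   \code{dwell_fit}.
#' @export
channel_stats <- function(ideal, fit_dwells = FALSE, min_record_s = 180) {
  stopifnot(inherits(ideal, "ip3r_idealization"))
  ev <- ideal$events
  if (nrow(ev) == 0) stop("no events: statistics undefined", call. = FALSE)
  record <- sum(ev$duration)
  if (record < min_record_s) {
    warning(sprintf("record (%.1f s) shorter than %.0f s; statistics may be unreliable",
                    record, min_record_s))
  }
  npo <- sum(ev$level * ev$duration) / record
  nch <- max(ev$level)
  open_dur <- ev$duration[ev$level >= 1]
  closed_dur <- ev$duration[ev$level == 0]
  mot <- mct <- NA_real_
  if (nch <= 1) {
    if (length(open_dur)) mot <- mean(open_dur)
    if (length(closed_dur)) mct <- mean(closed_dur) else if (length(open_dur)) {
      warning("record has no closed events; MCT undefined")
    }
  }
  dwell_fit <- NULL
  if (fit_dwells && nch <= 1) {
    dwell_fit <- list(
      open = if (length(open_dur) >= 5) fit_dwell_exp(open_dur) else NULL,
      closed = if (length(closed_dur) >= 5) fit_dwell_exp(closed_dur) else NULL)
  }
  structure(list(npo = npo, mot = mot, mct = mct,
                 n_open_events = sum(ev$level >= 1),
                 n_channels_est = as.integer(nch),
                 record_length = record, dwell_fit = dwell_fit),
            class = "ip3r_channel_stats")
}

#' Exponential-mixture maximum-likelihood dwell-time fit
#'
#' Fits 1- and 2-component exponential mixtures to raw (unbinned) dwell
#' times by EM and selects the 2-component model when the likelihood-ratio
#' test rejects the single exponential at level \code{alpha} (df = 2). The
#' single-component rate is exactly 1/mean(dwells).
#'
#' @param dwells positive dwell times, s.
#' @param alpha likelihood-ratio test level for adding the second component.
#' @param max_iter,tol EM iteration controls.
#' @return list with \code{n_components}, \code{rates} (1/s),
#'   \code{weights}, \code{loglik}, \code{mean} (mixture mean, s) and
#'   \code{lrt_p}.
#' @export
fit_dwell_exp <- function(dwells, alpha = 0.05, max_iter = 500, tol = 1e-8) {
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  n <- length(dwells)
  stopifnot(n >= 2)
  rate1 <- 1 / mean(dwells)
  ll1 <- sum(stats::dexp(dwells, rate1, log = TRUE))

  # 2-component EM, initialized by splitting at the median
  r <- c(1 / mean(dwells[dwells <= stats::median(dwells)]),
         1 / mean(dwells[dwells > stats::median(dwells)]))
  if (!all(is.finite(r)) || r[1] == r[2]) r <- rate1 * c(3, 1 / 3)
  w <- c(0.5, 0.5)
  ll2 <- -Inf
  for (it in seq_len(max_iter)) {
    p1 <- w[1] * stats::dexp(dwells, r[1])
    p2 <- w[2] * stats::dexp(dwells, r[2])
    tot <- p1 + p2
    ll_new <- sum(log(tot))
    g <- p1 / tot
    w <- c(mean(g), 1 - mean(g))
    r <- c(sum(g) / sum(g * dwells), sum(1 - g) / sum((1 - g) * dwells))
    if (!all(is.finite(r)) || any(w < 1e-9)) { ll2 <- ll_new; break }
    if (abs(ll_new - ll2) < tol) { ll2 <- ll_new; break }
    ll2 <- ll_new
  }
  lrt <- max(0, 2 * (ll2 - ll1))
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  if (is.finite(ll2) && p < alpha) {
    ord <- order(r, decreasing = TRUE)
    list(n_components = 2L, rates = r[ord], weights = w[ord],
         loglik = ll2, mean = sum(w / r), lrt_p = p)
  } else {
    list(n_components = 1L, rates = rate1, weights = 1,
         loglik = ll1, mean = 1 / rate1, lrt_p = p)
  }
}

#' Log-binned dwell-time histogram for diagnostics
#'
#' Returns counts on logarithmic bins (default 10 per decade) with the
#' log-transformed dwell density commonly used to visualize exponential
#' components; fitting is always done on raw dwells, not on these counts.
#'
#' @param dwells positive dwell times, s.
#' @param bins_per_decade bins per decade of dwell time.
#' @return data.frame with bin midpoints (s), counts and sqrt-count density.
#' @export
dwell_histogram <- function(dwells, bins_per_decade = 10) {
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  stopifnot(length(dwells) >= 1)
  lo <- floor(log10(min(dwells)) * bins_per_decade)
  hi <- ceiling(log10(max(dwells)) * bins_per_decade)
  edges <- 10^(seq(lo, hi + 1) / bins_per_decade)
  counts <- as.integer(table(cut(dwells, edges, include.lowest = TRUE)))
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  data.frame(t_mid = mids, count = counts, sqrt_density = sqrt(counts))
}

#' Write / read idealized events as TSV
#'
#' Columns: level, start_s, duration_s.
#'
#' @param ideal \code{ip3r_idealization}.
#' @param path file path.
#' @param sample_rate,unitary,baseline metadata to attach on read.
#' @return \code{read_idealization_tsv} returns an \code{ip3r_idealization}.
#' @export
write_idealization_tsv <- function(ideal, path) {
  stopifnot(inherits(ideal, "ip3r_idealization"))
  d <- data.frame(level = ideal$events$level,
                  start_s = ideal$events$start,
                  duration_s = ideal$events$duration)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_idealization_tsv
#' @export
read_idealization_tsv <- function(path, sample_rate = NA_real_,
                                  unitary = NA_real_, baseline = 0) {
  d <- utils::read.delim(path)
  stopifnot(all(c("level", "start_s", "duration_s") %in% names(d)))
  make_idealization(d$level, d$duration_s, unitary, baseline, sample_rate)
}
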