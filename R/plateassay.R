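#' Synthesize a plate-reader well fluorescence trace
#'
#' Fluo-8-style well trace: baseline F0 before the agonist addition at
#' t = 0, then \eqn{F(t) = F_0 [1 + A (1 - e^{-t/\tau_r}) e^{-t/\tau_d}]}
#' with the transient amplitude A given by the Hill response at the well's
#' ATP concentration, plus additive Gaussian noise.
#'
#' @param atp ATP concentration, mol/L.
#' @param hill \code{\link{hill_params}} with \code{pmax} on the dF/F0 scale.
#' @param rise_tau,decay_tau transient kinetics, s.
#' @param f0 baseline fluorescence, a.u.
#' @param noise_sd additive noise SD, a.u.
#' @param dt sampling interval, s (plate readers here: 2 or 4 s).
#' @param pre_s pre-stimulus baseline length, s (agonist lands at t = 0).
#' @param duration_s post-stimulus acquisition, s.
#' @param genotype label carried as metadata.
#' @param seed optional integer seed.
#' @return object of class \code{well_trace}: samples, time axis, dt, atp,
#'   genotype, and the index of the stimulus sample.
#' @export
synthesize_well <- function(atp, hill, rise_tau = 8, decay_tau = 40,
                            f0 = 1000, noise_sd = 0, dt = 2, pre_s = 20,
                            duration_s = 180, genotype = "wt", seed = NULL) {
  stopifnot(inherits(hill, "hill_params"), atp >= 0, rise_tau > 0,
            decay_tau > 0, f0 > 0, noise_sd >= 0, dt %in% c(2, 4),
            pre_s >= 5 * dt, duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(-pre_s, duration_s, by = dt)
  a <- hill_po(atp, hill)
  g <- ifelse(t > 0, (1 - exp(-t / rise_tau)) * exp(-t / decay_tau), 0)
  y <- f0 * (1 + a * g)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  structure(list(samples = y, time = t, dt = dt, atp = atp,
                 genotype = genotype, stim_index = sum(t <= 0)),
            class = "well_trace")
}

#' Peak of the well-transient kinetic envelope
#'
#' Closed-form maximum of \eqn{(1 - e^{-t/a}) e^{-t/b}}: attained at
#' \eqn{t^* = a \ln(1 + b/a)} with value \eqn{(b/(a+b)) ((a+b)/a)^{-a/b}}.
#' Used to relate the generator's amplitude parameter to the observed
#' maximal dF/F0.
#'
#' @param rise_tau,decay_tau kinetics, s.
#' @return list with \code{t_peak} (s) and \code{g_max} (unitless, < 1).
#' @export
well_kinetic_peak <- function(rise_tau, decay_tau) {
  a <- rise_tau; b <- decay_tau
  t_star <- a * log((a + b) / a)
  list(t_peak = t_star, g_max = (b / (a + b)) * ((a + b) / a)^(-a / b))
}

#' Maximal dF/F0 of a well trace
#'
#' F0 is the mean of the pre-stimulus window (at least 5 samples); the
#' statistic is the maximum of (F - F0)/F0 over the trace, computed on a
#' short moving-average smoothed copy (default 5 samples) to control the
#' upward bias that taking a maximum over noisy samples would introduce.
#'
#' @param trace \code{well_trace}.
#' @param smooth odd moving-average window length in samples (1 = none).
#' @return maximal dF/F0 (unitless).
#' @export
max_dff <- function(trace, smooth = 5) {
  stopifnot(inherits(trace, "well_trace"), smooth >= 1)
  pre <- trace$samples[seq_len(trace$stim_index)]
  if (length(pre) < 5) stop("need >= 5 pre-stimulus samples for F0", call. = FALSE)
  f0 <- mean(pre)
  if (f0 <= 0) stop("non-positive baseline F0", call. = FALSE)
  y <- trace$samples
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    r <- (smooth - 1) %/% 2
    yp <- c(rep(y[1], r), y, rep(y[length(y)], r))
    y <- as.numeric(stats::filter(yp, k, sides = 2))[(r + 1):(r + length(y))]
  }
  max((y - f0) / f0)
}

#' ATP dose-response assay from grouped well traces
#'
#' Computes mean and SE of maximal dF/F0 per ATP level and fits a Hill
#' curve (\code{\link{fit_hill}}) to the concentration-response.
#'
#' @param wells list of \code{well_trace} objects covering >= 4 ATP levels
#'   with >= 2 replicates each.
#' @param smooth passed to \code{\link{max_dff}}.
#' @param weighted use the empirical per-level SEs as 1/SE^2 fit weights.
#'   Off by default: with a handful of replicates the empirical variances
#'   are unstable, and up-weighting the quiet low-dose wells amplifies the
#'   noise floor of the max-dF/F0 statistic; the SEs are still reported in
#'   the points table.
#' @return list with \code{points} (x, y, y_err, n) and \code{fit}
#'   (\code{ip3r_fit}).
#' @export
atp_dose_response <- function(wells, smooth = 5, weighted = FALSE) {
  stopifnot(is.list(wells), length(wells) >= 1)
  atp <- vapply(wells, `[[`, numeric(1), "atp")
  amp <- vapply(wells, max_dff, numeric(1), smooth = smooth)
  levels <- sort(unique(atp))
  if (length(levels) < 4) {
    stop("dose-response fit refused: need >= 4 ATP levels spanning the ",
         "response range (got ", length(levels), ")", call. = FALSE)
  }
  y <- vapply(levels, function(l) mean(amp[atp == l]), numeric(1))
  y_err <- vapply(levels, function(l) {
    v <- amp[atp == l]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  n <- vapply(levels, function(l) sum(atp == l), numeric(1))
  points <- data.frame(x = levels, y = y, y_err = y_err, n = n)
  fit_points <- if (weighted) points else points[c("x", "y", "n")]
  list(points = points, fit = fit_hill(fit_points))
}

#' Read / write a plate layout CSV
#'
#' Columns: well, atp_M, genotype.
#'
#' @param layout data.frame plate layout.
#' @param path file path.
#' @return \code{read_plate_layout} returns the layout data.frame.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(all(c("well", "atp_M", "genotype") %in% names(layout)))
  utils::write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("well", "atp_M", "genotype") %in% names(d)))
  d
}
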