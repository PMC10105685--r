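#' Bilayer simulation configuration
#'
#' Recording conditions for the synthetic planar-bilayer experiment:
#' digitization at 20 kHz after 2 kHz low-pass filtering, unitary Cs+
#' conductance 248 pS, by default. The default noise SD (0.6 pA) keeps
#' half-amplitude detection at 248 pS / +30 mV (threshold 3.72 pA, > 6 SD)
#' at a negligible false-event rate.
#'
#' @param n_channels number of independently gating channels (>= 1).
#' @param duration record length, s.
#' @param sample_rate digitization rate, Hz (>= 2 * filter_corner).
#' @param filter_corner -3 dB corner of the low-pass filter, Hz; 0 disables
#'   filtering.
#' @param conductance unitary conductance, pS.
#' @param reversal reversal potential, mV.
#' @param em applied membrane potential, mV (trans side; cis at ground).
#' @param noise_sd additive Gaussian noise SD, pA.
#' @param seed optional integer seed for end-to-end reproducibility.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_channels = 1, duration = 60, sample_rate = 20000,
                       filter_corner = 2000, conductance = 248, reversal = 0,
                       em = 30, noise_sd = 0.6, seed = NULL) {
  stopifnot(n_channels >= 1, duration > 0, sample_rate > 0,
            filter_corner >= 0, sample_rate >= 2 * filter_corner,
            conductance > 0, noise_sd >= 0)
  structure(list(n_channels = as.integer(n_channels), duration = duration,
                 sample_rate = sample_rate, filter_corner = filter_corner,
                 conductance = conductance, reversal = reversal, em = em,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

#' Simulate a two-state gating event train
#'
#' Continuous-time two-state Markov chain (closed <-> open) with exponential
#' dwell times; the initial state is drawn from the equilibrium distribution
#' and the final dwell is truncated at \code{duration}.
#'
#' @param opening_rate,closing_rate transition rates, 1/s (> 0).
#' @param duration record length, s.
#' @param seed optional integer seed.
#' @return data.frame of class \code{event_train} with columns \code{state}
#'   ("closed"/"open"), \code{start} and \code{duration} (s), contiguous and
#'   alternating over [0, duration].
#' @export
#' @examples
#' tr <- simulate_train(10, 100, 5, seed = 1)
#' sum(tr$duration)  # 5
simulate_train <- function(opening_rate, closing_rate, duration, seed = NULL) {
  stopifnot(opening_rate > 0, closing_rate > 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  po <- opening_rate / (opening_rate + closing_rate)
  first <- stats::rbinom(1, 1, po)  # 1 = open
  states <- integer(0)
  durs <- numeric(0)
  total <- 0
  # expected dwell count plus slack, drawn in batches
  cycle_rate <- opening_rate * closing_rate / (opening_rate + closing_rate)
  while (total < duration) {
    n <- max(64L, ceiling(2 * (duration - total) * cycle_rate + 10 * sqrt(duration * cycle_rate)))
    st <- if (length(states) == 0) first else 1L - states[length(states)]
    batch_states <- (st + seq_len(n) - 1L) %% 2L
    rates <- ifelse(batch_states == 1L, closing_rate, opening_rate)
    batch <- stats::rexp(n, rates)
    states <- c(states, batch_states)
    durs <- c(durs, batch)
    total <- total + sum(batch)
  }
  cum <- cumsum(durs)
  k <- which(cum >= duration)[1]
  states <- states[seq_len(k)]
  durs <- durs[seq_len(k)]
  durs[k] <- durs[k] - (cum[k] - duration)
  out <- data.frame(state = c("closed", "open")[states + 1L],
                    start = c(0, cumsum(durs))[seq_len(k)],
                    duration = durs, stringsAsFactors = FALSE)
  class(out) <- c("event_train", "data.frame")
  out
}

# fraction of record spent open
open_fraction <- function(train) {
  sum(train$duration[train$state == "open"]) / sum(train$duration)
}

# Gaussian FIR low-pass approximating an analog Bessel filter; -3 dB at fc.
# sigma_t = sqrt(ln 2)/(2 pi fc); edges handled by replicate padding.
gaussian_lowpass <- function(x, sample_rate, fc) {
  if (fc <= 0 || fc >= sample_rate / 2) return(x)
  sigma <- sqrt(log(2)) / (2 * pi * fc) * sample_rate  # in samples
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(r + 1):(r + length(x))])
}

#' Render event trains into a filtered, noisy current trace
#'
#' Each open channel contributes a unitary current
#' \eqn{i = \gamma (E_m - E_{rev}) / 1000} pA (positive = trans-to-cis
#' cation flux, i.e. upward openings at positive potentials); contributions
#' sum across channels, the summed record is low-pass filtered with a
#' Gaussian FIR kernel (-3 dB at \code{filter_corner}) and Gaussian noise of
#' SD \code{noise_sd} is added. Uses the current RNG state for the noise;
#' seed via \code{\link{simulate_experiment}} or \code{set.seed} for
#' reproducibility.
#'
#' @param trains a single \code{\link{simulate_train}} result or a list of
#'   them (one per channel), each covering \code{config$duration}.
#' @param config \code{\link{sim_config}}.
#' @return object of class \code{current_trace}: list with \code{samples}
#'   (pA), \code{sample_rate} and \code{config}.
#' @export
render_trace <- function(trains, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(trains, "event_train")) trains <- list(trains)
  stopifnot(length(trains) >= 1)
  n <- round(config$duration * config$sample_rate)
  t_mid <- (seq_len(n) - 0.5) / config$sample_rate
  level <- integer(n)
  for (tr in trains) {
    stopifnot(inherits(tr, "event_train"))
    if (abs(sum(tr$duration) - config$duration) > 1 / config$sample_rate) {
      stop("event train does not cover the configured duration", call. = FALSE)
    }
    idx <- findInterval(t_mid, tr$start)
    level <- level + (tr$state[idx] == "open")
  }
  i_unit <- config$conductance * (config$em - config$reversal) / 1000  # pA
  y <- level * i_unit
  y <- gaussian_lowpass(y, config$sample_rate, config$filter_corner)
  if (config$noise_sd > 0) y <- y + stats::rnorm(n, 0, config$noise_sd)
  structure(list(samples = y, sample_rate = config$sample_rate,
                 config = config),
            class = "current_trace")
}

#' Unitary current implied by a simulation configuration
#'
#' @param config \code{\link{sim_config}}.
#' @return unitary current, pA.
#' @export
unitary_current <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$conductance * (config$em - config$reversal) / 1000
}

#' Simulate a complete bilayer experiment
#'
#' Composes the ligand surface (equilibrium Po), two-state kinetics
#' (\code{\link{rates_from_po}}), per-channel gating trains and trace
#' rendering into one seeded, reproducible experiment with ground truth.
#'
#' @param ligands named list of ligand concentrations, any of \code{ip3},
#'   \code{ca_cis} (mol/L), matching the axes of \code{surface}.
#' @param surface \code{\link{ligand_surface}} (or \code{hill_params},
#'   interpreted as a pure IP3 surface).
#' @param mot mean open time, s.
#' @param config \code{\link{sim_config}}; its \code{seed} (if set) makes the
#'   whole experiment deterministic.
#' @return list with \code{trace} (\code{current_trace}), \code{trains}
#'   (ground-truth event trains, one per channel), \code{po} (the generating
#'   open probability) and \code{ligands}.
#' @export
simulate_experiment <- function(ligands, surface, mot, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(surface, "hill_params")) {
    surface <- ligand_surface(surface$pmax, ip3 = surface)
  }
  po <- surface_po(surface, ip3 = ligands$ip3, ca_cis = ligands$ca_cis)
  if (!is.finite(po) || po <= 0 || po >= 1) {
    stop("ligand surface yields Po outside (0, 1): ", format(po), call. = FALSE)
  }
  rates <- rates_from_po(po, mot)
  if (!is.null(config$seed)) set.seed(config$seed)
  trains <- lapply(seq_len(config$n_channels), function(i) {
    simulate_train(rates$opening_rate, rates$closing_rate, config$duration)
  })
  trace <- render_trace(trains, config)
  list(trace = trace, trains = trains, po = po, ligands = ligands)
}

#' Write / read a current trace as CSV
#'
#' Flat two-column text format (time_s, current_pA); the sampling rate is
#' recovered from the time column on read.
#'
#' @param trace \code{current_trace}.
#' @param path file path.
#' @return \code{read_trace_csv} returns a \code{current_trace} (with a
#'   minimal reconstructed config).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 0.5) / trace$sample_rate,
               current_pA = trace$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "current_pA") %in% names(d)), nrow(d) >= 2)
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(samples = d$current_pA, sample_rate = fs,
                 config = NULL), class = "current_trace")
}
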