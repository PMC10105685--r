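# End-to-end study workflows: generate synthetic data under the documented
# study conditions and push it through the analysis chain. These compose the
# module-level functions and are what the reproduction script and the
# vignette run.

#' Synthetic ATP plate assay with Hill fit
#'
#' Generates well traces at log-spaced ATP levels from the registry Hill
#' parameters for the chosen genotype (multiplicative trace noise given as
#' a fraction of baseline fluorescence), extracts maximal dF/F0 per well and
#' fits the ATP concentration-response.
#'
#' @param genotype "wt" or "d2594k".
#' @param n_levels number of ATP levels.
#' @param atp_range range of ATP levels, mol/L (log-spaced).
#' @param replicates wells per level.
#' @param noise_frac trace noise SD as a fraction of F0.
#' @param seed integer seed for the whole assay.
#' @return list with \code{points}, \code{fit} and \code{ec50_uM}.
#' @export
run_atp_assay <- function(genotype = c("wt", "d2594k"), n_levels = 8,
                          atp_range = c(0.3e-6, 100e-6), replicates = 6,
                          noise_frac = 0.05, seed = 1) {
  genotype <- match.arg(genotype)
  hill <- ip3r_params(paste0(genotype, "_atp"))
  set.seed(seed)
  levels <- 10^seq(log10(atp_range[1]), log10(atp_range[2]),
                   length.out = n_levels)
  f0 <- 1000
  wells <- list()
  for (atp in levels) for (r in seq_len(replicates)) {
    wells[[length(wells) + 1]] <- synthesize_well(
      atp, hill, f0 = f0, noise_sd = noise_frac * f0, genotype = genotype)
  }
  res <- atp_dose_response(wells)
  c(res, list(ec50_uM = res$fit$params$ec50 * 1e6))
}

#' Simulated unitary current-voltage relation with linear fit
#'
#' Unitary current amplitudes from a linear i-V relation plus Gaussian
#' noise, refit by ordinary least squares.
#'
#' @param conductance generating slope conductance, pS.
#' @param reversal reversal potential, mV.
#' @param voltages test potentials, mV.
#' @param noise_pa amplitude noise SD, pA.
#' @param seed integer seed.
#' @return list with \code{points}, \code{fit} and \code{conductance_pS}.
#' @export
run_iv_experiment <- function(conductance = 248, reversal = 0,
                              voltages = c(-40, -30, -20, 20, 30, 40),
                              noise_pa = 0.2, seed = 3) {
  set.seed(seed)
  i <- conductance / 1000 * (voltages - reversal) +
    stats::rnorm(length(voltages), 0, noise_pa)
  points <- data.frame(x = voltages, y = i)
  fit <- fit_linear_iv(points)
  list(points = points, fit = fit,
       conductance_pS = fit$params$conductance_pS)
}

#' Full simulate-idealize-nPo-Hill pipeline over IP3 levels
#'
#' For each IP3 concentration, simulates bilayer records from the registry
#' Hill surface for the genotype (two-state gating at the surface's
#' equilibrium Po, rendered at the configured potential/conductance with
#' Gaussian low-pass filtering and noise), idealizes them with the
#' half-amplitude threshold and dead-time censoring, pools nPo across
#' replicates and fits the IP3 dose-response Hill curve.
#'
#' @param genotype "wt" or "d2594k".
#' @param ip3_levels IP3 concentrations, mol/L.
#' @param n_reps records per level.
#' @param duration record length per trace, s.
#' @param mot mean open time of the generator, s.
#' @param em applied potential, mV.
#' @param noise_sd trace noise, pA.
#' @param dead_time censoring dead time, s.
#' @param seed integer seed for the whole experiment.
#' @return list with \code{points}, \code{fit}, \code{ec50_nM} and
#'   \code{truth} (the generating parameters).
#' @export
run_ip3_npo_experiment <- function(genotype = c("wt", "d2594k"),
                                   ip3_levels = 10^seq(log10(30e-9),
                                                       log10(10e-6),
                                                       length.out = 7),
                                   n_reps = 3, duration = 60, mot = 8e-3,
                                   em = 30, noise_sd = 0.6,
                                   dead_time = 300e-6, seed = 1) {
  genotype <- match.arg(genotype)
  hill <- ip3r_params(paste0(genotype, "_ip3"))
  set.seed(seed)
  config <- sim_config(n_channels = 1, duration = duration, em = em,
                       noise_sd = noise_sd)
  unitary <- unitary_current(config)
  trace_sets <- lapply(ip3_levels, function(ip3) {
    lapply(seq_len(n_reps), function(r) {
      simulate_experiment(list(ip3 = ip3), hill, mot, config)$trace
    })
  })
  res <- dose_response_pipeline(trace_sets, ip3_levels, unitary = unitary,
                                dead_time = dead_time, fit = "hill")
  c(res, list(ec50_nM = res$fit$params$ec50 * 1e9, truth = hill))
}

#' Biphasic cytosolic Ca2+ dose-response recovery
#'
#' Synthesizes nPo points from the registry biphasic Hill parameters for
#' the genotype with multiplicative Gaussian noise and refits the biphasic
#' Hill equation.
#'
#' @param genotype "wt", "d2594k" or "d2594a".
#' @param n_points number of log-spaced cytosolic Ca2+ levels.
#' @param ca_range concentration range, mol/L.
#' @param noise_frac multiplicative noise SD.
#' @param seed integer seed.
#' @return list with \code{points}, \code{fit}, \code{ec50_act_nM},
#'   \code{ic50_inh_nM}.
#' @export
run_cyto_ca_experiment <- function(genotype = c("wt", "d2594k", "d2594a"),
                                   n_points = 12,
                                   ca_range = c(10e-9, 10e-6),
                                   noise_frac = 0.03, seed = 7) {
  genotype <- match.arg(genotype)
  pars <- ip3r_params(paste0(genotype, "_cyto_ca"))
  set.seed(seed)
  x <- 10^seq(log10(ca_range[1]), log10(ca_range[2]), length.out = n_points)
  y <- biphasic_po(x, pars) * (1 + stats::rnorm(n_points, 0, noise_frac))
  points <- data.frame(x = x, y = y)
  fit <- fit_biphasic_hill(points)
  list(points = points, fit = fit,
       ec50_act_nM = fit$params$ec50_act * 1e9,
       ic50_inh_nM = fit$params$ic50_inh * 1e9)
}

#' Double-Hill MOT-versus-EDF refit on noisy curve samples
#'
#' Evaluates the feedthrough mean-open-time model at positive driving
#' forces, perturbs it with multiplicative Gaussian noise, and refits with
#' the baseline fixed at 1.
#'
#' @param params \code{\link{feedthrough_mot_params}} (default: the
#'   registry wild-type set).
#' @param edf_mv driving-force sample points, mV; the default spaces 12
#'   points logarithmically over 60-260 mV, concentrating samples on the
#'   steep activation limb as a log dose grid does for a sigmoid.
#' @param noise_frac multiplicative noise SD.
#' @param seed integer seed.
#' @return list with \code{points}, \code{fit} and \code{va50_mV}.
#' @export
run_mot_edf_experiment <- function(params = ip3r_params("wt_mot_edf"),
                                   edf_mv = exp(seq(log(60), log(260),
                                                    length.out = 12)),
                                   noise_frac = 0.05, seed = 11) {
  set.seed(seed)
  y <- mot_edf_model(edf_mv, params) *
    (1 + stats::rnorm(length(edf_mv), 0, noise_frac))
  points <- data.frame(x = edf_mv, y = y)
  fit <- fit_mot_edf(points)
  list(points = points, fit = fit, va50_mV = fit$params$va50)
}

#' Synthetic linescan experiment: generate, detect, measure
#'
#' Synthesizes linescans whose event kinetics are tuned (via the
#' closed-form FDHM identity, \code{\link{puff_shape_for_fdhm}}) to a
#' target half-duration, with event amplitude expressed as a multiple of
#' the background noise SD, then runs the SD-threshold detector and pools
#' the measured kinetics and per-cell frequency.
#'
#' @param fdhm_target generator full duration at half maximum, s.
#' @param rate events/s/cell. The kinetics default (0.03/s) keeps events
#'   sparse enough that overlapping puffs rarely distort single-event
#'   kinetics; frequency studies pass the condition's own rate instead.
#' @param n_cells,duration scan geometry (defaults give ~86 expected events).
#' @param amp_over_sd event peak amplitude as a multiple of background SD.
#' @param k_sd detection threshold, SDs.
#' @param dt,dx line period (s) and pixel size (um).
#' @param seed integer seed.
#' @return list with \code{events} (detected), \code{truth},
#'   \code{mean_fdhm_s}, \code{frequency_hz}, \code{n_detected}.
#' @export
run_puff_experiment <- function(fdhm_target, rate = 0.03, n_cells = 24,
                                duration = 120, amp_over_sd = 10,
                                k_sd = 5.5, dt = 0.1, dx = 0.63, seed = 9) {
  shape <- puff_shape_for_fdhm(fdhm_target)
  baseline_f0 <- 100
  noise_sd <- 5
  spec <- puff_gen_spec(rate = rate,
                        amplitude = amp_over_sd * noise_sd / baseline_f0,
                        rise_time = shape$rise_time,
                        decay_tau = shape$decay_tau,
                        baseline_f0 = baseline_f0, noise_sd = noise_sd,
                        duration = duration, dt = dt, dx = dx, seed = seed)
  syn <- synthesize_linescan(spec, n_cells = n_cells)
  events <- detect_puffs(syn$image, k_sd = k_sd)
  fdhm <- events$fdhm_s[is.finite(events$fdhm_s)]
  list(events = events, truth = syn$truth,
       mean_fdhm_s = mean(fdhm),
       frequency_hz = puff_frequency(events, n_cells, duration),
       n_detected = nrow(events))
}
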