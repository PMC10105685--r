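# Physical constants (SI): gas constant, Faraday constant, Ca2+ valence
.R_GAS <- 8.314
.FARADAY <- 96485
.Z_CA <- 2

#' Hill activation parameters
#'
#' @param pmax open-probability ceiling, in (0, 1] for Po data (larger values
#'   are allowed for other response scales such as dF/F0).
#' @param ec50 half-activation ligand concentration, mol/L (> 0).
#' @param h Hill coefficient (> 0).
#' @return object of class \code{hill_params}.
#' @export
hill_params <- function(pmax, ec50, h) {
  stopifnot(is.finite(pmax), pmax > 0, is.finite(ec50), ec50 > 0,
            is.finite(h), h > 0)
  structure(list(pmax = pmax, ec50 = ec50, h = h), class = "hill_params")
}

#' Biphasic (bell-shaped) Hill parameters
#'
#' Product of an activating and an inhibitory Hill term, the standard model
#' for the bell-shaped cytosolic Ca2+ dependence of IP3R open probability.
#'
#' @param pmax response ceiling (> 0).
#' @param ec50_act activation midpoint, mol/L.
#' @param h_act activation Hill coefficient.
#' @param ic50_inh inhibition midpoint, mol/L (typically > ec50_act).
#' @param h_inh inhibition Hill coefficient.
#' @return object of class \code{biphasic_hill_params}.
#' @export
biphasic_hill_params <- function(pmax, ec50_act, h_act, ic50_inh, h_inh) {
  stopifnot(is.finite(pmax), pmax > 0,
            is.finite(ec50_act), ec50_act > 0, is.finite(h_act), h_act > 0,
            is.finite(ic50_inh), ic50_inh > 0, is.finite(h_inh), h_inh > 0)
  structure(list(pmax = pmax, ec50_act = ec50_act, h_act = h_act,
                 ic50_inh = ic50_inh, h_inh = h_inh),
            class = "biphasic_hill_params")
}

#' Double-Hill parameters for mean open time versus driving force
#'
#' @param range amplitude of the bell above the baseline of 1 (> 0).
#' @param va50 activation midpoint, mV (> 0).
#' @param ha activation exponent.
#' @param vi50 inhibition midpoint, mV (> 0).
#' @param hi inhibition exponent.
#' @return object of class \code{feedthrough_mot_params}.
#' @export
feedthrough_mot_params <- function(range, va50, ha, vi50, hi) {
  stopifnot(is.finite(range), range > 0, is.finite(va50), va50 > 0,
            is.finite(ha), ha > 0, is.finite(vi50), vi50 > 0,
            is.finite(hi), hi > 0)
  structure(list(range = range, va50 = va50, ha = ha, vi50 = vi50, hi = hi),
            class = "feedthrough_mot_params")
}

#' Ionic conditions across the bilayer
#'
#' The trans (luminal) side carries the applied potential, cis (cytosolic)
#' is at ground; positive driving force means trans-to-cis Ca2+ flux.
#'
#' @param em membrane potential, mV.
#' @param ca_cis,ca_trans free Ca2+ on the cis / trans side, mol/L (> 0).
#' @param temperature K (default 295.15, i.e. 22 C).
#' @return object of class \code{ion_conditions}.
#' @export
ion_conditions <- function(em, ca_cis, ca_trans, temperature = 295.15) {
  stopifnot(is.finite(em))
  if (!is.finite(ca_cis) || ca_cis <= 0 || !is.finite(ca_trans) || ca_trans <= 0) {
    stop("ca_cis and ca_trans must be finite and > 0", call. = FALSE)
  }
  stopifnot(is.finite(temperature), temperature > 0)
  structure(list(em = em, ca_cis = ca_cis, ca_trans = ca_trans,
                 temperature = temperature), class = "ion_conditions")
}

#' Hill open probability
#'
#' \eqn{Po = pmax / (1 + (EC50/L)^h)}; zero at zero ligand, saturating at
#' \code{pmax}.
#'
#' @param ligand ligand concentration(s), mol/L (>= 0). Vectorized.
#' @param params \code{\link{hill_params}}.
#' @return open probability, same length as \code{ligand}.
#' @export
#' @examples
#' hill_po(660e-9, hill_params(0.1, 660e-9, 1.8))  # pmax/2
hill_po <- function(ligand, params) {
  stopifnot(inherits(params, "hill_params"), all(is.finite(ligand)), all(ligand >= 0))
  out <- numeric(length(ligand))
  pos <- ligand > 0
  out[pos] <- params$pmax / (1 + (params$ec50 / ligand[pos])^params$h)
  out
}

#' Biphasic Hill open probability
#'
#' \eqn{Po = pmax \, [1+(EC50/Ca)^{h_a}]^{-1} [1+(Ca/IC50)^{h_i}]^{-1}}:
#' activation at low and inhibition at high cytosolic Ca2+, vanishing at both
#' extremes.
#'
#' @param ca cytosolic Ca2+ concentration(s), mol/L (>= 0). Vectorized.
#' @param params \code{\link{biphasic_hill_params}}.
#' @return open probability.
#' @export
biphasic_po <- function(ca, params) {
  stopifnot(inherits(params, "biphasic_hill_params"),
            all(is.finite(ca)), all(ca >= 0))
  out <- numeric(length(ca))
  pos <- ca > 0
  x <- ca[pos]
  out[pos] <- params$pmax /
    (1 + (params$ec50_act / x)^params$h_act) /
    (1 + (x / params$ic50_inh)^params$h_inh)
  out
}

#' Nernst potential for Ca2+
#'
#' \eqn{E_{Ca} = (RT / z_{Ca} F)\,\ln([Ca]_{cis}/[Ca]_{trans})} in mV, with
#' R = 8.314 J/(K mol), F = 96485 C/mol, z = 2.
#'
#' @param cond \code{\link{ion_conditions}}.
#' @return Nernst potential, mV.
#' @export
#' @examples
#' nernst_eca(ion_conditions(0, 140e-9, 1e-3))  # about -112.9 mV
nernst_eca <- function(cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  (.R_GAS * cond$temperature / (.Z_CA * .FARADAY)) *
    log(cond$ca_cis / cond$ca_trans) * 1000
}

#' Electrochemical driving force for Ca2+
#'
#' \eqn{EDF = E_m - E_{Ca}}; positive values drive trans-to-cis (lumen-to-
#' cytosol) Ca2+ flux.
#'
#' @param cond \code{\link{ion_conditions}}.
#' @return driving force, mV.
#' @export
edf <- function(cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  cond$em - nernst_eca(cond)
}

#' Normalized mean open time as a function of driving force
#'
#' Double-Hill bell on the positive-EDF side,
#' \eqn{MOT = 1 + Range\,[1+(Va_{50}/EDF)^{Ha}]^{-1}[1+(EDF/Vi_{50})^{Hi}]^{-1}},
#' pinned to the baseline of 1 for \eqn{EDF \le 0} where flux is
#' cytosol-to-lumen and feedthrough cannot occur (and where the power terms
#' are undefined for non-integer exponents).
#'
#' @param edf_mv driving force(s), mV. Vectorized.
#' @param params \code{\link{feedthrough_mot_params}}.
#' @return normalized mean open time, in [1, 1 + range].
#' @export
mot_edf_model <- function(edf_mv, params) {
  stopifnot(inherits(params, "feedthrough_mot_params"), all(is.finite(edf_mv)))
  out <- rep(1, length(edf_mv))
  pos <- edf_mv > 0
  x <- edf_mv[pos]
  out[pos] <- 1 + params$range /
    (1 + (params$va50 / x)^params$ha) /
    (1 + (x / params$vi50)^params$hi)
  out
}

#' Two-state rates from equilibrium open probability and mean open time
#'
#' Maps an equilibrium target onto closed <-> open kinetics: closing rate
#' \eqn{\beta = 1/MOT} and opening rate \eqn{\alpha = Po/((1-Po)\,MOT)}, so
#' that \eqn{\alpha/(\alpha+\beta) = Po}.
#'
#' @param po open probability, strictly in (0, 1).
#' @param mot mean open time, s (> 0).
#' @return named list with \code{opening_rate} and \code{closing_rate}, 1/s.
#' @export
#' @examples
#' rates_from_po(0.5, 0.01)  # 100/s each
rates_from_po <- function(po, mot) {
  if (!is.finite(po) || po <= 0 || po >= 1) {
    stop("po must be strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(is.finite(mot), mot > 0)
  list(opening_rate = po / ((1 - po) * mot), closing_rate = 1 / mot)
}

#' Joint ligand surface for the gating simulator
#'
#' Composes the per-ligand dependences multiplicatively:
#' \eqn{Po = pmax \cdot f_{IP3}([IP3]) \cdot f_{Ca}([Ca]_{cis})}, each factor
#' normalized to [0, 1] (a modelling choice; per-axis fits never depend on
#' the composition rule). Either factor may be omitted (treated as 1).
#'
#' @param pmax overall Po ceiling.
#' @param ip3 optional \code{\link{hill_params}} for the IP3 axis (its own
#'   \code{pmax} is ignored; the factor is normalized).
#' @param ca optional \code{\link{biphasic_hill_params}} for the cytosolic
#'   Ca2+ axis (normalized to a peak of 1 on a log grid).
#' @return object of class \code{ligand_surface}.
#' @export
ligand_surface <- function(pmax, ip3 = NULL, ca = NULL) {
  stopifnot(is.finite(pmax), pmax > 0)
  if (!is.null(ip3)) stopifnot(inherits(ip3, "hill_params"))
  if (!is.null(ca)) stopifnot(inherits(ca, "biphasic_hill_params"))
  ca_peak <- if (is.null(ca)) 1 else {
    grid <- 10^seq(log10(ca$ec50_act) - 3, log10(ca$ic50_inh) + 3, length.out = 2000)
    max(biphasic_po(grid, ca)) / ca$pmax
  }
  structure(list(pmax = pmax, ip3 = ip3, ca = ca, ca_peak = ca_peak),
            class = "ligand_surface")
}

#' Evaluate a ligand surface
#'
#' @param surface \code{\link{ligand_surface}}.
#' @param ip3 cytosolic IP3, mol/L (ignored if the surface has no IP3 axis).
#' @param ca_cis cytosolic free Ca2+, mol/L (ignored if no Ca axis).
#' @return open probability.
#' @export
surface_po <- function(surface, ip3 = NULL, ca_cis = NULL) {
  stopifnot(inherits(surface, "ligand_surface"))
  po <- surface$pmax
  if (!is.null(surface$ip3)) {
    if (is.null(ip3)) stop("surface has an IP3 axis; supply ip3", call. = FALSE)
    po <- po * hill_po(ip3, surface$ip3) / surface$ip3$pmax
  }
  if (!is.null(surface$ca)) {
    if (is.null(ca_cis)) stop("surface has a Ca axis; supply ca_cis", call. = FALSE)
    po <- po * biphasic_po(ca_cis, surface$ca) / surface$ca$pmax / surface$ca_peak
  }
  po
}

#' Named gating parameter registry
#'
#' Returns one entry of the shipped parameter registry
#' (\code{inst/params/ip3r_params.yaml}) as the corresponding parameter
#' object. Entries hold the fitted dose-response parameters for the
#' wild-type and mutant channels (IP3 activation, cytosolic Ca2+ biphasic
#' dependence, ATP plate response, feedthrough MOT model, puff kinetics).
#'
#' @param name registry entry, e.g. \code{"wt_ip3"}; call with no arguments
#'   to list available names.
#' @return a parameter object, or a character vector of entry names.
#' @export
#' @examples
#' ip3r_params()
#' ip3r_params("wt_ip3")
ip3r_params <- function(name = NULL) {
  path <- system.file("params", "ip3r_params.yaml", package = "ip3rkit")
  reg <- yaml::read_yaml(path)
  if (is.null(name)) return(names(reg))
  if (!name %in% names(reg)) {
    stop("unknown parameter set '", name, "'; see ip3r_params()", call. = FALSE)
  }
  p <- reg[[name]]
  switch(p$model,
    hill = hill_params(p$pmax, p$ec50, p$h),
    biphasic = biphasic_hill_params(p$pmax, p$ec50_act, p$h_act,
                                    p$ic50_inh, p$h_inh),
    mot_edf = feedthrough_mot_params(p$range, p$va50, p$ha, p$vi50, p$hi),
    puffs = p[setdiff(names(p), "model")],
    stop("unknown model type in registry: ", p$model)
  )
}
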