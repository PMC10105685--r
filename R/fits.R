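# Shared nonlinear least-squares driver: multi-start Levenberg-Marquardt
# (minpack.lm::nls.lm) with box constraints; returns the best-RSS fit.
nls_multistart <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  best_rss <- Inf
  best_h <- Inf
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    h0 <- if ("h" %in% names(p0)) p0[["h"]] else Inf
    # best RSS wins; exact ties broken toward the smallest starting h
    if (rss < best_rss - 1e-12 || (abs(rss - best_rss) <= 1e-12 && h0 < best_h)) {
      best <- fit
      best_rss <- rss
      best_h <- h0
    }
  }
  best
}

# parameter standard errors from a converged nls.lm fit (Jacobian-based)
nls_se <- function(fit, n, p) {
  se <- tryCatch(unname(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) rep(NA_real_, p))
  if (length(se) != p) se <- rep(NA_real_, p)
  se
}

new_fit_result <- function(params, se, rss, converged, n_points, model,
                           flags = character(0)) {
  structure(list(params = params, se = se, rss = rss, converged = converged,
                 n_points = n_points, model = model, flags = flags),
            class = "ip3r_fit")
}

#' @export
print.ip3r_fit <- function(x, ...) {
  cat(sprintf("%s fit (%d points)%s\n", x$model, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]"))
  est <- data.frame(estimate = unlist(x$params), se = unlist(x$se))
  print(signif(est, 4))
  cat(sprintf("RSS: %.4g\n", x$rss))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

check_points <- function(points, min_n) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  points <- points[is.finite(points$x) & is.finite(points$y), , drop = FALSE]
  if (nrow(points) < min_n) {
    stop("need at least ", min_n, " finite data points", call. = FALSE)
  }
  points
}

point_weights <- function(points) {
  if (!is.null(points$y_err) && all(is.finite(points$y_err)) &&
      all(points$y_err > 0)) 1 / points$y_err^2 else rep(1, nrow(points))
}

#' Fit a Hill dose-response curve
#'
#' Weighted least squares of \code{\link{hill_po}} to (concentration,
#' response) points. EC50 is log-parameterized to keep it positive;
#' initialization is multi-start over log-spaced EC50 seeds spanning the
#' data's x-range crossed with Hill coefficients \{1, 2, 4\}, the best-RSS
#' fit winning (ties broken toward the smallest h). Standard errors come
#' from the Jacobian at the optimum (delta method for EC50).
#'
#' @param points data.frame with columns \code{x} (mol/L), \code{y} and
#'   optional \code{y_err} (SE used for 1/SE^2 weighting).
#' @return \code{ip3r_fit} with params pmax, ec50, h. A flat or
#'   uninformative response yields \code{converged = FALSE} with an
#'   "ec50 unidentifiable" flag rather than an error.
#' @export
#' @examples
#' x <- 10^seq(-7.5, -5, length.out = 8)
#' pts <- data.frame(x = x, y = hill_po(x, hill_params(0.1, 660e-9, 1.8)))
#' fit_hill(pts)
fit_hill <- function(points) {
  points <- check_points(points, 4)
  x <- points$x; y <- points$y; w <- point_weights(points)
  xr <- range(x[x > 0])
  if (diff(log10(xr)) < 1) warning("x values span less than one decade")
  resid_fn <- function(p) {
    sqrt(w) * (y - p[["pmax"]] / (1 + exp(p[["lec50"]] - log(x))^p[["h"]]))
  }
  ec_seeds <- exp(seq(log(xr[1]), log(xr[2]), length.out = 5))
  starts <- list()
  for (ec in ec_seeds) for (h in c(1, 2, 4)) {
    starts[[length(starts) + 1]] <- c(pmax = max(y), lec50 = log(ec), h = h)
  }
  lower <- c(pmax = 1e-12, lec50 = log(xr[1]) - log(1e4), h = 0.1)
  upper <- c(pmax = 10 * max(abs(y)) + 1, lec50 = log(xr[2]) + log(1e4), h = 25)
  fit <- nls_multistart(resid_fn, starts, lower, upper)
  if (is.null(fit)) {
    return(new_fit_result(list(pmax = NA, ec50 = NA, h = NA),
                          list(pmax = NA, ec50 = NA, h = NA),
                          NA, FALSE, nrow(points), "hill", "optimization failed"))
  }
  p <- fit$par
  se_raw <- nls_se(fit, nrow(points), 3)
  ec50 <- exp(p[["lec50"]])
  params <- list(pmax = p[["pmax"]], ec50 = ec50, h = p[["h"]])
  se <- list(pmax = se_raw[1], ec50 = ec50 * se_raw[2], h = se_raw[3])
  flags <- character(0)
  converged <- TRUE
  # unidentifiable midpoint: flat data or EC50 pushed far outside the data
  if (!is.finite(se_raw[2]) || se_raw[2] > 5 ||
      ec50 < xr[1] / 1e3 || ec50 > xr[2] * 1e3 || stats::sd(y) == 0) {
    converged <- FALSE
    flags <- "ec50 unidentifiable"
  }
  new_fit_result(params, se, sum(fit$fvec^2), converged, nrow(points),
                 "hill", flags)
}

#' Fit a biphasic (bell-shaped) Hill curve
#'
#' Weighted least squares of \code{\link{biphasic_po}}. The midpoints are
#' parameterized as log(EC50) and log(IC50) = log(EC50) + exp(gap), which
#' enforces EC50 < IC50. Multi-start over midpoint pairs spanning the data
#' range and Hill coefficients \{1, 2, 4\}.
#'
#' @param points data.frame with columns \code{x} (mol/L), \code{y},
#'   optional \code{y_err}; needs coverage on both sides of the mode for the
#'   descending limb to be identifiable (otherwise the result carries an
#'   "ic50 unidentifiable" flag).
#' @return \code{ip3r_fit} with params pmax, ec50_act, h_act, ic50_inh, h_inh.
#' @export
fit_biphasic_hill <- function(points) {
  points <- check_points(points, 6)
  x <- points$x; y <- points$y; w <- point_weights(points)
  xr <- range(x[x > 0])
  model <- function(p) {
    ec <- exp(p[["lec50"]]); ic <- exp(p[["lec50"]] + exp(p[["lgap"]]))
    p[["pmax"]] / (1 + (ec / x)^p[["h_act"]]) / (1 + (x / ic)^p[["h_inh"]])
  }
  resid_fn <- function(p) sqrt(w) * (y - model(p))
  ec_seeds <- exp(seq(log(xr[1]), log(sqrt(prod(xr))), length.out = 4))
  gap_seeds <- log(c(1, 2.5, 5))  # IC50/EC50 ratio seeds e^1..e^5
  starts <- list()
  for (ec in ec_seeds) for (g in gap_seeds) for (h in c(1, 2, 4)) {
    starts[[length(starts) + 1]] <-
      c(pmax = max(y), lec50 = log(ec), h_act = h, lgap = g, h_inh = h)
  }
  lower <- c(pmax = 1e-12, lec50 = log(xr[1] / 1e4), h_act = 0.1,
             lgap = log(1e-3), h_inh = 0.1)
  upper <- c(pmax = 10 * max(abs(y)) + 1, lec50 = log(xr[2] * 1e4), h_act = 25,
             lgap = log(30), h_inh = 25)
  fit <- nls_multistart(resid_fn, starts, lower, upper)
  if (is.null(fit)) {
    nal <- list(pmax = NA, ec50_act = NA, h_act = NA, ic50_inh = NA, h_inh = NA)
    return(new_fit_result(nal, nal, NA, FALSE, nrow(points), "biphasic_hill",
                          "optimization failed"))
  }
  p <- fit$par
  se_raw <- nls_se(fit, nrow(points), 5)
  ec50 <- exp(p[["lec50"]])
  ic50 <- exp(p[["lec50"]] + exp(p[["lgap"]]))
  params <- list(pmax = p[["pmax"]], ec50_act = ec50, h_act = p[["h_act"]],
                 ic50_inh = ic50, h_inh = p[["h_inh"]])
  # delta method: d(lic)/d(lec)=1, d(lic)/d(lgap)=exp(lgap)
  se <- list(pmax = se_raw[1], ec50_act = ec50 * se_raw[2],
             h_act = se_raw[3],
             ic50_inh = ic50 * sqrt(se_raw[2]^2 + (exp(p[["lgap"]]) * se_raw[4])^2),
             h_inh = se_raw[5])
  flags <- character(0)
  converged <- TRUE
  if (ic50 > xr[2] * 50 || !is.finite(se_raw[4]) || se_raw[4] > 5) {
    flags <- c(flags, "ic50 unidentifiable (no descending limb?)")
    converged <- FALSE
  }
  if (ec50 < xr[1] / 1e3 || stats::sd(y) == 0) {
    flags <- c(flags, "ec50 unidentifiable")
    converged <- FALSE
  }
  new_fit_result(params, se, sum(fit$fvec^2), converged, nrow(points),
                 "biphasic_hill", flags)
}

#' Linear current-voltage fit (slope conductance)
#'
#' Ordinary least squares of unitary current (pA) on voltage (mV); the slope
#' (pA/mV = nS) is reported as conductance in pS together with the reversal
#' potential (the x-intercept).
#'
#' @param points data.frame with columns \code{x} (mV) and \code{y} (pA);
#'   at least 3 rows and 2 distinct voltages.
#' @return \code{ip3r_fit} with params conductance_pS and reversal_mV.
#' @export
#' @examples
#' v <- c(-40, -30, -20, 20, 30, 40)
#' fit_linear_iv(data.frame(x = v, y = 0.248 * v))
fit_linear_iv <- function(points) {
  points <- check_points(points, 2)
  if (length(unique(points$x)) < 2) stop("need >= 2 distinct voltages", call. = FALSE)
  if (nrow(points) < 3 && length(unique(points$x)) < 2) {
    stop("rank-deficient i-V data", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = points)
  cf <- stats::coef(fit)
  slope <- cf[["x"]]; intercept <- cf[["(Intercept)"]]
  se <- if (nrow(points) > 2) {
    suppressWarnings(sqrt(diag(stats::vcov(fit))))  # exact fits: SE ~ 0
  } else c(NA_real_, NA_real_)
  new_fit_result(
    params = list(conductance_pS = slope * 1000,
                  reversal_mV = -intercept / slope),
    se = list(conductance_pS = unname(se[2]) * 1000,
              reversal_mV = NA_real_),
    rss = sum(stats::resid(fit)^2), converged = TRUE,
    n_points = nrow(points), model = "linear_iv")
}

#' Fit the double-Hill MOT-versus-EDF model
#'
#' Least squares of \code{\link{mot_edf_model}} (baseline fixed at 1) to
#' normalized mean-open-time points at positive electrochemical driving
#' forces. The inhibition midpoint is parameterized as
#' vi50 = va50 + d (d > 0), which enforces the physical ordering
#' activation-before-inhibition and removes a degenerate unordered branch
#' of the RSS surface. Bounded multi-start: midpoints in [10, 500] mV,
#' exponents in [0.5, 20].
#'
#' @param points data.frame with columns \code{x} (EDF, mV) and \code{y}
#'   (normalized MOT); at least 5 points with x > 0 are required, with
#'   coverage of both limbs for the inhibition parameters to be
#'   identifiable.
#' @return \code{ip3r_fit} with params range, va50, ha, vi50, hi.
#' @export
fit_mot_edf <- function(points) {
  points <- check_points(points, 5)
  pos <- points[points$x > 0, , drop = FALSE]
  if (nrow(pos) < 5) stop("need >= 5 points with EDF > 0", call. = FALSE)
  x <- pos$x; y <- pos$y; w <- point_weights(pos)
  resid_fn <- function(p) {
    vi <- p[["va50"]] + p[["d"]]
    m <- 1 + p[["range"]] / (1 + (p[["va50"]] / x)^p[["ha"]]) /
      (1 + (x / vi)^p[["hi"]])
    sqrt(w) * (y - m)
  }
  starts <- list()
  for (va in c(80, 120, 180)) for (d in c(30, 80, 150)) {
    for (ha in c(4, 8)) for (hi in c(2, 4)) {
      starts[[length(starts) + 1]] <-
        c(range = max(max(y) - 1, 0.5), va50 = va, ha = ha, d = d, hi = hi)
    }
  }
  lower <- c(range = 1e-6, va50 = 10, ha = 0.5, d = 0.1, hi = 0.5)
  upper <- c(range = 100, va50 = 500, ha = 20, d = 490, hi = 20)
  fit <- nls_multistart(resid_fn, starts, lower, upper)
  if (is.null(fit)) {
    nal <- list(range = NA, va50 = NA, ha = NA, vi50 = NA, hi = NA)
    return(new_fit_result(nal, nal, NA, FALSE, nrow(pos), "mot_edf",
                          "optimization failed"))
  }
  pp <- fit$par
  vi50 <- pp[["va50"]] + pp[["d"]]
  params <- list(range = pp[["range"]], va50 = pp[["va50"]], ha = pp[["ha"]],
                 vi50 = vi50, hi = pp[["hi"]])
  rss <- sum(fit$fvec^2)
  vc <- tryCatch(rss / max(1, nrow(pos) - 5) * chol2inv(chol(fit$hessian)),
                 error = function(e) matrix(NA_real_, 5, 5))
  se_raw <- sqrt(pmax(diag(vc), 0))
  se <- list(range = se_raw[1], va50 = se_raw[2], ha = se_raw[3],
             vi50 = sqrt(max(vc[2, 2] + vc[4, 4] + 2 * vc[2, 4], 0)),
             hi = se_raw[5])
  flags <- character(0)
  converged <- TRUE
  if (vi50 >= 500 || pp[["d"]] >= 490 * 0.999 || max(x) < pp[["va50"]] ||
      !is.finite(se$vi50) || se$vi50 > vi50) {
    flags <- "vi50 unidentifiable (no descending limb?)"
    converged <- FALSE
  }
  new_fit_result(params, se, rss, converged, nrow(pos), "mot_edf", flags)
}

#' Overlay the flipped, scaled MOT curve on mean closed times
#'
#' Fits \eqn{MCT(EDF) = a - b \cdot MOT_{model}(EDF)} with \eqn{b \ge 0} by
#' least squares over (a, b): the bell fitted to mean open time, inverted
#' and rescaled, as a descriptive overlay for the closed-time dependence.
#' Reports the scale, offset, RSS, and an F-test against the constant-only
#' model.
#'
#' @param mot_fit a converged \code{\link{fit_mot_edf}} result (or a
#'   \code{\link{feedthrough_mot_params}} object).
#' @param points data.frame with \code{x} (EDF, mV) and \code{y}
#'   (normalized MCT).
#' @return list with \code{a}, \code{b}, \code{rss}, \code{rss_const},
#'   \code{f_p} (F-test p-value vs constant fit) and fitted values.
#' @export
mct_overlay <- function(mot_fit, points) {
  if (inherits(mot_fit, "ip3r_fit")) {
    if (!isTRUE(mot_fit$converged)) stop("MOT fit did not converge", call. = FALSE)
    pars <- do.call(feedthrough_mot_params, mot_fit$params[c("range", "va50", "ha", "vi50", "hi")])
  } else {
    pars <- mot_fit
  }
  stopifnot(inherits(pars, "feedthrough_mot_params"))
  points <- check_points(points, 3)
  m <- mot_edf_model(points$x, pars)
  fit <- stats::lm(y ~ I(-m), data = points)
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  if (!is.finite(b) || b < 0) {  # constrained: flipped means b >= 0
    b <- 0
    a <- mean(points$y)
    rss <- sum((points$y - a)^2)
  } else {
    rss <- sum(stats::resid(fit)^2)
  }
  rss0 <- sum((points$y - mean(points$y))^2)
  n <- nrow(points)
  fstat <- if (rss > 0) (rss0 - rss) / (rss / (n - 2)) else Inf
  f_p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(a = a, b = b, rss = rss, rss_const = rss0, f_p = f_p,
       fitted = a - b * m)
}

#' Dose-response pipeline over simulated or recorded traces
#'
#' Idealizes every trace of every condition, computes per-condition nPo
#' (mean and SE across traces) and fits the requested dose-response model.
#' Full provenance (idealization settings, per-trace nPo) is returned.
#'
#' @param trace_sets list (one element per condition) of lists of
#'   \code{current_trace} objects.
#' @param x vector of condition values (ligand concentration, mol/L), one
#'   per element of \code{trace_sets}.
#' @param unitary unitary current, pA, for the half-amplitude idealizer.
#' @param n_levels,dead_time idealization settings (see
#'   \code{\link{idealize_trace}}).
#' @param fit one of "hill", "biphasic", "none".
#' @return list with \code{points} (data.frame x, y, y_err, n), \code{fit}
#'   (\code{ip3r_fit} or NULL), \code{per_trace} nPo values, and
#'   \code{provenance}.
#' @export
dose_response_pipeline <- function(trace_sets, x, unitary, n_levels = 1,
                                   dead_time = 300e-6,
                                   fit = c("hill", "biphasic", "none")) {
  fit <- match.arg(fit)
  stopifnot(is.list(trace_sets), length(trace_sets) == length(x),
            all(lengths(trace_sets) >= 1))
  per_trace <- lapply(trace_sets, function(traces) {
    vapply(traces, function(tr) {
      ideal <- idealize_trace(tr, unitary = unitary, n_levels = n_levels,
                              dead_time = dead_time)
      suppressWarnings(channel_stats(ideal)$npo)
    }, numeric(1))
  })
  y <- vapply(per_trace, mean, numeric(1))
  y_err <- vapply(per_trace, function(v) {
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  points <- data.frame(x = x, y = y, y_err = y_err, n = lengths(per_trace))
  fit_res <- NULL
  if (fit != "none") {
    if (length(x) < 2) {
      warning("single condition: dose-response fit refused (need multiple ",
              "ligand levels); returning points only")
    } else {
      fit_res <- switch(fit,
        hill = fit_hill(points),
        biphasic = fit_biphasic_hill(points))
    }
  }
  list(points = points, fit = fit_res, per_trace = per_trace,
       provenance = list(unitary = unitary, n_levels = n_levels,
                         dead_time = dead_time, model = fit))
}

#' Read / write dose-response points as CSV
#'
#' Columns: x, y, and optionally y_err, n.
#'
#' @param points data.frame of dose-response points.
#' @param path file path.
#' @return \code{read_dose_response_csv} returns the points data.frame.
#' @export
write_dose_response_csv <- function(points, path) {
  stopifnot(all(c("x", "y") %in% names(points)))
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x", "y") %in% names(d)))
  d
}
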