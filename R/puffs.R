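#' Synthetic linescan generator specification
#'
#' Parameters of the synthetic confocal linescan: sparse Ca2+ puffs on a
#' noisy baseline. Each puff follows a linear rise over \code{rise_time} to
#' \code{amplitude} (in dF/F0 units) followed by single-exponential decay
#' with \code{decay_tau}, spread spatially as a Gaussian of SD
#' \code{spatial_sigma}. Event times are homogeneous-Poisson per cell with
#' positions uniform within the cell's span.
#'
#' @param rate events per second per cell.
#' @param amplitude peak dF/F0 of an event.
#' @param rise_time baseline-to-peak ramp duration, s.
#' @param decay_tau exponential decay time constant, s.
#' @param spatial_sigma Gaussian spatial SD, um.
#' @param baseline_f0 baseline fluorescence, arbitrary units.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param duration scan duration, s.
#' @param dt line period, s (default 0.1; the acquisition line period is a
#'   configuration value, never hard-coded downstream).
#' @param dx pixel size, um (default 0.63).
#' @param seed optional integer seed.
#' @return object of class \code{puff_gen_spec}.
#' @export
puff_gen_spec <- function(rate, amplitude, rise_time, decay_tau,
                          spatial_sigma = 1, baseline_f0 = 100,
                          noise_sd = 5, duration = 120, dt = 0.1,
                          dx = 0.63, seed = NULL) {
  stopifnot(rate >= 0, amplitude > 0, rise_time > 0, decay_tau > 0,
            spatial_sigma > 0, baseline_f0 > 0, noise_sd >= 0,
            duration > 0, dt > 0, dx > 0)
  structure(list(rate = rate, amplitude = amplitude, rise_time = rise_time,
                 decay_tau = decay_tau, spatial_sigma = spatial_sigma,
                 baseline_f0 = baseline_f0, noise_sd = noise_sd,
                 duration = duration, dt = dt, dx = dx, seed = seed),
            class = "puff_gen_spec")
}

#' Rise/decay pair hitting a target full duration at half maximum
#'
#' For the ramp-plus-exponential event shape, FDHM = rise/2 + tau ln 2.
#' This helper splits a target FDHM equally between the two limbs:
#' rise = FDHM and tau = FDHM / (2 ln 2).
#'
#' @param fdhm target full duration at half maximum, s.
#' @return list with \code{rise_time} and \code{decay_tau} (s).
#' @export
#' @examples
#' p <- puff_shape_for_fdhm(0.68)
#' 0.5 * p$rise_time + p$decay_tau * log(2)  # 0.68
puff_shape_for_fdhm <- function(fdhm) {
  stopifnot(fdhm > 0)
  list(rise_time = fdhm, decay_tau = fdhm / (2 * log(2)))
}

new_linescan_image <- function(pixels, dx, dt, cells) {
  structure(list(pixels = pixels, dx = dx, dt = dt, cells = cells),
            class = "linescan_image")
}

#' Synthesize a linescan image with ground-truth puffs
#'
#' Builds a space x time fluorescence matrix: baseline F0 plus Poisson-timed
#' ramp/exponential events with Gaussian spatial profiles, plus additive
#' Gaussian noise. Event peak times are snapped to the line grid and
#' positions to pixel centres so the noise-free peak-pixel dF/F0 equals the
#' specified amplitude exactly.
#'
#' @param spec \code{\link{puff_gen_spec}}.
#' @param n_cells number of cell regions stacked along the spatial axis.
#' @param cell_span_um spatial extent of each cell, um.
#' @return list with \code{image} (\code{linescan_image}: pixels matrix
#'   [space x time], dx, dt, cell ROI table) and \code{truth} (data.frame of
#'   ground-truth events: cell_id, position_um, t_onset, t_peak, amplitude).
#' @export
synthesize_linescan <- function(spec, n_cells = 1, cell_span_um = 10) {
  stopifnot(inherits(spec, "puff_gen_spec"), n_cells >= 1)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  cell_px <- max(4L, round(cell_span_um / spec$dx))
  n_space <- n_cells * cell_px
  n_time <- round(spec$duration / spec$dt)
  stopifnot(n_time >= 3)
  img <- matrix(spec$baseline_f0, nrow = n_space, ncol = n_time)
  cells <- data.frame(cell_id = seq_len(n_cells),
                      row_start = (seq_len(n_cells) - 1) * cell_px + 1,
                      row_end = seq_len(n_cells) * cell_px)
  truth <- list()
  sig_px <- spec$spatial_sigma / spec$dx
  for (ci in seq_len(n_cells)) {
    k <- stats::rpois(1, spec$rate * spec$duration)
    if (k == 0) next
    t_raw <- stats::runif(k, 0, spec$duration)
    pos_px <- sample(seq_len(cell_px), k, replace = TRUE)
    for (e in seq_len(k)) {
      # snap the peak to the sampling grid (keeps the sampled maximum exact)
      t_peak <- round((t_raw[e] + spec$rise_time) / spec$dt) * spec$dt
      t_on <- t_peak - spec$rise_time
      row0 <- cells$row_start[ci] + pos_px[e] - 1
      tt <- (seq_len(n_time) - 1) * spec$dt
      prof <- numeric(n_time)
      up <- tt >= t_on & tt <= t_peak
      prof[up] <- (tt[up] - t_on) / spec$rise_time
      dn <- tt > t_peak
      prof[dn] <- exp(-(tt[dn] - t_peak) / spec$decay_tau)
      rows <- max(1, row0 - ceiling(4 * sig_px)):min(n_space, row0 + ceiling(4 * sig_px))
      spatial <- exp(-0.5 * ((rows - row0) / sig_px)^2)
      img[rows, ] <- img[rows, ] +
        spec$baseline_f0 * spec$amplitude * outer(spatial, prof)
      truth[[length(truth) + 1]] <- data.frame(
        cell_id = ci, position_um = (row0 - 0.5) * spec$dx,
        t_onset = t_on, t_peak = t_peak, amplitude = spec$amplitude)
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                        nrow = n_space)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cell_id = integer(0), position_um = numeric(0),
               t_onset = numeric(0), t_peak = numeric(0),
               amplitude = numeric(0))
  list(image = new_linescan_image(img, spec$dx, spec$dt, cells),
       truth = truth)
}

# 8-connected component labels of a logical mask (matrix); returns an
# integer vector of component ids for the TRUE pixels (in mask index order)
label_components <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer(0))
  nr <- nrow(mask)
  pos <- match(idx, idx)  # identity; membership lookup done via match below
  edges <- list()
  # neighbor offsets covering half the 8-neighborhood (the rest are implied)
  row_i <- ((idx - 1) %% nr) + 1
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    di <- off[1]; dj <- off[2]
    nb <- idx + di + dj * nr
    valid <- row_i + di >= 1 & row_i + di <= nr &
      nb >= 1 & nb <= length(mask)
    m <- match(nb[valid], idx)
    ok <- !is.na(m)
    if (any(ok)) {
      edges[[length(edges) + 1]] <-
        cbind(which(valid)[ok], m[ok])
    }
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' Detect Ca2+ puffs in a linescan image
#'
#' Background mean and SD are estimated robustly over the whole image
#' (median and MAD; puffs are sparse). Pixels exceeding
#' mean + \code{k_sd} * SD are grouped by 8-connected spatiotemporal
#' connectivity. Components whose intensity profile shows multiple peaks
#' separated by deep valleys (below half of the smaller flanking peak, a
#' drop noise alone cannot produce at these thresholds) are split along the
#' valley, first in time and then in space, so that spatiotemporally
#' overlapping puffs are counted separately. Each resulting event is
#' measured at its peak pixel, whose time course (as dF/F0 against that
#' pixel's own temporal baseline, the lower quartile of its trace plus the
#' known quartile offset of the noise - an estimator unbiased under noise
#' and robust to event occupancy) feeds \code{\link{measure_kinetics}}.
#'
#' @param image \code{linescan_image}.
#' @param k_sd detection threshold in background SDs; the conventional
#'   working range is 5 to 6.5 (values outside it are allowed with a
#'   warning).
#' @param min_px minimum connected component size in pixels; smaller
#'   components are discarded as isolated noise crossings (a genuine puff
#'   covers tens of pixels at these thresholds).
#' @return data.frame of puff events: cell_id, position_um, t_peak_s,
#'   amplitude_dff, fdhm_s, ttp_s, rise_s, decay_s, right_censored.
#'   Kinetic fields are NA when an event is too truncated at the image
#'   border to measure.
#' @export
detect_puffs <- function(image, k_sd = 5.5, min_px = 4) {
  stopifnot(inherits(image, "linescan_image"))
  if (k_sd < 5 || k_sd > 6.5) {
    warning("k_sd = ", k_sd, " is outside the conventional 5-6.5 range")
  }
  px <- image$pixels
  if (ncol(px) < 9) stop("image too short for kinetic analysis", call. = FALSE)
  bg_mean <- stats::median(px)
  bg_sd <- stats::mad(px)
  mask <- px > bg_mean + k_sd * bg_sd
  idx <- which(mask)
  if (length(idx) == 0) return(empty_puff_table())
  memb <- label_components(mask)
  nr <- nrow(px)
  nt <- ncol(px)
  comps <- split(idx, memb)
  comps <- comps[lengths(comps) >= min_px]
  if (length(comps) == 0) return(empty_puff_table())
  # split merged components along deep valleys (time, then space)
  thr_lvl <- bg_mean + k_sd * bg_sd
  comps <- unlist(lapply(comps, function(ci) {
    parts <- split_component(ci, px, nr, thr_lvl, by_row = FALSE)
    unlist(lapply(parts, split_component, px = px, nr = nr,
                  floor_lvl = thr_lvl, by_row = TRUE), recursive = FALSE)
  }), recursive = FALSE)
  out <- vector("list", length(comps))
  for (comp in seq_along(comps)) {
    ci <- comps[[comp]]
    pk <- ci[which.max(px[ci])]
    row0 <- ((pk - 1) %% nr) + 1
    col0 <- ((pk - 1) %/% nr) + 1
    # average the peak row with its spatial neighbours: for a spatially
    # separable event this rescales the amplitude but leaves every relative
    # kinetic measurement unchanged, while cutting the profile noise
    rows <- max(1, row0 - 1):min(nr, row0 + 1)
    f <- colMeans(px[rows, , drop = FALSE])
    # lower quartile + the noise's known quartile offset: unbiased under
    # Gaussian noise, robust to elevated (event) samples in the trace
    sd_f <- bg_sd / sqrt(length(rows))
    f0 <- as.numeric(stats::quantile(f, 0.25)) + stats::qnorm(0.75) * sd_f
    dff <- (f - f0) / f0
    cols <- ((ci - 1) %/% nr) + 1
    win <- event_window(dff, col0, range(cols))
    # border-truncated events can leave sub-minimal windows; pad, then give
    # up on kinetics (not on the detection) if still degenerate
    if (diff(win) < 4) win <- c(max(1, win[1] - 2), min(nt, win[2] + 2))
    kin <- tryCatch(
      measure_kinetics(dff[win[1]:win[2]], image$dt,
                       peak_index = col0 - win[1] + 1),
      error = function(e) list(amplitude = dff[col0], fdhm = NA_real_,
                               time_to_peak = NA_real_, rise_20_80 = NA_real_,
                               decay_80_20 = NA_real_, right_censored = TRUE))
    cell <- image$cells$cell_id[row0 >= image$cells$row_start &
                                row0 <= image$cells$row_end]
    out[[comp]] <- data.frame(
      cell_id = if (length(cell)) cell[1] else NA_integer_,
      position_um = (row0 - 0.5) * image$dx,
      t_peak_s = (col0 - 1) * image$dt,
      amplitude_dff = kin$amplitude,
      fdhm_s = kin$fdhm, ttp_s = kin$time_to_peak,
      rise_s = kin$rise_20_80, decay_s = kin$decay_80_20,
      right_censored = kin$right_censored)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_puff_table())
  do.call(rbind, out)
}

empty_puff_table <- function() {
  data.frame(cell_id = integer(0), position_um = numeric(0),
             t_peak_s = numeric(0), amplitude_dff = numeric(0),
             fdhm_s = numeric(0), ttp_s = numeric(0), rise_s = numeric(0),
             decay_s = numeric(0), right_censored = logical(0))
}

# Split a connected component along valleys of its max-intensity projection
# (over columns when by_row = FALSE, rows when TRUE). Since every component
# pixel already exceeds the detection threshold, the threshold - not the
# background - is the reference floor: two peaks are distinct events when
# the (smoothed) valley between them retraces more than half of the smaller
# peak's elevation above the threshold. Smoothing the projection keeps
# single noisy events from producing spurious valleys. Returns a list of
# pixel-index vectors.
split_component <- function(ci, px, nr, floor_lvl, by_row) {
  coord <- if (by_row) ((ci - 1) %% nr) + 1 else ((ci - 1) %/% nr) + 1
  u <- min(coord):max(coord)
  if (length(u) < 5) return(list(ci))
  prof <- vapply(u, function(k) {
    v <- px[ci[coord == k]]
    if (length(v)) max(v) else floor_lvl
  }, numeric(1))
  n <- length(prof)
  prof <- as.numeric(stats::filter(c(prof[1], prof, prof[n]), rep(1 / 3, 3),
                                   sides = 2))[2:(n + 1)]
  is_max <- c(TRUE, diff(prof) > 0) & c(diff(prof) < 0, TRUE)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(list(ci))
  accepted <- peaks[which.max(prof[peaks])]
  for (p in peaks[order(prof[peaks], decreasing = TRUE)][-1]) {
    ok <- TRUE
    for (a in accepted) {
      rng <- if (p < a) p:a else a:p
      valley <- min(prof[rng])
      if (valley - floor_lvl >= 0.5 * (min(prof[p], prof[a]) - floor_lvl)) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  if (length(accepted) < 2) return(list(ci))
  cuts <- vapply(seq_len(length(accepted) - 1), function(i) {
    rng <- accepted[i]:accepted[i + 1]
    rng[which.min(prof[rng])]
  }, integer(1))
  seg_of <- findInterval(match(coord, u), cuts + 0.5) + 1
  parts <- split(ci, seg_of)
  unname(parts[lengths(parts) > 0])
}

# widen the component's column range until the profile has dropped to 10%
# of its peak (or the image edge), so all threshold crossings are inside
event_window <- function(dff, peak_col, col_range) {
  floor_level <- 0.1 * dff[peak_col]
  lo <- col_range[1]
  while (lo > 1 && dff[lo] > floor_level) lo <- lo - 1
  hi <- col_range[2]
  while (hi < length(dff) && dff[hi] > floor_level) hi <- hi + 1
  c(lo, hi)
}

# linear-interpolated crossing time (index units) of `thr` between samples
# i and i+1
interp_cross <- function(y, i, thr) {
  i + (thr - y[i]) / (y[i + 1] - y[i])
}

#' Kinetic measurements of a single event time course
#'
#' Measures, on a baseline-subtracted dF/F0 profile with a single dominant
#' maximum: full duration at half maximum (dwell above 50% of peak), time to
#' peak (last baseline crossing to the maximum), 20-80% rise time on the
#' ascending limb and 80-20% decay time on the descending limb.
#'
#' The durations are dwell statistics and are estimated by sample counting
#' within the relevant amplitude band: for a profile crossing a threshold
#' under symmetric noise, the expected number of samples beyond the
#' threshold equals the noise-free dwell, so counting is unbiased even when
#' the noise exceeds the per-sample slope (where interpolated
#' first-crossing search systematically stops early). The peak amplitude is
#' taken from a 3-point parabola on the raw samples centred on the argmax
#' of a 3-point-smoothed copy, which avoids conditioning the amplitude on a
#' selected noise maximum. Reported durations are floored at one sample
#' interval.
#'
#' @param profile numeric dF/F0 time course (baseline at 0).
#' @param dt sample interval, s.
#' @param baseline baseline level (default 0).
#' @param peak_index optional index of the event peak; used as a fallback
#'   anchor when the smoothed argmax lies far outside the expected bump.
#' @return list with \code{amplitude}, \code{fdhm}, \code{time_to_peak},
#'   \code{rise_20_80}, \code{decay_80_20} (s) and \code{right_censored}
#'   (TRUE when the profile never returns below 20% of peak; decay - and
#'   FDHM, when the tail stays above 50% - are then NA).
#' @export
#' @examples
#' t <- seq(0, 6, 0.05)
#' prof <- ifelse(t < 1, t / 1, exp(-(t - 1) / 0.5))
#' measure_kinetics(prof, 0.05)  # rise 0.6, decay 0.5*log(4), fdhm 0.5+0.5*log(2)
measure_kinetics <- function(profile, dt, baseline = 0, peak_index = NULL) {
  y <- as.numeric(profile) - baseline
  n <- length(y)
  stopifnot(n >= 3, dt > 0)
  # peak located on a lightly smoothed copy so the centre sample of the
  # parabola below is not a selected noise maximum
  ys <- as.numeric(stats::filter(c(y[1], y, y[n]), rep(1 / 3, 3),
                                 sides = 2))[2:(n + 1)]
  cand <- which(ys == max(ys))
  ipk <- cand[which.max(y[cand])]
  if (!is.null(peak_index) && abs(ipk - peak_index) > max(3, n %/% 4)) {
    ipk <- peak_index  # smoothed max belongs to a different bump
  }
  ipk <- max(2L, min(n - 1L, ipk))
  if (y[ipk] <= 0) stop("profile has no positive excursion", call. = FALSE)
  # parabola on raw samples around the (smoothed-selected) peak; centring on
  # the smoothed argmax keeps the raw centre sample unconditioned, so the
  # vertex is not inflated the way a raw running maximum would be
  d2 <- y[ipk - 1] - 2 * y[ipk] + y[ipk + 1]
  delta <- if (d2 < 0) 0.5 * (y[ipk - 1] - y[ipk + 1]) / d2 else Inf
  amp <- if (is.finite(delta) && abs(delta) <= 1) {
    y[ipk] - 0.25 * (y[ipk - 1] - y[ipk + 1]) * delta
  } else {
    # no local curvature (ramp corner, plateau): take the raw local maximum
    max(y[(ipk - 1):(ipk + 1)])
  }
  thr <- amp * c(0.2, 0.5, 0.8)

  # counting bounds: stop at the first run of `gap` consecutive sub-20%
  # samples on each side of the peak, so neighbouring events in the window
  # never contribute to this event's counts
  gap <- 5L
  above20 <- y >= thr[1]
  ub <- n; run <- 0L
  for (j in ipk:n) {
    run <- if (above20[j]) 0L else run + 1L
    if (run >= gap) { ub <- j; break }
  }
  lb <- 1L; run <- 0L
  for (j in ipk:1) {
    run <- if (above20[j]) 0L else run + 1L
    if (run >= gap) { lb <- j; break }
  }
  pre <- lb:ipk              # ascending limb including the peak sample
  post <- ipk:ub             # descending limb including the peak sample
  # samples exactly at a threshold count half: exact in noise-free
  # geometry, measure-zero (hence irrelevant) under noise
  band_count <- function(v, lo, hi) {
    sum(v > lo & v < hi) + 0.5 * sum(v == lo | v == hi)
  }
  count_dur <- function(k) max(k, 1) * dt
  right_censored <- ub == n && above20[n]
  fdhm <- if (ub == n && y[n] >= thr[2]) NA_real_ else
    count_dur(band_count(y[lb:ub], thr[2], Inf))
  rise <- count_dur(band_count(y[pre], thr[1], thr[3]))
  decay <- if (right_censored) NA_real_ else
    count_dur(band_count(y[post], thr[1], thr[3]))
  # time to peak: from the last pre-peak baseline crossing (interpolated)
  i <- ipk
  while (i > 1 && y[i - 1] > 0) i <- i - 1
  base_cross <- if (i == 1) 1 else interp_cross(y, i - 1, 0)
  list(amplitude = amp,
       fdhm = fdhm,
       time_to_peak = max(ipk - base_cross, 1) * dt,
       rise_20_80 = rise,
       decay_80_20 = decay,
       right_censored = right_censored)
}

#' Puff frequency per cell
#'
#' @param events puff event table (or anything with one row per event).
#' @param n_cells number of cells observed.
#' @param duration observation time per cell, s.
#' @return events per cell per second, Hz.
#' @export
#' @examples
#' puff_frequency(data.frame(id = 1:12), 1, 120)  # 0.1 Hz
puff_frequency <- function(events, n_cells, duration) {
  stopifnot(n_cells >= 1, duration > 0)
  n <- if (is.data.frame(events)) nrow(events) else length(events)
  n / (n_cells * duration)
}

#' Read / write linescan images as single-channel TIFF
#'
#' Images are stored as 32-bit float TIFF scaled to [0, 1] by a recorded
#' factor when needed; \code{dx}/\code{dt} are supplied by the caller on
#' read (TIFF carries no calibrated axes here).
#'
#' @param image \code{linescan_image}.
#' @param path file path.
#' @param dx,dt pixel size (um) and line period (s) to attach on read.
#' @param n_cells split the spatial axis into this many equal cell ROIs.
#' @return \code{read_linescan_tiff} returns a \code{linescan_image}.
#' @export
write_linescan_tiff <- function(image, path) {
  stopifnot(inherits(image, "linescan_image"))
  px <- image$pixels
  scale <- max(px, 1)
  tiff::writeTIFF(px / scale, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_linescan_tiff
#' @export
read_linescan_tiff <- function(path, dx = 0.63, dt = 0.1, n_cells = 1) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  cell_px <- nrow(px) %/% n_cells
  cells <- data.frame(cell_id = seq_len(n_cells),
                      row_start = (seq_len(n_cells) - 1) * cell_px + 1,
                      row_end = seq_len(n_cells) * cell_px)
  new_linescan_image(px, dx, dt, cells)
}
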