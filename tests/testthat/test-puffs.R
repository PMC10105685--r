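default_spec <- function(...) {
  args <- list(rate = 0.05, amplitude = 0.5, rise_time = 0.68,
               decay_tau = 0.49, baseline_f0 = 100, noise_sd = 5,
               duration = 120, dt = 0.1, dx = 0.63, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(puff_gen_spec, args)
}

test_that("empty and noise-only linescans produce no detections", {
  syn <- synthesize_linescan(default_spec(rate = 1e-9, seed = 2), n_cells = 2)
  expect_equal(nrow(syn$truth), 0)
  expect_equal(nrow(detect_puffs(syn$image, 5.5)), 0)
})

test_that("noise-free single event peaks at exactly the specified amplitude", {
  spec <- default_spec(rate = 1 / 120, noise_sd = 0, seed = 3)
  repeat {  # draw until exactly one event lands
    syn <- synthesize_linescan(spec, n_cells = 1)
    if (nrow(syn$truth) == 1) break
    spec$seed <- spec$seed + 1
  }
  peak <- max(syn$image$pixels)
  expect_equal((peak - 100) / 100, 0.5, tolerance = 1e-9)
})

test_that("event counts follow the Poisson law of the generator rate", {
  spec <- default_spec(rate = 40 / (120 * 4), seed = 4)  # expect 40 events
  syn <- synthesize_linescan(spec, n_cells = 4)
  n <- nrow(syn$truth)
  expect_true(n >= qpois(0.005, 40) && n <= qpois(0.995, 40))
})

test_that("detector achieves full recall and precision on clear events", {
  # amplitude 10x background SD, well-separated events
  spec <- default_spec(rate = 0.02, seed = 5)
  syn <- synthesize_linescan(spec, n_cells = 6)
  ev <- detect_puffs(syn$image, 5.5)
  # match each truth event to a detection within 2 s and 3 um
  matched <- vapply(seq_len(nrow(syn$truth)), function(i) {
    any(abs(ev$t_peak_s - syn$truth$t_peak[i]) < 2 &
        abs(ev$position_um - syn$truth$position_um[i]) < 3)
  }, logical(1))
  expect_true(all(matched))
  expect_equal(nrow(ev), nrow(syn$truth))
})

test_that("sub-threshold events are missed by construction", {
  # peak at ~2.5 background SD, below a 5.5 SD threshold
  spec <- default_spec(rate = 0.02, amplitude = 0.125, seed = 6)
  syn <- synthesize_linescan(spec, n_cells = 2)
  expect_gt(nrow(syn$truth), 0)
  ev <- detect_puffs(syn$image, 5.5)
  expect_equal(nrow(ev), 0)
})

test_that("well-separated event pairs are never merged", {
  # two noise-free events placed far apart in one cell
  spec <- default_spec(rate = 1e-9, noise_sd = 0, seed = 7, duration = 60)
  syn <- synthesize_linescan(spec, n_cells = 1)
  img <- syn$image
  n_time <- ncol(img$pixels)
  add_event <- function(img, row0, col0, spec) {
    tt <- seq_len(n_time)
    prof <- numeric(n_time)
    up <- tt >= col0 - spec$rise_time / spec$dt & tt <= col0
    prof[up] <- (tt[up] - (col0 - spec$rise_time / spec$dt)) /
      (spec$rise_time / spec$dt)
    dn <- tt > col0
    prof[dn] <- exp(-(tt[dn] - col0) * spec$dt / spec$decay_tau)
    rows <- pmax(1, row0 - 6):pmin(nrow(img$pixels), row0 + 6)
    spatial <- exp(-0.5 * ((rows - row0) * spec$dx / spec$spatial_sigma)^2)
    img$pixels[rows, ] <- img$pixels[rows, ] +
      spec$baseline_f0 * spec$amplitude * outer(spatial, prof)
    img
  }
  img <- add_event(img, 4, 100, spec)
  img <- add_event(img, 12, 400, spec)   # > 3 sigma apart, > 5 FDHM apart
  img$pixels <- img$pixels + matrix(rnorm(length(img$pixels), 0, 5),
                                    nrow = nrow(img$pixels))
  ev <- detect_puffs(img, 5.5)
  expect_equal(nrow(ev), 2)
})

test_that("measure_kinetics satisfies the closed-form ramp/exp identities", {
  dt <- 0.01
  grid <- expand.grid(rise = c(0.3, 0.68, 1.5), tau = c(0.2, 0.49, 1.2))
  for (i in seq_len(nrow(grid))) {
    r <- grid$rise[i]; tau <- grid$tau[i]
    prof <- ramp_exp_profile(r, tau, dt)
    k <- measure_kinetics(prof, dt)
    expect_equal(k$rise_20_80, 0.6 * r, tolerance = dt / (0.6 * r))
    expect_equal(k$decay_80_20, tau * log(4), tolerance = dt / (tau * log(4)))
    expect_equal(k$fdhm, 0.5 * r + tau * log(2),
                 tolerance = dt / (0.5 * r + tau * log(2)))
    expect_equal(k$time_to_peak, r, tolerance = 2 * dt / r)
  }
})

test_that("measure_kinetics handles triangles, spikes and censored decays", {
  dt <- 0.05
  # symmetric triangle of base 2w: FDHM = w
  w <- 1
  t <- seq(0, 2 * w, dt)
  tri <- 1 - abs(t - w) / w
  expect_equal(measure_kinetics(tri, dt)$fdhm, w, tolerance = dt)
  # one-sample spike: durations floored at dt
  spike <- c(0, 0, 1, 0, 0)
  k <- measure_kinetics(spike, dt)
  expect_equal(k$fdhm, dt)
  expect_equal(k$rise_20_80, dt)
  # profile that never returns below 20 percent: right-censored
  cens <- c(0, 0.5, 1, 0.9, 0.85, 0.8)
  kc <- measure_kinetics(cens, dt)
  expect_true(kc$right_censored)
  expect_true(is.na(kc$fdhm))
})

test_that("puff_frequency normalizes per cell and per second", {
  expect_equal(puff_frequency(data.frame(), 4, 100), 0)
  expect_equal(puff_frequency(data.frame(i = 1:12), 1, 120), 0.1)
  expect_equal(puff_frequency(data.frame(i = 1:24), 2, 120), 0.1)
})

test_that("detected frequency is unbiased against the generator rate", {
  # aggregate over independent small scans
  rate <- 0.05
  counts <- 0
  cells_time <- 0
  for (s in 1:25) {
    syn <- synthesize_linescan(default_spec(rate = rate, duration = 60,
                                            seed = 100 + s), n_cells = 2)
    counts <- counts + nrow(detect_puffs(syn$image, 5.5))
    cells_time <- cells_time + 2 * 60
  }
  freq <- counts / cells_time
  se <- sqrt(rate / cells_time)  # Poisson SE
  expect_lt(abs(freq - rate), 3 * se)
})

test_that("linescan TIFF round-trips pixels within float precision", {
  syn <- synthesize_linescan(default_spec(rate = 0.02, seed = 8), n_cells = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_linescan_tiff(syn$image, path)
  back <- read_linescan_tiff(path, dx = 0.63, dt = 0.1, n_cells = 2)
  scale <- max(syn$image$pixels, 1)
  expect_equal(back$pixels * scale, syn$image$pixels, tolerance = 1e-5)
  expect_equal(dim(back$pixels), dim(syn$image$pixels))
})
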