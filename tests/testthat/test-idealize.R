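test_that("half-amplitude idealization resolves clean square pulses", {
  fs <- 20000
  # 5 ms pulse at the unitary level inside a 20 ms record
  x <- rep(0, 400)
  x[101:200] <- 7.44
  id <- idealize_trace(x, unitary = 7.44, sample_rate = fs)
  expect_equal(id$events$level, c(0L, 1L, 0L))
  expect_equal(id$events$duration[2], 0.005, tolerance = 1 / fs)
  # stacked pulse at twice the unitary level
  x2 <- x
  x2[121:180] <- 14.88
  id2 <- idealize_trace(x2, unitary = 7.44, n_levels = 2, sample_rate = fs)
  expect_equal(max(id2$events$level), 2L)
  # polarity mismatch warns
  expect_warning(idealize_trace(-x, unitary = 7.44, sample_rate = fs),
                 "polarity")
})

test_that("idealization recovers the generating train on clean traces", {
  cfg <- clean_config(20)
  cfg$seed <- 41
  ex <- simulate_experiment(list(ip3 = 2e-6), ip3r_params("wt_ip3"), 8e-3, cfg)
  id <- idealize_trace(ex$trace, unitary = 7.44)
  truth <- ex$trains[[1]]
  # boundary recovery within one sample for resolvable events
  got_open <- id$events[id$events$level == 1, ]
  true_open <- truth[truth$state == "open", ]
  expect_equal(nrow(got_open), nrow(true_open))
  expect_lt(max(abs(got_open$start - true_open$start)), 1 / 20000 + 1e-12)
  expect_lt(max(abs(got_open$duration - true_open$duration)), 2 / 20000)
  # Po error under 5 percent relative
  st <- suppressWarnings(channel_stats(id))
  expect_equal(st$npo, train_open_fraction(truth), tolerance = 0.05)
})

test_that("dead-time censoring removes brief events and merges flanks", {
  fs <- 1e5
  # 200 us opening between long closures: removed, closures merge
  x <- rep(0, 3000)
  x[1001:1020] <- 7.44
  id <- idealize_trace(x, unitary = 7.44, sample_rate = fs)
  cen <- apply_dead_time(id, 300e-6)
  expect_equal(nrow(cen$events), 1)
  expect_equal(cen$events$level, 0L)
  expect_equal(sum(cen$events$duration), sum(id$events$duration))
  # 500 us opening survives
  x[1001:1050] <- 7.44
  cen2 <- apply_dead_time(idealize_trace(x, unitary = 7.44, sample_rate = fs),
                          300e-6)
  expect_equal(cen2$events$level, c(0L, 1L, 0L))
})

test_that("dead-time censoring is idempotent, conservative and zero-safe", {
  cfg <- sim_config(duration = 10, seed = 43)
  ex <- simulate_experiment(list(ip3 = 1e-6), ip3r_params("wt_ip3"), 2e-3, cfg)
  id <- idealize_trace(ex$trace, unitary = 7.44)
  once <- apply_dead_time(id, 300e-6)
  twice <- apply_dead_time(once, 300e-6)
  expect_equal(once$events, twice$events)
  expect_identical(apply_dead_time(id, 0)$events, id$events)
  # conservation of record length through censoring
  expect_equal(sum(once$events$duration), sum(id$events$duration))
  expect_equal(sum(once$events$duration), 10)
  # never increases the event count; no short events remain
  expect_lte(nrow(once$events), nrow(id$events))
  expect_true(all(once$events$duration >= 300e-6))
})

test_that("channel counting from stacked openings and amplitude modes", {
  cfg1 <- sim_config(duration = 60, seed = 44)
  surface1 <- ligand_surface(0.3, ip3 = hill_params(0.3, 660e-9, 1.8))
  ex1 <- simulate_experiment(list(ip3 = 1), surface1, 8e-3, cfg1)
  id1 <- idealize_trace(ex1$trace, unitary = 7.44, n_levels = 3,
                        dead_time = 300e-6)
  expect_equal(estimate_n_channels(id1), 1L)

  cfg3 <- sim_config(n_channels = 3, duration = 60, seed = 45)
  surface3 <- ligand_surface(0.4, ip3 = hill_params(0.4, 660e-9, 1.8))
  ex3 <- simulate_experiment(list(ip3 = 1), surface3, 8e-3, cfg3)
  id3 <- idealize_trace(ex3$trace, unitary = 7.44, n_levels = 5,
                        dead_time = 300e-6)
  expect_equal(estimate_n_channels(id3), 3L)
  # amplitude histogram shows closed + 3 open levels
  expect_equal(amplitude_modes(ex3$trace, 7.44, min_height = 1e-4), 4)

  # all-closed record: count 0 with a warning
  x <- rep(0, 2000)
  id0 <- idealize_trace(x, unitary = 7.44, sample_rate = 2e4)
  expect_warning(n0 <- estimate_n_channels(id0), "indeterminate")
  expect_equal(n0, 0L)
})

test_that("channel_stats arithmetic on deterministic event sequences", {
  # alternating 10 ms open / 30 ms closed: npo exactly 0.25
  fs <- 1e5
  x <- rep(rep(c(0, 7.44), times = c(3000, 1000)), 10)
  id <- idealize_trace(x, unitary = 7.44, sample_rate = fs)
  st <- suppressWarnings(channel_stats(id))
  expect_equal(st$npo, 0.25, tolerance = 1e-3)
  expect_equal(st$mot, 0.010, tolerance = 1e-3)
  expect_equal(st$mct, 0.030, tolerance = 1e-3)
  # permanently open channel: npo 1, MCT undefined
  xo <- rep(7.44, 5000)
  ido <- idealize_trace(xo, unitary = 7.44, sample_rate = fs)
  expect_warning(sto <- channel_stats(ido, min_record_s = 0.01),
                 "no closed events")
  expect_equal(sto$npo, 1)
  expect_true(is.na(sto$mct))
  # empty idealization errors; short record warns
  expect_warning(channel_stats(id), "shorter")
})

test_that("dwell-fit mean matches the generating mean within 3 SE", {
  set.seed(46)
  d <- rexp(5000, 1 / 0.010)
  f <- fit_dwell_exp(d)
  se <- mean(d) / sqrt(5000)
  expect_lt(abs(f$mean - 0.010), 3 * se)
})

test_that("exponential-mixture LRT distinguishes one from two components", {
  set.seed(47)
  one <- rexp(3000, 100)
  f1 <- fit_dwell_exp(one)
  expect_equal(f1$n_components, 1L)
  expect_equal(f1$rates[1], 1 / mean(one))
  two <- c(rexp(1500, 1000), rexp(1500, 20))
  f2 <- fit_dwell_exp(two)
  expect_equal(f2$n_components, 2L)
  expect_equal(f2$mean, mean(two), tolerance = 0.1)
  expect_gt(f2$rates[1], f2$rates[2])
})

test_that("npo from idealized noisy records tracks n*Po within 5 percent", {
  cfg <- sim_config(duration = 240, seed = 48)
  surface <- ligand_surface(0.2, ip3 = hill_params(0.2, 660e-9, 1.8))
  ex <- simulate_experiment(list(ip3 = 1), surface, 8e-3, cfg)
  id <- idealize_trace(ex$trace, unitary = 7.44, dead_time = 300e-6)
  st <- channel_stats(id)
  expect_equal(st$npo, 0.2, tolerance = 0.05)
  expect_equal(st$record_length, 240)
})

test_that("idealization TSV round-trips the event table", {
  fs <- 2e4
  x <- rep(0, 1000)
  x[301:500] <- 7.44
  id <- idealize_trace(x, unitary = 7.44, sample_rate = fs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_idealization_tsv(id, path)
  back <- read_idealization_tsv(path)
  expect_equal(back$events$level, id$events$level)
  expect_equal(back$events$duration, id$events$duration)
})
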