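# shared fixtures built in code

egta_1mm <- function() buffer_system(list(chelator_spec("egta", 1e-3)))

# independent bisection oracle for the Ca2+ conservation equation
bisect_free_ca <- function(totals, kds, total_ca, iters = 200) {
  f <- function(c) c + sum(totals * c / (c + kds)) - total_ca
  lo <- 0; hi <- total_ca
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# noise-free, unfiltered rendering config for oracle-equivalence tests
clean_config <- function(duration, em = 30, n_channels = 1) {
  sim_config(n_channels = n_channels, duration = duration, em = em,
             filter_corner = 0, noise_sd = 0)
}

# build an event train data.frame directly from dwell vectors
manual_train <- function(states, durations) {
  out <- data.frame(state = states,
                    start = c(0, cumsum(durations))[seq_along(durations)],
                    duration = durations, stringsAsFactors = FALSE)
  class(out) <- c("event_train", "data.frame")
  out
}

# fraction of record open in a train
train_open_fraction <- function(tr) {
  sum(tr$duration[tr$state == "open"]) / sum(tr$duration)
}

# ramp + exponential event profile sampled at dt
ramp_exp_profile <- function(rise, tau, dt, t_end = rise + 10 * tau,
                             amplitude = 1) {
  t <- seq(0, t_end, by = dt)
  amplitude * ifelse(t <= rise, t / rise, exp(-(t - rise) / tau))
}
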