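# shared fixtures, generated once per test run

# small behavioural session reused across tests
.cache <- new.env(parent = emptyenv())

test_session <- function() {
  if (is.null(.cache$session)) {
    .cache$session <- simulate_session(observer_spec(), n_subjects = 4,
                                       trials_per_cell = 30, seed = 101)
  }
  .cache$session
}

# slow, independent Wiener density: pure-R large-time series with a fixed,
# generous number of terms (valid away from t - t0 ~ 0); used as the
# double-implementation oracle for the compiled density
r_wiener_density <- function(t, a, v, z, t0, bound = "upper", K = 200) {
  tt <- t - t0
  if (tt <= 0) return(0)
  if (bound == "upper") { v <- -v; z <- 1 - z }
  tau <- tt / a^2
  k <- seq_len(K)
  f <- pi * sum(k * exp(-k^2 * pi^2 * tau / 2) * sin(k * pi * z))
  f / a^2 * exp(-v * a * z - v^2 * tt / 2)
}

# tiny epoch study used by the decoding tests
test_epoch_study <- function(noise_scale = 0.5, n_channels = 24,
                             trials_per_cell = 16, seed = 201) {
  key <- paste("epochs", noise_scale, n_channels, trials_per_cell, seed,
               sep = "_")
  if (is.null(.cache[[key]])) {
    tr <- simulate_session(observer_spec(), n_subjects = 1,
                           trials_per_cell = trials_per_cell,
                           confidence_format = "binary", seed = seed)
    truth <- epoch_ground_truth(n_channels = n_channels,
                                noise_scale = noise_scale)
    .cache[[key]] <- simulate_epochs(tr, truth, seed = seed + 1,
                                     times_ms = seq(0, 3000, by = 10),
                                     post_onset_ms = 1500)
  }
  .cache[[key]]
}
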