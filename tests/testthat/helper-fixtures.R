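# Shared fixtures, built in code.  Heavier objects are created lazily and
# cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# coarse frequency grid for cheap inversions in module tests
coarse_grid <- function() frequency_grid(8, 48, by = 4)

# small synthetic dataset + converged fit on a coarse grid
fixture_fit <- function() {
  fixture("fit_small", function() {
    truth <- true_trajectories(amplitudes = c(intrinsic1 = 2))
    ds <- generate_dataset(truth, snr = 4, seed = 42, grid = coarse_grid())
    fit <- fit_cmc_csd(ds$data, model_spec(changes = "intrinsic1"),
                       settings = inversion_settings(max_iter = 32))
    list(truth = truth, ds = ds, fit = fit)
  })
}

# sine-wave multichannel recording
sine_recording <- function(freqs = c(10, 10), fs = 256, dur = 4,
                           amp = 50, phase = c(0, 0)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- t(sapply(seq_along(freqs), function(i)
    amp * sin(2 * pi * freqs[i] * t + phase[i])))
  recording(x, fs, paste0("ch", seq_along(freqs)))
}

random_hermitian_stack <- function(nc = 2, nf = 5, nw = 3) {
  arr <- array(0 + 0i, c(nc, nc, nf, nw))
  for (w in seq_len(nw)) for (f in seq_len(nf)) {
    M <- matrix(complex(real = rnorm(nc * nc), imaginary = rnorm(nc * nc)),
                nc, nc)
    arr[, , f, w] <- M %*% Conj(t(M))   # Hermitian PSD
  }
  arr
}
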