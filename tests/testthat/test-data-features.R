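# Recordings, montage, filtering, windowing and cross-spectral estimation.

test_that("text recordings round-trip with their sampling rate", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 512), 4), 256,
                   c("LH4", "LH5", "LH6", "LH7"))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$rate, 256)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_error(read_recording(tempfile()), "not found")
})

test_that("EDF files round-trip through the reader", {
  rec <- sine_recording(c(10, 25), fs = 256, dur = 3)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_equal(back$rate, 256)
  expect_equal(back$labels, c("ch1", "ch2"))
  expect_equal(ncol(back$samples), 3 * 256)
  # 16-bit quantization: near-perfect correlation, small absolute error
  expect_gt(cor(back$samples[1, ], rec$samples[1, 1:768]), 0.999999)
  expect_lt(max(abs(back$samples - rec$samples[, 1:768])), 0.01)
})

test_that("truncated EDF files fail with the byte offset in the error", {
  rec <- sine_recording(c(10, 25), fs = 256, dur = 2)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  full <- readBin(path, "raw", file.info(path)$size)
  short <- tempfile(fileext = ".edf")
  writeBin(full[1:600], short)
  expect_error(read_edf(short), "byte offset")
  writeBin(full[1:100], short)
  expect_error(read_edf(short), "byte offset")
})

test_that("bipolar montage rejects common-mode signals and labels pairs", {
  set.seed(2)
  x <- matrix(rnorm(4 * 256), 4)
  rec <- recording(x, 256, c("LH4", "LH5", "LH6", "LH7"))
  out <- bipolar_montage(rec, list(c("LH4", "LH5"), c("LH6", "LH7")))
  expect_equal(out$labels, c("LH4-LH5", "LH6-LH7"))
  expect_equal(nrow(out$samples), 2)

  same <- bipolar_montage(rec, list(c("LH4", "LH4")))
  expect_equal(max(abs(same$samples)), 0)

  shifted <- recording(x + 13.7, 256, rec$labels)
  out2 <- bipolar_montage(shifted, list(c("LH4", "LH5"), c("LH6", "LH7")))
  expect_equal(out2$samples, out$samples, tolerance = 1e-12)

  expect_error(bipolar_montage(rec, list(c("LH4", "XX"))), "unknown channel")
})

test_that("zero-phase band-pass attenuates out-of-band and keeps in-band", {
  fs <- 256
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  hi <- recording(rbind(sin(2 * pi * 100 * t)), fs, "hi")
  lo <- recording(rbind(sin(2 * pi * 10 * t)), fs, "lo")
  dc <- recording(rbind(rep(1, length(t))), fs, "dc")
  mid <- function(x) x[, seq(fs, length(t) - fs)]  # avoid filter edges
  pw <- function(r) mean(mid(r$samples)^2)
  expect_lt(pw(bandpass(hi, 0.5, 48)) / pw(hi), 0.01)
  amp_ratio <- sqrt(pw(bandpass(lo, 0.5, 48)) / pw(lo))
  expect_equal(amp_ratio, 1, tolerance = 0.05)
  expect_lt(pw(bandpass(dc, 0.5, 48)) / pw(dc), 0.001)
  expect_error(bandpass(lo, 0.5, 200), "Nyquist")
})

test_that("window partition reproduces the 9 + 9 layout and its geometry", {
  w <- segment_windows(10, 2, 0.5)
  expect_equal(nrow(w), 9)
  expect_equal(w$start, 0:8)
  expect_equal(unique(w$end - w$start), 2)

  expect_equal(nrow(segment_windows(10, 10, 0)), 1)

  two <- rbind(segment_windows(10, 2, 0.5), segment_windows(10, 2, 0.5))
  expect_equal(nrow(two), 18)

  ep <- epoch_windows(onset = 30, pre = 10, post = 10)
  expect_equal(nrow(ep), 18)
  expect_equal(sum(ep$segment == "pre"), 9)
  expect_equal(ep$start[10], 30)

  # property: equal lengths, constant stride of len * (1 - overlap)
  for (ov in c(0, 0.25, 0.5, 0.75)) {
    ww <- segment_windows(12, 2, ov)
    expect_equal(unique(round(ww$end - ww$start, 9)), 2)
    if (nrow(ww) > 1)
      expect_equal(unique(round(diff(ww$start), 9)), 2 * (1 - ov))
  }
  expect_error(segment_windows(1, 2, 0.5), "infeasible")
  expect_error(segment_windows(10, 2, 1), "overlap")
})

test_that("duplicated channels give unit coherence at every frequency", {
  set.seed(3)
  x <- rnorm(512)
  rec <- recording(rbind(x, x), 256, c("a", "b"))
  est <- estimate_csd(rec, data.frame(start = 0, end = 2),
                      method = "multitaper")
  G <- est$csd[, , , 1]
  coh <- abs(G[1, 2, ])^2 / (Re(G[1, 1, ]) * Re(G[2, 2, ]))
  expect_equal(coh, rep(1, length(est$freq)), tolerance = 1e-9)
})

test_that("independent white noise gives flat spectra and small coherence", {
  set.seed(4)
  fs <- 256
  x <- matrix(rnorm(2 * 60 * fs), 2)
  rec <- recording(x, fs, c("a", "b"))
  est <- estimate_csd(rec, data.frame(start = 0, end = 60),
                      method = "multitaper", n_tapers = 64)
  auto <- Re(est$csd[1, 1, , 1])
  # white noise of unit variance has one-sided density 2/fs
  expect_equal(mean(auto), 2 / fs, tolerance = 0.1)
  expect_lt(max(auto) / min(auto), 2)
  coh <- abs(est$csd[1, 2, , 1])^2 / (Re(est$csd[1, 1, , 1]) *
                                        Re(est$csd[2, 2, , 1]))
  expect_lt(mean(coh), 0.1)
})

test_that("cross-spectral phase reflects a known time lag", {
  fs <- 400
  lag <- 0.025
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  set.seed(5)
  x1 <- sin(2 * pi * 10 * t) + 0.05 * rnorm(length(t))
  x2 <- sin(2 * pi * 10 * (t - lag)) + 0.05 * rnorm(length(t))
  rec <- recording(rbind(x1, x2), fs, c("a", "b"))
  est <- estimate_csd(rec, data.frame(start = 0, end = 10),
                      grid = 8:12, method = "multitaper", n_tapers = 16)
  ph <- Arg(est$csd[1, 2, 3, 1])       # 10 Hz bin
  expect_equal(ph, 2 * pi * 10 * lag, tolerance = 0.02)
})

test_that("VAR and multitaper estimators agree on smooth spectra", {
  p <- cmc_parameters()
  sim <- cmc_integrate(p, duration = 34, seed = 8)
  keep <- sim$time >= 2
  rec <- recording(sim$output[, keep], sim$fs, c("a", "b"))
  w <- data.frame(start = 0, end = 32)
  g <- frequency_grid(8, 48, 2)
  e1 <- estimate_csd(rec, w, g, method = "var", order = 12)
  e2 <- estimate_csd(rec, w, g, method = "multitaper", n_tapers = 64)
  r <- Re(e1$csd[1, 1, , 1]) / Re(e2$csd[1, 1, , 1])
  expect_lt(sqrt(mean((r - 1)^2)), 0.25)
  expect_equal(e1$meta$method, "var")
  expect_equal(e2$meta$n_tapers, 64)
})

test_that("montage and filtering commute (both are linear)", {
  set.seed(6)
  rec <- recording(matrix(rnorm(4 * 1024), 4), 256,
                   c("LH4", "LH5", "LH6", "LH7"))
  pairs <- list(c("LH4", "LH5"), c("LH6", "LH7"))
  a <- bandpass(bipolar_montage(rec, pairs), 0.5, 48)
  b <- bipolar_montage(bandpass(rec, 0.5, 48), pairs)
  expect_equal(a$samples, b$samples, tolerance = 1e-8)
})

test_that("windowed CSD containers validate and serialize losslessly", {
  set.seed(7)
  arr <- random_hermitian_stack(2, 4, 3)
  w <- data.frame(start = 0:2, end = 2:4,
                  segment = c("pre", "pre", "ictal"))
  x <- windowed_csd(arr, c(10, 20, 30, 40), w, c("a", "b"))
  path <- tempfile(fileext = ".json")
  write_windowed_csd(x, path)
  back <- read_windowed_csd(path)
  expect_equal(back$csd, x$csd)
  expect_equal(back$freq, x$freq)
  expect_equal(back$windows$segment, w$segment)
  expect_error(windowed_csd(arr, c(10, 20), w), "dim")
})
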