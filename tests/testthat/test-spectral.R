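# Spectral forward model: linearization, transfer functions and predicted
# cross-spectral densities, checked against independent oracles.

test_that("frequency grid and power-law spectra behave as specified", {
  g <- frequency_grid()
  expect_equal(range(g), c(8, 48))
  expect_length(g, 41)
  expect_true(all(diff(g) > 0))
  expect_error(frequency_grid(10, 5))

  expect_equal(powerlaw_spectrum(3, 0, g), rep(3, 41))
  expect_equal(powerlaw_spectrum(1, 1, 2 * g) / powerlaw_spectrum(1, 1, g),
               rep(0.5, 41))
  expect_equal(powerlaw_spectrum(0, 2, g), rep(0, 41))
  expect_error(powerlaw_spectrum(-1, 1, g))
})

test_that("state-space Jacobian matches finite differences of the motion", {
  p <- cmc_parameters(logs = c(int_sp_sp_s1 = 0.3, ext_fw = -0.2))
  set.seed(11)
  x_star <- rnorm(16, sd = 0.5)
  ss <- cmc_statespace(p, x_star = x_star)
  A <- ss$A0 + ss$Ai + ss$Ae          # zero-delay total Jacobian
  h <- 1e-6
  Afd <- matrix(0, 16, 16)
  for (j in 1:16) {
    ep <- em <- x_star
    ep[j] <- ep[j] + h; em[j] <- em[j] - h
    Afd[, j] <- (cmc_motion(ep, p, state_delayed = ep) -
                   cmc_motion(em, p, state_delayed = em)) / (2 * h)
  }
  expect_lt(max(abs(A - Afd)) / max(abs(A)), 1e-6)
})

test_that("with couplings silenced the system decouples into kappa blocks", {
  logs <- setNames(rep(-40, 22),
                   c(grep("^(int|ext)", default_priors()$name, value = TRUE)))
  p <- cmc_parameters(logs = logs)
  ss <- cmc_statespace(p)
  A <- ss$A0 + ss$Ai + ss$Ae
  kap <- ss$kappa
  expect_equal(A[1:8, 9:16], diag(8), tolerance = 1e-12)
  expect_equal(diag(A[9:16, 1:8]), -kap^2, tolerance = 1e-10)
  expect_equal(diag(A[9:16, 9:16]), -2 * kap, tolerance = 1e-12)
  offdiag <- A[9:16, 1:8]; diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-8)
})

test_that("transfer function equals an independent resolvent evaluation", {
  p <- cmc_parameters(logs = c(int_sp_sp_s2 = 0.4))
  ss <- cmc_statespace(p)
  g <- frequency_grid()
  T <- transfer_function(ss, g)
  set.seed(2)
  for (k in sample(length(g), 5)) {
    w <- 2 * pi * g[k]
    Aw <- ss$A0 + ss$Ai * exp(-1i * w * ss$tau_i) +
      ss$Ae * exp(-1i * w * ss$tau_e)
    Tref <- ss$L %*% solve(1i * w * diag(16) - Aw, ss$B)
    expect_equal(T[, , k], unname(Tref), tolerance = 1e-10)
  }
})

test_that("zero electrode gain gives an identically zero transfer function", {
  ss <- cmc_statespace(cmc_parameters())
  ss$L[] <- 0
  T <- transfer_function(ss, frequency_grid())
  expect_equal(max(abs(T)), 0)
})

test_that("predicted CSD is Hermitian with real non-negative diagonal", {
  p <- cmc_parameters(logs = c(int_sp_sp_s1 = 1, ext_bw = 0.5))
  G <- predict_csd(p)
  expect_true(validate_csd(G))
  expect_true(all(abs(Im(G[1, 1, ])) == 0 | abs(Im(G[1, 1, ])) < 1e-20))
})

test_that("with silenced input the CSD equals the noise spectrum exactly", {
  p <- cmc_parameters(logs = c(input_amp_s1 = -40, input_amp_s2 = -40))
  g <- frequency_grid()
  G <- predict_csd(p, g)
  Gn <- synaptrack:::noise_csd(1, 1, g, common_frac = 0.25, scale = 1e-8)
  expect_equal(Re(G), Gn, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(Im(G))), 1e-20)
})

test_that("channel gain scales the neuronal auto-spectrum by exp(2 delta)", {
  g <- frequency_grid()
  p0 <- cmc_parameters()
  G0 <- predict_csd(p0, g)
  delta <- 0.3
  p1 <- cmc_parameters(logs = c(gain_1 = delta))
  G1 <- predict_csd(p1, g)
  Gn <- synaptrack:::noise_csd(1, 1, g, common_frac = 0.25, scale = 1e-8)
  ratio <- (Re(G1[1, 1, ]) - Gn[1, 1, ]) / (Re(G0[1, 1, ]) - Gn[1, 1, ])
  expect_equal(ratio, rep(exp(2 * delta), length(g)), tolerance = 1e-8)
  # the other channel's neuronal term is unchanged
  ratio2 <- (Re(G1[2, 2, ]) - Gn[2, 2, ]) / (Re(G0[2, 2, ]) - Gn[2, 2, ])
  expect_equal(ratio2, rep(1, length(g)), tolerance = 1e-8)
})

test_that("CSD prediction is differentiable in every free log-scaling", {
  pr <- default_priors()
  comp <- synaptrack:::compile_model(pr, "fw_primary", cmc_config())
  g <- frequency_grid()
  logs <- setNames(numeric(nrow(pr)), pr$name)
  h <- 1e-3
  for (nm in pr$name[pr$var > 0]) {
    lp <- lm <- logs
    lp[nm] <- h; lm[nm] <- -h
    d <- (synaptrack:::predict_csd_logs(comp, lp, g, guard = FALSE) -
            synaptrack:::predict_csd_logs(comp, lm, g, guard = FALSE)) / (2 * h)
    expect_true(all(is.finite(Re(d))) && all(is.finite(Im(d))))
  }
})

test_that("stable draws from the prior always yield valid CSDs", {
  pr <- default_priors()
  comp <- synaptrack:::compile_model(pr, "fw_primary", cmc_config())
  g <- frequency_grid()
  set.seed(20)
  n_ok <- 0
  for (k in 1:20) {
    logs <- setNames(rnorm(nrow(pr), 0, sqrt(pr$var)), pr$name)
    G <- tryCatch(synaptrack:::predict_csd_logs(comp, logs, g),
                  cmc_unstable = function(c) NULL)
    if (is.null(G)) next
    n_ok <- n_ok + 1
    expect_true(validate_csd(G))
  }
  expect_gt(n_ok, 10)   # most prior draws are dynamically stable
})

test_that("predicted auto-spectra match nonparametric spectra of a long
          simulation", {
  p <- cmc_parameters()
  sim <- cmc_integrate(p, duration = 64, seed = 11)
  keep <- sim$time >= 4
  rec <- recording(sim$output[, keep], sim$fs, c("ch1", "ch2"))
  g <- frequency_grid()
  est <- estimate_csd(rec, data.frame(start = 0, end = 60), g,
                      method = "multitaper", n_tapers = 96)
  ss <- cmc_statespace(p)
  T <- transfer_function(ss, g)
  Gu <- cbind(powerlaw_spectrum(1, 1, g), powerlaw_spectrum(1, 1, g))
  for (c in 1:2) {
    pred <- sapply(seq_along(g), function(k)
      Re((T[, , k] %*% diag(Gu[k, ]) %*% Conj(t(T[, , k])))[c, c]))
    obs <- Re(est$csd[c, c, , 1])
    expect_lt(sqrt(mean((obs / pred - 1)^2)), 0.10)
  }
})
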