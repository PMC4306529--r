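# The canonical-microcircuit source model: priors, the log-scaling
# parameterization, sigmoid coupling, equations of motion and the delay
# integrator.

test_that("default priors cover every parameter with the documented values", {
  pr <- default_priors()
  expect_s3_class(pr, "prior_spec")
  expect_false(anyDuplicated(pr$name) > 0)
  expect_true(all(pr$mean > 0))
  expect_true(all(pr$var >= 0))

  val <- function(n) pr$mean[pr$name == n]
  vvar <- function(n) pr$var[pr$name == n]
  expect_equal(val("delay_ext"), 8)      # extrinsic conduction delay, ms
  expect_equal(val("delay_int"), 1)      # intrinsic conduction delay, ms
  expect_equal(val("noise_amp"), 1)      # measurement-noise amplitude
  expect_equal(val("input_amp_s1"), 1)
  expect_equal(val("input_exp"), 1)
  expect_equal(val("noise_exp"), 1)
  expect_equal(val("gamma"), 2 / 3)
  expect_equal(unname(sapply(paste0("kappa_", c("ss", "sp", "ii", "dp"), "_s1"),
                             val)),
               c(1000 / 2, 1000 / 2, 1000 / 16, 1000 / 28))
  expect_equal(vvar("int_sp_sp_s1"), 1 / 8)
  expect_equal(vvar("ext_fw"), 1 / 8)
  expect_equal(vvar("kappa_sp_s2"), 1 / 16)
  expect_equal(vvar("gamma"), 1 / 32)
  expect_equal(vvar("delay_ext"), 1 / 32)
  expect_equal(vvar("noise_amp"), 1 / 128)
})

test_that("priors round-trip through flat key-value files", {
  pr <- default_priors()
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_priors(pr, path)
    back <- read_priors(path)
    expect_equal(back$name, pr$name)
    expect_equal(back$mean, pr$mean, tolerance = 1e-12)
    expect_equal(back$var, pr$var, tolerance = 1e-12)
  }
})

test_that("effective_value implements the log-scaling parameterization", {
  expect_equal(effective_value(10, 0), 10)
  expect_equal(effective_value(1, 2), exp(2))
  expect_equal(effective_value(4, -log(2)), 2)
  expect_error(effective_value(-1, 0), "invalid prior")
  expect_error(effective_value(0, 1), "invalid prior")
  # round trip at zero log-scaling, and monotonicity
  pr <- default_priors()
  expect_equal(effective_value(pr$mean, 0), pr$mean)
  ls <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(effective_value(3.7, ls)) > 0))
  expect_true(all(effective_value(pr$mean, rnorm(nrow(pr))) > 0))
})

test_that("sigmoid response is centered, odd, bounded and monotone", {
  g <- 2 / 3
  expect_equal(sigmoid_response(0, g), 0)
  v <- seq(-20, 20, by = 0.5)
  expect_equal(sigmoid_response(-v, g), -sigmoid_response(v, g))
  expect_true(all(abs(sigmoid_response(v, g)) < 0.5))
  expect_equal(sigmoid_response(1e4, g), 0.5, tolerance = 1e-12)
  expect_true(all(diff(sigmoid_response(v, g)) > 0))
  expect_error(sigmoid_response(0, -1))
})

test_that("equations of motion: fixed point, locality and error contract", {
  p <- cmc_parameters()
  x0 <- numeric(16)
  expect_equal(cmc_motion(x0, p), numeric(16))
  expect_error(cmc_motion(numeric(5), p), "malformed state")

  # perturbing the tracked self-inhibition changes only the superficial
  # pyramidal acceleration of that source
  set.seed(7)
  x <- rnorm(16, sd = 2)
  f0 <- cmc_motion(x, p)
  p2 <- cmc_parameters(logs = c(int_sp_sp_s1 = log(2)))
  f2 <- cmc_motion(x, p2)
  changed <- which(abs(f2 - f0) > 1e-12)
  expect_equal(changed, 8 + 2)  # z-block entry of sp, source 1
})

test_that("fixed point solver finds machine-precision roots from any start", {
  p <- cmc_parameters()
  fp0 <- fixed_point(p)
  expect_equal(fp0$state, numeric(16))

  # constant input: root-finding oracle — residual of the motion equations
  fp <- fixed_point(p, input = c(0.5, -0.2))
  expect_lt(fp$residual, 1e-9)
  expect_lt(max(abs(cmc_motion(fp$state, p, input = c(0.5, -0.2),
                               state_delayed = fp$state))), 1e-9)
  # multi-start: perturbed starts converge to the same root
  set.seed(1)
  for (k in 1:3) {
    fpk <- fixed_point(p, input = c(0.5, -0.2), start = rnorm(16, sd = 1))
    expect_equal(fpk$state, fp$state, tolerance = 1e-6)
  }
})

test_that("linearization at default priors is stable (decaying kernels)", {
  ss <- cmc_statespace(cmc_parameters())
  ev <- eigen(ss$A0 + ss$Ai + ss$Ae, only.values = TRUE)$values
  expect_lt(max(Re(ev)), 0)
})

test_that("integrator: fixed point, reproducibility, impulse decay", {
  p <- cmc_parameters()
  nd <- matrix(0, 2049, 2)
  z <- cmc_integrate(p, duration = 1, drive = nd)
  expect_equal(max(abs(z$output)), 0)      # unforced fixed point preserved

  s1 <- cmc_integrate(p, duration = 2, seed = 5)
  s2 <- cmc_integrate(p, duration = 2, seed = 5)
  expect_identical(s1$output, s2$output)   # bit-reproducible
  s3 <- cmc_integrate(p, duration = 2, seed = 6)
  expect_false(identical(s3$output, s1$output))

  # small impulse decays back towards the origin (stable linearization)
  init <- c(rep(0.5, 8), rep(0, 8))
  si <- cmc_integrate(p, duration = 2, drive = matrix(0, 4097, 2),
                      init = init, keep_states = TRUE)
  early <- max(abs(si$states[, 2]))
  late <- max(abs(si$states[, ncol(si$states)]))
  expect_lt(late, early / 100)

  expect_error(cmc_integrate(p, duration = 1, dt = 2), "delay")
})

test_that("halving the step changes the output spectrum by under 1%", {
  p <- cmc_parameters()
  n1 <- 2048 * 8 + 1
  drvc <- powerlaw_drive(n1, 2048, exponent = 1, n_series = 2, seed = 9)
  # same continuous (piecewise-linear) drive on both step grids
  drvf <- apply(drvc, 2, function(x)
    approx(seq_along(x), x, n = 2 * n1 - 1)$y)
  s1 <- cmc_integrate(p, duration = 8, dt = 1000 / 2048, drive = drvc)
  s2 <- cmc_integrate(p, duration = 8, dt = 1000 / 4096, drive = drvf)
  pw <- function(s) {
    rec <- recording(s$output, s$fs, c("a", "b"))
    est <- estimate_csd(rec, data.frame(start = 1, end = 8),
                        method = "multitaper", n_tapers = 12)
    sum(Re(est$csd[1, 1, , 1]))
  }
  expect_lt(abs(pw(s1) - pw(s2)) / pw(s2), 0.01)
})

test_that("generated power-law drive has the requested spectral density", {
  drv <- powerlaw_drive(2^14, 256, amp = 2, exponent = 0, seed = 1)
  rec <- recording(t(drv), 256, c("a", "b"))
  est <- estimate_csd(rec, data.frame(start = 0, end = 64),
                      grid = frequency_grid(8, 48, 4),
                      method = "multitaper", n_tapers = 48)
  expect_equal(mean(Re(est$csd[1, 1, , 1])), 2, tolerance = 0.1)
})
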