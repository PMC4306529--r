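# Candidate models, temporal bases, model comparison, Bayesian updating and
# trajectory extraction.

test_that("the temporal basis is an orthonormal per-segment block design", {
  X <- temporal_basis(9, 9, 3)
  expect_equal(dim(X), c(18, 8))
  expect_equal(qr(X)$rank, 8)
  expect_equal(unname(crossprod(X)), diag(8), tolerance = 1e-10)  # orthonormal
  expect_equal(max(abs(X[1:9, 5:8])), 0)                   # block structure
  expect_equal(max(abs(X[10:18, 1:4])), 0)

  X0 <- temporal_basis(9, 9, 0)
  expect_equal(dim(X0), c(18, 2))
  expect_equal(length(unique(round(X0[1:9, 1], 12))), 1)   # constant columns

  expect_error(temporal_basis(3, 9, 3), "rank-deficient")
})

test_that("the model space enumerates all change combinations", {
  ms <- enumerate_models()
  expect_length(ms, 16)
  ids <- vapply(ms, `[[`, "", "id")
  expect_equal(anyDuplicated(ids), 0)
  expect_equal(ids[1], "FW-0000")
  expect_equal(ids[16], "FW-1111")
  flags <- t(vapply(ms, function(m) m$flags, logical(4)))
  expect_equal(nrow(unique(flags)), 16)

  expect_length(enumerate_models(factors = character(0)), 1)  # null only
})

test_that("excluding a non-converged model leaves 15 in the comparison", {
  set.seed(1)
  F16 <- matrix(rnorm(16, -1000, 5), 16, 1,
                dimnames = list(sprintf("m%02d", 1:16), NULL))
  F16["m11", 1] <- NA   # failed inversion
  cmp <- compare_models(F16)
  expect_equal(sum(!cmp$table$excluded), 15)
  expect_true(cmp$table$excluded[cmp$table$model == "m11"])
  expect_equal(sum(cmp$table$prob, na.rm = TRUE), 1)
})

test_that("expand_parameters applies deviations only to flagged couplings", {
  base <- cmc_parameters()
  X <- temporal_basis(9, 9, 3)
  flags <- setNames(c(TRUE, FALSE, FALSE, FALSE),
                    c("intrinsic1", "intrinsic2", "forward", "backward"))
  # zero coefficients: identical windows
  logs <- expand_parameters(base, rep(0, 8), X, flags)
  expect_equal(nrow(unique(round(logs, 12))), 1)

  set.seed(2)
  beta <- rnorm(8)
  logs <- expand_parameters(base, beta, X, flags)
  varying <- names(which(apply(logs, 2, function(c) diff(range(c)) > 0)))
  expect_equal(varying, "int_sp_sp_s1")

  # a pure pre-segment constant coefficient shifts all 9 pre windows equally
  b0 <- c(1, rep(0, 7))
  logs0 <- expand_parameters(base, b0, X, flags)
  dev <- logs0[, "int_sp_sp_s1"]
  expect_equal(length(unique(round(dev[1:9], 12))), 1)
  expect_gt(dev[1], 0)
  expect_equal(dev[10:18], rep(0, 9))

  expect_error(expand_parameters(base, beta[-1], X, flags), "length")
})

test_that("model comparison normalizes evidence and pools over sessions", {
  two <- matrix(c(-100, -100), 2, 1, dimnames = list(c("a", "b"), NULL))
  cmp <- compare_models(two)
  expect_equal(cmp$table$prob, c(0.5, 0.5))

  # a log-evidence difference of 3 is odds of about 20:1
  two[1] <- -97
  cmp <- compare_models(two)
  odds <- cmp$table$prob[1] / cmp$table$prob[2]
  expect_equal(odds, exp(3), tolerance = 1e-9)
  expect_equal(round(odds), 20)

  # pooling: per-session differences of (1, 1, 1) pool to 3
  F2 <- rbind(a = c(-50, -60, -40), b = c(-51, -61, -41))
  cmp2 <- compare_models(F2)
  expect_equal(diff(rev(cmp2$table$pooled_F)), 3)
  # invariance to a constant shift of all evidences
  cmp3 <- compare_models(F2 + 123.4)
  expect_equal(cmp3$table$prob, cmp2$table$prob, tolerance = 1e-10)
})

test_that("Bayesian updating carries posteriors and resets session gains", {
  fx <- fixture_fit()
  pr0 <- default_priors()
  up <- bayesian_update(fx$fit, pr0)
  co <- coef(fx$fit)
  carried <- setdiff(intersect(names(co), pr0$name), c("gain_1", "gain_2"))
  expect_equal(up$lmean[match(carried, up$name)], unname(co[carried]))
  # carried variances equal posterior variances
  pv <- diag(fx$fit$posterior$cov)[carried]
  expect_equal(up$var[match(carried, up$name)], unname(pv))
  # session-specific gains return to their original priors
  expect_equal(up$lmean[up$name == "gain_1"], 0)
  expect_equal(up$var[up$name == "gain_1"], pr0$var[pr0$name == "gain_1"])
  expect_true(!is.null(attr(up, "cov")))

  bad <- fx$fit
  bad$converged <- FALSE
  expect_error(bayesian_update(bad, pr0), "non-converged")
})

test_that("trajectory extraction propagates the coefficient posterior", {
  fx <- fixture_fit()
  tr <- extract_trajectories(fx$fit)
  expect_s3_class(tr, "cmc_trajectory")
  expect_equal(nrow(tr), 18)
  expect_true(all(tr$lo <= tr$mean & tr$mean <= tr$hi))
  # interval centre equals the projected mean
  expect_equal((tr$lo + tr$hi) / 2, tr$mean, tolerance = 1e-12)

  # zero posterior covariance: zero-width intervals
  fit0 <- fx$fit
  cn <- grep("^traj_", names(fit0$posterior$mean), value = TRUE)
  fit0$posterior$cov[cn, ] <- 0
  fit0$posterior$cov[, cn] <- 0
  tr0 <- extract_trajectories(fit0)
  expect_equal(tr0$lo, tr0$mean)
  expect_equal(tr0$hi, tr0$mean)

  # null model: no trajectories
  expect_equal(nrow(extract_trajectories(
    structure(list(model = model_spec(changes = character()),
                   basis = fx$fit$basis, posterior = fx$fit$posterior),
              class = "cmc_dcm"))), 0)
})

test_that("fitted-model methods expose the posterior coherently", {
  fx <- fixture_fit()
  fit <- fx$fit
  expect_output(print(fit), "Free energy")
  s <- summary(fit)
  expect_true(all(c("parameter", "mean", "sd") %in% names(s$coefficients)))
  expect_equal(unname(coef(fit)), unname(s$coefficients$mean))
  expect_equal(dim(vcov(fit)), rep(length(coef(fit)), 2))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$F)

  pred <- fitted(fit)
  expect_s3_class(pred, "windowed_csd")
  r <- residuals(fit)
  expect_length(r, length(featurize(fit$data)))
  # the model explains most of the feature variance at SNR 4
  expect_lt(sd(r) / sd(as.numeric(featurize(fit$data))), 0.6)
})
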