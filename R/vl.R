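# Variational Laplace: Gaussian posterior over parameters of a nonlinear
# prediction function by Gauss-Newton ascent on the variational free energy,
# with closed-form updates of band-wise noise log-precision hyperparameters.
#
# The free energy is
#   F = E_q[log p(y | theta)] - KL(q(theta) || p(theta)) - KL(q(lambda) || p(lambda))
# with Gaussian q, i.i.d. Gaussian observation noise of precision
# exp(lambda_b) within feature band b, and the expected log-likelihood
# evaluated under the local linearization (exact for linear models).

#' Inversion settings
#'
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence: change in free energy (nats) below which an
#'   accepted step counts towards convergence.
#' @param n_conv number of consecutive proposals without an improvement of
#'   at least `tol` after which the ascent is declared converged.
#' @param fd_step central finite-difference step in log-scaling space.
#' @param lambda0,lambda_var hyperprior mean and variance of the noise
#'   log-precisions (a variance of 0 fixes them).
#' @param n_bands number of frequency bands with separate noise precisions.
#' @param max_reject consecutive rejected steps after which the ascent is
#'   abandoned (flagged non-convergent if the objective was still moving).
#' @param verbose print per-iteration free energy.
#' @return list of settings.
#' @export
inversion_settings <- function(max_iter = 64, tol = 1e-2, n_conv = 8,
                               fd_step = 1e-3, lambda0 = 0, lambda_var = 16,
                               n_bands = 1, max_reject = 24, verbose = FALSE) {
  list(max_iter = max_iter, tol = tol, n_conv = n_conv, fd_step = fd_step,
       lambda0 = lambda0, lambda_var = lambda_var, n_bands = n_bands,
       max_reject = max_reject, verbose = verbose)
}

# log-determinant of a symmetric positive-definite matrix
ldet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)

# inverse of a symmetric matrix with an eigenvalue floor, robust to the
# near-singular precision matrices that arise when residuals vanish
sym_inv <- function(M, floor_rel = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, max(e$values) * floor_rel)
  e$vectors %*% (t(e$vectors) / ev)
}

# Gaussian Kullback-Leibler divergence KL(N(m1,S1) || N(m0,S0))
gauss_kl <- function(m1, S1, m0, S0) {
  p <- length(m1)
  iS0 <- solve(S0)
  0.5 * (sum(diag(iS0 %*% S1)) + t(m1 - m0) %*% iS0 %*% (m1 - m0) - p +
           ldet(S0) - ldet(S1))[1]
}

#' Variational free energy of a Gaussian posterior
#'
#' Computes `F = accuracy - complexity` for a Gaussian posterior over the
#' parameters of a prediction function under i.i.d. Gaussian noise with
#' (band-wise) log-precisions `lambda`: the accuracy is the expected
#' log-likelihood under the posterior (using the local linearization of the
#' prediction), the complexity is the KL divergence from the prior, plus the
#' corresponding KL term for estimated noise hyperparameters.
#'
#' @param mean,cov posterior mean and covariance.
#' @param y data vector.
#' @param gfun prediction function `gfun(theta) -> y-length vector`.
#' @param theta0,Sigma0 prior mean and covariance.
#' @param lambda noise log-precision(s), one per band.
#' @param bands list of feature index vectors, one per band.
#' @param lambda_prior list `(mean, var, cov)` describing the hyperprior and
#'   the posterior variance of `lambda`; with `var = 0` the hyperparameters
#'   are treated as fixed and contribute no complexity.
#' @param J optional precomputed Jacobian of `gfun` at `mean`.
#' @param fd_step finite-difference step when `J` is not supplied.
#' @return list `F`, `accuracy`, `complexity` (parameter KL),
#'   `complexity_lambda`.
#' @export
free_energy <- function(mean, cov, y, gfun, theta0, Sigma0, lambda = 0,
                        bands = list(seq_along(y)),
                        lambda_prior = list(mean = 0, var = 0, cov = 0),
                        J = NULL, fd_step = 1e-3) {
  e <- y - gfun(mean)
  if (any(!is.finite(e))) stop("non-finite prediction at the posterior mean")
  if (is.null(J)) J <- fd_jacobian(gfun, mean, length(y), fd_step)
  d <- rowSums((J %*% cov) * J)           # diag(J cov J')
  acc <- 0
  for (b in seq_along(bands)) {
    ib <- bands[[b]]
    pi_b <- exp(lambda[b])
    acc <- acc + 0.5 * (length(ib) * (lambda[b] - log(2 * pi)) -
                          pi_b * (sum(e[ib]^2) + sum(d[ib])))
  }
  comp <- gauss_kl(mean, cov, theta0, Sigma0)
  compl_l <- 0
  if (any(lambda_prior$var > 0)) {
    lv <- rep_len(lambda_prior$var, length(lambda))
    lm <- rep_len(lambda_prior$mean, length(lambda))
    lc <- rep_len(lambda_prior$cov, length(lambda))
    for (b in seq_along(lambda)) {
      if (lv[b] > 0)
        compl_l <- compl_l + 0.5 * ((lambda[b] - lm[b])^2 / lv[b] +
                                      lc[b] / lv[b] - 1 + log(lv[b]) -
                                      log(lc[b]))
    }
  }
  list(F = acc - comp - compl_l, accuracy = acc, complexity = comp,
       complexity_lambda = compl_l)
}

fd_jacobian <- function(gfun, theta, ny, h) {
  p <- length(theta)
  J <- matrix(0, ny, p)
  for (k in seq_len(p)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    gp <- tryCatch(gfun(tp), cmc_unstable = function(c) NULL)
    gm <- tryCatch(gfun(tm), cmc_unstable = function(c) NULL)
    if (!is.null(gp) && !is.null(gm)) {
      J[, k] <- (gp - gm) / (2 * h)
    } else {
      g0 <- gfun(theta)
      if (!is.null(gp)) J[, k] <- (gp - g0) / h
      else if (!is.null(gm)) J[, k] <- (g0 - gm) / h
      # both sides unstable: leave the column at zero
    }
  }
  J
}

# Newton updates of band-wise noise log-precisions given residuals e and
# the linearized posterior uncertainty d = diag(J S J').
update_lambda <- function(lambda, e, d, bands, l0, lv) {
  lcov <- numeric(length(lambda))
  for (b in seq_along(bands)) {
    ib <- bands[[b]]
    Nb <- length(ib)
    Rb <- sum(e[ib]^2) + sum(d[ib])
    if (lv == 0) { lcov[b] <- 0; next }
    for (it in 1:8) {
      pi_b <- exp(lambda[b])
      dF <- 0.5 * (Nb - pi_b * Rb) - (lambda[b] - l0) / lv
      ddF <- -0.5 * pi_b * Rb - 1 / lv
      step <- dF / ddF
      lambda[b] <- lambda[b] - max(min(step, 4), -4)
      # clamp to a wide numeric range: residual variances below exp(-32)
      # of the data scale are indistinguishable from noiseless
      lambda[b] <- max(min(lambda[b], l0 + 32), l0 - 32)
      if (abs(step) < 1e-8) break
    }
    lcov[b] <- 1 / (0.5 * exp(lambda[b]) * Rb + 1 / lv)
  }
  list(lambda = lambda, cov = lcov)
}

#' Variational-Laplace model inversion (generic engine)
#'
#' Estimates a Gaussian posterior over the free parameters of an arbitrary
#' prediction function by Gauss-Newton / Levenberg-Marquardt ascent on the
#' variational free energy.  Gradients are central finite differences;
#' noise precisions are updated in closed form between parameter steps;
#' steps that decrease F are rejected with increased regularization.
#' Parameters with zero prior variance are fixed at their prior mean.
#'
#' @param y data vector.
#' @param gfun prediction function over the full parameter vector.  It may
#'   signal a condition of class `cmc_unstable` for infeasible parameters;
#'   such steps are rejected.
#' @param theta0 prior mean (full parameter vector, named).
#' @param Sigma0 prior covariance (full); zero diagonal entries mark fixed
#'   parameters.
#' @param bands list of feature-index vectors sharing a noise precision.
#' @param settings from [inversion_settings()].
#' @param gfun_fd optional cheaper variant of `gfun` used only inside the
#'   finite-difference Jacobian (e.g. with stability guards disabled).
#' @return list with posterior `mean`, `cov` (full dimension; zero
#'   rows/columns for fixed parameters), free energy `F` and parts, the
#'   accepted-iteration `trace`, `lambda` and its posterior variance,
#'   `converged`, `iterations` and the indices of `free` parameters.
#' @export
vl_laplace <- function(y, gfun, theta0, Sigma0, bands = NULL,
                       settings = inversion_settings(), gfun_fd = NULL) {
  ny <- length(y)
  if (is.null(bands)) bands <- list(seq_len(ny))
  if (is.vector(Sigma0)) Sigma0 <- diag(Sigma0, length(theta0))
  free <- which(diag(Sigma0) > 0)
  if (!length(free)) stop("no free parameters: all prior variances are zero")
  S0 <- Sigma0[free, free, drop = FALSE]
  iS0 <- solve(S0)
  th0 <- theta0[free]

  embed <- function(tf) { full <- theta0; full[free] <- tf; full }
  gf <- function(tf) gfun(embed(tf))
  gf_fd <- if (is.null(gfun_fd)) gf else function(tf) gfun_fd(embed(tf))

  mu <- th0
  g0 <- gf(mu)
  if (any(!is.finite(g0))) stop("non-finite prediction at the prior mean")

  l0 <- settings$lambda0; lv <- settings$lambda_var
  lambda <- rep(l0, length(bands))
  p <- length(free)
  logv <- -2           # Levenberg regularization, log scale
  Fcur <- -Inf
  trace <- numeric(0)
  n_small <- 0; n_rej <- 0
  converged <- FALSE
  Scur <- S0
  parts <- NULL

  for (iter in seq_len(settings$max_iter)) {
    J <- fd_jacobian(gf_fd, mu, ny, settings$fd_step)
    e <- y - g0
    # alternate posterior covariance and noise precision a few times
    for (cyc in 1:3) {
      piv <- numeric(ny)
      for (b in seq_along(bands)) piv[bands[[b]]] <- exp(lambda[b])
      P <- crossprod(J * sqrt(piv)) + iS0
      Scur <- sym_inv(P)
      d <- rowSums((J %*% Scur) * J)
      up <- update_lambda(lambda, e, d, bands, l0, lv)
      lambda <- up$lambda
    }
    Fnew <- free_energy(mu, Scur, y, gf, th0, S0, lambda, bands,
                        list(mean = l0, var = lv, cov = up$cov), J = J)
    improved <- iter > 1 && Fnew$F > Fcur + settings$tol
    n_small <- if (improved) 0 else n_small + 1
    if (iter == 1 || Fnew$F > Fcur) {     # accept
      Fcur <- Fnew$F; parts <- Fnew
      trace <- c(trace, Fcur)
      mu_acc <- mu; S_acc <- Scur; l_acc <- lambda; lcov_acc <- up$cov
      J_acc <- J; e_acc <- e
      logv <- max(logv - 1, -8)
      n_rej <- 0
    } else {                              # reject: restore and regularize
      mu <- mu_acc; lambda <- l_acc
      logv <- logv + 2
      n_rej <- n_rej + 1
      if (n_rej >= settings$max_reject) break
      J <- J_acc; e <- e_acc
      piv <- numeric(ny)
      for (b in seq_along(bands)) piv[bands[[b]]] <- exp(lambda[b])
      P <- crossprod(J * sqrt(piv)) + iS0
    }
    if (iter > 1 && n_small >= settings$n_conv) { converged <- TRUE; break }
    # Gauss-Newton step with Levenberg damping
    grad <- crossprod(J, piv * e) - iS0 %*% (mu - th0)
    H <- P + exp(logv) * diag(diag(P), p)
    step <- tryCatch(solve(H, grad), error = function(e) sym_inv(H) %*% grad)
    cand <- mu + as.vector(step)
    gc_ <- tryCatch(gf(cand), cmc_unstable = function(c) NULL)
    tries <- 0
    while ((is.null(gc_) || any(!is.finite(gc_))) && tries < 8) {
      logv <- logv + 2; tries <- tries + 1
      H <- P + exp(logv) * diag(diag(P), p)
      cand <- mu + as.vector(solve(H, grad))
      gc_ <- tryCatch(gf(cand), cmc_unstable = function(c) NULL)
    }
    if (is.null(gc_) || any(!is.finite(gc_))) break
    mu <- cand; g0 <- gc_
    if (settings$verbose)
      message(sprintf("iter %2d  F = %.3f", iter, Fcur))
  }

  mean_full <- theta0; mean_full[free] <- mu_acc
  cov_full <- matrix(0, length(theta0), length(theta0),
                     dimnames = list(names(theta0), names(theta0)))
  cov_full[free, free] <- (S_acc + t(S_acc)) / 2
  list(mean = mean_full, cov = cov_full, F = Fcur,
       accuracy = parts$accuracy,
       complexity = parts$complexity + parts$complexity_lambda,
       trace = trace, lambda = l_acc, lambda_cov = lcov_acc,
       converged = converged, iterations = length(trace), free = free)
}
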