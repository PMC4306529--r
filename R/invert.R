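# Model inversion: fit the windowed CSD-DCM to data by variational Laplace.

#' Fit the windowed CSD dynamic causal model
#'
#' Estimates the posterior density over log-scaling parameters of the
#' two-source CMC model — shared (base) parameters plus polynomial
#' trajectory coefficients for the couplings the model allows to change —
#' from windowed complex cross-spectra, by Gauss-Newton ascent on the
#' variational free energy.  The free energy approximates the log model
#' evidence and is used for Bayesian model comparison.
#'
#' Parameters flagged as changing lose their shared free log-scaling; their
#' per-segment constant basis column plays that role, so the trajectory
#' coefficients carry both the level and the time course of the deviation.
#' Inversions start deterministically at the prior means.
#'
#' @param data a [windowed_csd()] (e.g. from [estimate_csd()] or
#'   [generate_dataset()]); window count must match the model's
#'   `n_pre + n_post`.
#' @param model a [model_spec()].
#' @param priors `prior_spec` from [default_priors()], possibly updated by
#'   [bayesian_update()] (an optional `lmean` column holds non-zero prior
#'   means of the log-scalings, and a `"cov"` attribute a full prior
#'   covariance).
#' @param config a [cmc_config()].
#' @param settings an [inversion_settings()] list.
#' @param traj_prior_var prior variance of the trajectory basis
#'   coefficients: a vector over the per-segment polynomial orders
#'   (0..order), or a scalar applied to all.  The default halves the
#'   variance per order — a smoothness prior reflecting the premise that
#'   the tracked modulations are slow, so high-order wiggle is shrunk more
#'   strongly than slow drift.
#' @param noise_rho assumed lag-one correlation of the feature noise across
#'   neighbouring frequency bins.  Windowed spectral estimators smooth over
#'   a bandwidth of a few bins, so their sampling error is correlated
#'   across frequency; the likelihood models this as an AR(1) dependence
#'   and whitens each frequency series accordingly.  Set to 0 for an
#'   independent-noise likelihood.
#' @return an object of class `cmc_dcm`; see [summary.cmc_dcm()],
#'   [coef.cmc_dcm()], [extract_trajectories()], [compare_models()].
#' @export
fit_cmc_csd <- function(data, model = model_spec(), priors = default_priors(),
                        config = cmc_config(), settings = inversion_settings(),
                        traj_prior_var = NULL, noise_rho = 0.6,
                        weight_profile = NULL) {
  stopifnot(inherits(data, "windowed_csd"), inherits(model, "model_spec"))
  validate_priors(priors)
  nw <- nrow(data$windows)
  if (nw != model$n_pre + model$n_post)
    stop("window count (", nw, ") does not match model segmentation (",
         model$n_pre, " + ", model$n_post, ")")
  grid <- data$freq
  comp <- compile_model(priors, model$architecture, config)
  X <- temporal_basis(model$n_pre, model$n_post, model$basis_order)

  fp <- flag_params(config)
  on <- names(model$flags)[model$flags]
  flag_par <- fp[on]
  miss <- setdiff(flag_par, priors$name)
  if (length(miss)) stop("flagged parameter(s) not in priors: ",
                         paste(miss, collapse = ", "))

  # full parameter vector: base log-scalings then trajectory coefficients
  lmean <- if (is.null(priors$lmean)) rep(0, nrow(priors)) else priors$lmean
  base_names <- priors$name
  traj_names <- if (length(on))
    as.vector(t(outer(paste0("traj_", on, "_"), colnames(X), paste0)))
  else character(0)
  theta0 <- setNames(c(lmean, numeric(length(traj_names))),
                     c(base_names, traj_names))
  pvar <- priors$var
  pvar[match(flag_par, base_names)] <- 0   # level absorbed by basis constants
  nb <- ncol(X)
  if (is.null(traj_prior_var))
    traj_prior_var <- 2 * 0.5^(0:model$basis_order)
  tv <- rep_len(rep(traj_prior_var, length.out = model$basis_order + 1), nb)
  Sigma0 <- diag(c(pvar, rep(tv, length(on))))
  dimnames(Sigma0) <- list(names(theta0), names(theta0))
  pc <- attr(priors, "cov")
  if (!is.null(pc)) {
    i <- match(base_names, rownames(pc))
    blk <- pc[i, i]
    blk[match(flag_par, base_names), ] <- 0
    blk[, match(flag_par, base_names)] <- 0
    diag(blk)[match(flag_par, base_names)] <- 0
    Sigma0[seq_along(base_names), seq_along(base_names)] <- blk
  }

  ib <- seq_along(base_names)
  flag_idx <- match(flag_par, base_names)
  gfun <- function(theta, guard = TRUE) {
    base_logs <- theta[ib]
    names(base_logs) <- base_names
    pred <- array(0 + 0i, dim(data$csd))
    if (length(on)) {
      B <- matrix(theta[-ib], nb, length(on))
      dev <- X %*% B
    }
    for (w in seq_len(nw)) {
      logs <- base_logs
      if (length(on)) logs[flag_idx] <- logs[flag_idx] + dev[w, ]
      pred[, , , w] <- predict_csd_logs(comp, logs, grid, guard = guard)
    }
    as.numeric(featurize(pred, map = FALSE))
  }

  # Feature weighting and whitening.  CSD sampling error is proportional to
  # the local spectral amplitude, so features are divided by the empirical
  # profile sqrt(|G_ii| |G_jj|) (variance stabilization), then each
  # (window, component) frequency series is AR(1)-whitened to account for
  # the smoothness of spectral-estimation error across neighbouring bins.
  nf <- length(grid)
  nch <- dim(data$csd)[1]
  ncomp <- nch^2
  # Weighting profile from segment-averaged data auto-spectra: averaging
  # over the windows of a segment suppresses the noise correlation that
  # would bias per-window empirical weights, while still tracking the
  # spectral change across the transition.
  if (is.null(weight_profile)) {
    seg <- data$windows$segment
    if (all(is.na(seg))) seg <- rep("all", nw)
    amp_seg <- array(0, c(nch, nf, nw))
    for (s in unique(seg)) {
      iw <- which(seg == s)
      for (c in seq_len(nch))
        amp_seg[c, , iw] <- rowMeans(abs(matrix(data$csd[c, c, , iw], nf)))
    }
  } else {
    stopifnot(all(dim(weight_profile) == dim(data$csd)))
    amp_seg <- array(0, c(nch, nf, nw))
    for (c in seq_len(nch)) amp_seg[c, , ] <- abs(weight_profile[c, c, , ])
  }
  prof <- array(0, c(ncomp, nf, nw))
  ut <- which(upper.tri(diag(nch), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  st <- which(upper.tri(diag(nch)), arr.ind = TRUE)
  st <- st[order(st[, 2], st[, 1]), , drop = FALSE]
  ij <- rbind(ut, st)
  for (r in seq_len(nrow(ij)))
    prof[r, , ] <- sqrt(amp_seg[ij[r, 1], , ] * amp_seg[ij[r, 2], , ])
  prof <- pmax(prof, 0.05 * mean(prof))
  whiten <- function(v) {
    x <- array(v, c(ncomp, nf, nw)) / prof
    if (noise_rho > 0) {
      a <- 1 / sqrt(1 - noise_rho^2)
      x[, -1, ] <- a * (x[, -1, , drop = FALSE] -
                          noise_rho * x[, -nf, , drop = FALSE])
    }
    as.numeric(x)
  }

  # scale features to unit spread so noise log-precisions are O(1)
  y_raw <- featurize(data)
  yw <- whiten(as.numeric(y_raw))
  scale <- sd(yw)
  y <- yw / scale
  gfun_s <- function(theta) whiten(gfun(theta)) / scale
  # guard-free variant for finite-difference perturbations (a 1e-3 nudge
  # from a stable point cannot destabilize materially; skipping the
  # eigenvalue check there saves a third of the runtime)
  gfun_fd <- function(theta) whiten(gfun(theta, guard = FALSE)) / scale

  bands <- if (settings$n_bands > 1) {
    cut_idx <- cut(attr(y_raw, "map")$freq_index, settings$n_bands,
                   labels = FALSE)
    lapply(seq_len(settings$n_bands), function(b) which(cut_idx == b))
  } else list(seq_along(y))

  post <- vl_laplace(y, gfun_s, theta0, Sigma0, bands, settings,
                     gfun_fd = gfun_fd)

  structure(list(posterior = post, F = post$F, converged = post$converged,
                 model = model, priors = priors, config = config,
                 basis = X, grid = grid, data = data, scale = scale,
                 settings = settings, call = match.call()),
            class = "cmc_dcm")
}
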