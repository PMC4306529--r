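# Face-validation generator: windowed CSD datasets from known parameter
# trajectories with realistic sampling noise, and recovery scoring.

#' Ground-truth parameter trajectories
#'
#' Mono-exponential trajectories for the face-validation design: all
#' pre-transition windows sit at the prior expectation (log-scaling 0); at
#' onset each changing parameter jumps by its excursion amplitude and
#' decays back with its time constant, evaluated at the window schedule
#' (default 9 pre + 9 post windows at 1-s steps).  Defaults follow the
#' validation design: intrinsic (superficial-pyramidal self-inhibition)
#' excursions of +2 log units decaying with an 8-s time constant in both
#' sources, and a forward-connection excursion of +1 log unit decaying with
#' a 2-s time constant.
#'
#' @param tau_intrinsic,tau_extrinsic decay time constants (s).
#' @param amplitudes named onset excursions (log units) over a subset of
#'   `c("intrinsic1", "intrinsic2", "forward", "backward")`.
#' @param n_pre,n_post windows per segment.
#' @param step window step (s).
#' @return object of class `trajectory_truth`: matrix windows x changing
#'   parameters plus schedule attributes.
#' @export
true_trajectories <- function(tau_intrinsic = 8, tau_extrinsic = 2,
                              amplitudes = c(intrinsic1 = 2, intrinsic2 = 2,
                                             forward = 1),
                              n_pre = 9, n_post = 9, step = 1) {
  if (tau_intrinsic <= 0 || tau_extrinsic <= 0)
    stop("decay time constants must be positive")
  stopifnot(all(names(amplitudes) %in% change_factors), step > 0)
  t_post <- (seq_len(n_post) - 1) * step
  vals <- vapply(names(amplitudes), function(fl) {
    tau <- if (grepl("^intrinsic", fl)) tau_intrinsic else tau_extrinsic
    c(rep(0, n_pre), amplitudes[[fl]] * exp(-t_post / tau))
  }, numeric(n_pre + n_post))
  structure(vals, class = "trajectory_truth",
            n_pre = n_pre, n_post = n_post, step = step,
            tau_intrinsic = tau_intrinsic, tau_extrinsic = tau_extrinsic,
            amplitudes = amplitudes)
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat(sprintf("Ground-truth trajectories: %d + %d windows, step %g s\n",
              attr(x, "n_pre"), attr(x, "n_post"), attr(x, "step")))
  cat(sprintf("tau_intrinsic = %g s, tau_extrinsic = %g s\n",
              attr(x, "tau_intrinsic"), attr(x, "tau_extrinsic")))
  print(round(unclass(x), 3))
  invisible(x)
}

# Hermitian noise with autoregressive smoothness across frequency, scaled
# so the per-channel RMS amplitude ratio of signal to noise equals snr.
ar1_series <- function(n, rho) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (k in 2:n) x[k] <- rho * x[k - 1] + sqrt(1 - rho^2) * rnorm(1)
  x
}

csd_noise_draw <- function(nc, nf, rho) {
  E <- array(0 + 0i, c(nc, nc, nf))
  for (i in seq_len(nc)) E[i, i, ] <- ar1_series(nf, rho)
  for (i in seq_len(nc)) for (j in seq_len(nc)) if (i < j) {
    z <- complex(real = ar1_series(nf, rho),
                 imaginary = ar1_series(nf, rho)) / sqrt(2)
    E[i, j, ] <- z
    E[j, i, ] <- Conj(z)
  }
  E
}

# Shape the raw draw by the local spectral amplitude (sampling error of a
# spectral estimate is proportional to the spectrum) and normalize so the
# per-channel RMS amplitude ratio of signal to noise equals snr exactly.
scale_noise <- function(E, G, snr) {
  nc <- dim(G)[1]
  s <- vapply(seq_len(nc), function(c) sqrt(mean(abs(G[c, c, ])^2)), 0)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    prof <- sqrt(abs(G[i, i, ]) * abs(G[j, j, ]))
    shaped <- E[i, j, ] * prof
    target <- sqrt(s[i] * s[j]) / snr
    r <- sqrt(mean(abs(shaped)^2))
    E[i, j, ] <- shaped * (target / r)
  }
  for (i in seq_len(nc)) for (j in seq_len(nc)) if (i < j)
    E[j, i, ] <- Conj(E[i, j, ])
  E
}

# core generator used by both generate_dataset and simulate.cmc_dcm
generate_from_logs <- function(logs, priors, config, architecture, grid,
                               snr, seed, windows, rho = 0.6) {
  comp <- compile_model(priors, architecture, config)
  nw <- nrow(logs)
  nc <- 2
  noiseless <- array(0 + 0i, c(nc, nc, length(grid), nw))
  for (w in seq_len(nw)) {
    G <- tryCatch(predict_csd_logs(comp, logs[w, ], grid),
                  cmc_unstable = function(c)
                    stop("unstable parameter draw at window ", w))
    noiseless[, , , w] <- G
  }
  noisy <- noiseless
  if (is.finite(snr)) {
    set.seed(seed)
    pool <- lapply(seq_len(nw), function(w)
      csd_noise_draw(nc, length(grid), rho))
    perm <- sample(nw)      # permute the noise pool over windows
    for (w in seq_len(nw)) {
      E <- scale_noise(pool[[perm[w]]], noiseless[, , , w], snr)
      noisy[, , , w] <- noiseless[, , , w] + E
    }
  }
  windowed_csd(noisy, grid, windows, paste0("ch", 1:nc),
               list(method = "synthetic", snr = snr, seed = seed))
}

#' Generate a synthetic windowed-CSD dataset
#'
#' The face-validation generator: noiseless cross-spectra per window are
#' computed from the spectral forward model at the base parameters expanded
#' along the ground-truth trajectories; Hermitian-structured noise with
#' autoregressive smoothness across frequency (mimicking the amplitude and
#' form of CSD sampling error) is drawn as a permuted pool over windows and
#' scaled so the per-channel, per-window RMS amplitude ratio of signal to
#' noise equals `snr`.
#'
#' @param truth a [true_trajectories()] object.
#' @param params base [cmc_parameters()] (defaults: prior means).
#' @param snr signal-to-noise RMS amplitude ratio (`Inf` for noiseless).
#' @param seed integer seed; identical seed and configuration reproduce the
#'   dataset bit-exactly.
#' @param grid frequency grid (Hz).
#' @param architecture extrinsic architecture of the generating model.
#' @param window_len,overlap window geometry recorded in the metadata.
#' @param rho autoregressive coefficient of the noise across frequency.
#' @return object of class `cmc_synth`: list with `data` (the noisy
#'   [windowed_csd()]), `noiseless`, `truth`, `snr`, `seed` and a manifest.
#' @export
generate_dataset <- function(truth, params = cmc_parameters(), snr = 4,
                             seed = 1, grid = frequency_grid(),
                             architecture = "fw_primary",
                             window_len = 2, overlap = 0.5, rho = 0.6) {
  stopifnot(inherits(truth, "trajectory_truth"), snr > 0)
  n_pre <- attr(truth, "n_pre"); n_post <- attr(truth, "n_post")
  step <- attr(truth, "step")
  nw <- n_pre + n_post
  flags <- setNames(change_factors %in% colnames(truth), change_factors)
  fp <- flag_params(params$config)
  logs <- matrix(rep(params$logs, each = nw), nw, length(params$logs),
                 dimnames = list(NULL, names(params$logs)))
  for (fl in colnames(truth)) logs[, fp[fl]] <- logs[, fp[fl]] + truth[, fl]

  starts <- (seq_len(nw) - 1) * step
  windows <- data.frame(start = starts, end = starts + window_len,
                        segment = rep(c("pre", "ictal"), c(n_pre, n_post)))
  data <- generate_from_logs(logs, params$priors, params$config,
                             architecture, grid, snr, seed, windows, rho)
  manifest <- list(snr = snr, seed = seed, rho = rho,
                   architecture = architecture,
                   tau_intrinsic = attr(truth, "tau_intrinsic"),
                   tau_extrinsic = attr(truth, "tau_extrinsic"),
                   amplitudes = as.list(attr(truth, "amplitudes")),
                   n_pre = n_pre, n_post = n_post, step = step,
                   grid = range(grid), base_logs = "prior means",
                   package = as.character(utils::packageVersion("synaptrack")))
  structure(list(data = data, noiseless = NULL, truth = truth,
                 truth_logs = logs, snr = snr, seed = seed,
                 manifest = manifest),
            class = "cmc_synth")
}

#' @export
print.cmc_synth <- function(x, ...) {
  cat("Synthetic windowed-CSD dataset (seed", x$seed, ", SNR", x$snr, ")\n")
  print(x$data)
  invisible(x)
}

#' Score parameter recovery against ground truth
#'
#' @param truth a [true_trajectories()] object.
#' @param trajectory a [extract_trajectories()] result from a fit to the
#'   generated data.
#' @return data frame per parameter (plus an `overall` row over changing
#'   parameters): `coverage` (fraction of windows whose credible interval
#'   contains the truth), `bias` and `rmse` of the posterior mean.
#' @export
assess_recovery <- function(truth, trajectory) {
  stopifnot(inherits(truth, "trajectory_truth"),
            inherits(trajectory, "cmc_trajectory"))
  nw <- attr(truth, "n_pre") + attr(truth, "n_post")
  pars <- intersect(colnames(truth), unique(trajectory$parameter))
  if (!length(pars)) stop("no common changing parameters to assess")
  rows <- lapply(pars, function(p) {
    d <- trajectory[trajectory$parameter == p, ]
    if (nrow(d) != nw) stop("window schedule mismatch for ", p,
                            ": ", nrow(d), " vs ", nw)
    tv <- truth[, p]
    data.frame(parameter = p,
               coverage = mean(tv >= d$lo & tv <= d$hi),
               bias = mean(d$mean - tv),
               rmse = sqrt(mean((d$mean - tv)^2)))
  })
  out <- do.call(rbind, rows)
  err <- unlist(lapply(pars, function(p)
    trajectory$mean[trajectory$parameter == p] - truth[, p]))
  cov <- unlist(lapply(pars, function(p) {
    d <- trajectory[trajectory$parameter == p, ]
    truth[, p] >= d$lo & truth[, p] <= d$hi
  }))
  rbind(out, data.frame(parameter = "overall", coverage = mean(cov),
                        bias = mean(err), rmse = sqrt(mean(err^2))))
}
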