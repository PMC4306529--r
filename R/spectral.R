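# Spectral forward model: transfer functions of the linearized delay system
# and predicted complex cross-spectral densities over channels.

#' Frequency grid
#'
#' Strictly increasing analysis frequencies in Hz.  The default covers
#' 8-48 Hz in 1-Hz bins, removing slow (theta-range) fluctuations while
#' retaining beta/low-gamma activity.
#'
#' @param from,to band edges in Hz.
#' @param by bin width in Hz.
#' @return numeric vector of frequencies.
#' @export
frequency_grid <- function(from = 8, to = 48, by = 1) {
  stopifnot(from > 0, to > from, by > 0)
  f <- seq(from, to, by = by)
  if (length(f) < 2) stop("frequency grid must contain at least 2 bins")
  f
}

#' Power-law spectral density
#'
#' `g(f) = amp * f^(-exponent)` on the grid; used for both the endogenous
#' neuronal input and the measurement-noise spectra (one-sided densities).
#'
#' @param amp amplitude (>= 0).
#' @param exponent power-law exponent.
#' @param grid frequency grid in Hz.
#' @return numeric vector of spectral densities.
#' @export
powerlaw_spectrum <- function(amp, exponent, grid) {
  stopifnot(amp >= 0)
  amp * grid^(-exponent)
}

#' Modulation transfer functions
#'
#' Frequency response of the linearized delay system mapping endogenous
#' input fluctuations at each source to the observed channels,
#' `T(f) = L (i 2 pi f I - A(f))^-1 B`, where the conduction delays enter as
#' exact phase factors `exp(-i 2 pi f tau)` on the delayed couplings.
#'
#' @param statespace linearization from [cmc_statespace()].
#' @param grid frequency grid (Hz).
#' @return complex array channels x sources x frequencies.
#' @export
transfer_function <- function(statespace, grid) {
  T <- cmc_transfer_cpp(statespace$A0, statespace$Ai, statespace$Ae,
                        statespace$B, statespace$L,
                        statespace$tau_i, statespace$tau_e, grid)
  dimnames(T) <- list(channel = NULL, source = NULL, frequency = NULL)
  attr(T, "freq") <- grid
  T
}

# Measurement-noise cross-spectra: a channel-specific power-law term on the
# diagonal plus a common-mode power-law term shared by all channel pairs.
noise_csd <- function(amp, exponent, grid, n_channels = 2,
                      common_frac = 0.25, scale = 1) {
  sn <- scale * powerlaw_spectrum(amp, exponent, grid)
  Gn <- array(rep(common_frac * sn, each = n_channels * n_channels),
              dim = c(n_channels, n_channels, length(grid)))
  for (c in seq_len(n_channels)) Gn[c, c, ] <- Gn[c, c, ] + sn
  Gn
}

# Fast internal path used by the inversion: full log-scaling vector ->
# predicted CSD array, with an optional stability guard that signals a
# condition instead of returning meaningless spectra.
predict_csd_logs <- function(comp, logs, grid, guard = TRUE) {
  ss <- statespace_from_logs(comp, logs)
  amp <- comp$inamp_mean * exp(logs[comp$inamp_par]) * comp$config$input_scale
  iexp <- comp$inexp_mean * exp(logs[comp$inexp_par])
  Gu <- cbind(powerlaw_spectrum(amp[1], iexp, grid),
              powerlaw_spectrum(amp[2], iexp, grid))
  Gn <- noise_csd(comp$namp_mean * exp(logs[comp$namp_par]),
                  comp$nexp_mean * exp(logs[comp$nexp_par]),
                  grid, common_frac = comp$config$noise_common_frac,
                  scale = comp$config$noise_scale)
  tryCatch(
    cmc_csd_cpp(ss$A0, ss$Ai, ss$Ae, ss$B, ss$L, ss$tau_i, ss$tau_e,
                grid, Gu, Gn, guard),
    error = function(e) {
      if (grepl("unstable", conditionMessage(e)))
        stop(structure(class = c("cmc_unstable", "error", "condition"),
                       list(message = "unstable linearization", call = NULL)))
      stop(e)
    })
}

#' Predicted cross-spectral density
#'
#' The spectral forward model: `G_y(f) = T(f) G_u(f) T(f)^H + G_n(f)`,
#' with `T` the modulation transfer functions, `G_u` the (source-wise,
#' independent) endogenous power-law input spectra and `G_n` the
#' measurement-noise cross-spectra (channel-specific plus common-mode
#' power-law terms).  The result is Hermitian at every frequency with a
#' real, non-negative neuronal diagonal.
#'
#' @param params a [cmc_parameters()] object.
#' @param grid frequency grid in Hz (default [frequency_grid()]).
#' @param architecture extrinsic architecture.
#' @return complex array `channels x channels x frequencies` with the grid
#'   attached as attribute `freq`.
#' @export
predict_csd <- function(params, grid = frequency_grid(),
                        architecture = "fw_primary") {
  rp <- resolve_params(params, architecture)
  G <- predict_csd_logs(rp$comp, rp$logs, grid)
  attr(G, "freq") <- grid
  G
}

#' Validate a stack of cross-spectral matrices
#'
#' Checks the defining invariants of a CSD: Hermitian symmetry at every
#' frequency and (optionally) a real, non-negative diagonal.
#'
#' @param G complex array channels x channels x frequencies.
#' @param strict also require non-negative diagonal (appropriate for
#'   noiseless model predictions; sampling noise can produce small negative
#'   diagonal excursions in estimates).
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; signals an error on violation.
#' @export
validate_csd <- function(G, strict = TRUE, tol = 1e-8) {
  stopifnot(is.array(G), length(dim(G)) == 3, dim(G)[1] == dim(G)[2])
  sc <- max(abs(G), 1e-300)
  for (k in seq_len(dim(G)[3])) {
    M <- G[, , k]
    if (max(abs(M - Conj(t(M)))) > tol * sc)
      stop("CSD not Hermitian at frequency index ", k)
    if (strict && any(Re(diag(M)) < -tol * sc))
      stop("negative diagonal CSD at frequency index ", k)
  }
  invisible(TRUE)
}
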