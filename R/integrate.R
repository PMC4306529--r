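# Time-domain simulation of the nonlinear delay model: simulated seizure-
# like responses to random fluctuating input, and an independent oracle for
# the spectral forward model.

#' Power-law (1/f-like) random drive
#'
#' Gaussian noise spectrally shaped so that its one-sided power spectral
#' density equals `amp * f^(-exponent)` (flattened below `f_min` to keep the
#' variance finite).  Used as the endogenous fluctuation driving the input
#' cells.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param amp,exponent power-law amplitude and exponent.
#' @param n_series number of independent series (columns).
#' @param f_min flattening frequency (Hz).
#' @param seed optional integer seed.
#' @return matrix `n x n_series`.
#' @export
powerlaw_drive <- function(n, fs, amp = 1, exponent = 1, n_series = 2,
                           f_min = 1, seed = NULL) {
  stopifnot(n > 8, fs > 0, amp >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, n, n_series)
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  S <- amp * pmax(f, f_min)^(-exponent)
  for (j in seq_len(n_series)) {
    X <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
    X <- X * sqrt(S * fs * n / 2)
    if (n %% 2 == 0) X[nf] <- complex(real = sqrt(2) * Re(X[nf]))
    spec <- c(0 + 0i, X, Conj(rev(X[seq_len(nf - 1 + n %% 2)])))
    out[, j] <- Re(fft(spec, inverse = TRUE)) / n
  }
  out
}

#' Integrate the two-source CMC model
#'
#' Fixed-step delay-aware RK4 integration of the nonlinear equations of
#' motion, with a ring history of delayed depolarisations (linear
#' interpolation within the step grid).  With a fixed seed and drive the
#' output is bit-reproducible.  The observation is the depolarisation of the
#' superficial pyramidal cells scaled by the electrode gain.
#'
#' @param params a [cmc_parameters()] object.
#' @param duration simulated time (s).
#' @param dt integration step (ms); must not exceed the smallest conduction
#'   delay.  The default gives an output rate of 2048 Hz before decimation.
#' @param drive optional matrix (`n_steps + 1` rows, one column per source)
#'   of exogenous drive sampled on the integration grid; if `NULL`, a
#'   seeded power-law drive at the parameter set's input amplitude/exponent
#'   is generated.
#' @param seed seed for the generated drive.
#' @param architecture extrinsic architecture.
#' @param fs_out output sampling rate (Hz); must divide `1000 / dt`.
#' @param init initial state (defaults to the origin fixed point).
#' @param keep_states return the full thinned state matrix.
#' @return list with `time` (s), `output` (channels x samples), `fs`,
#'   and optionally `states`.
#' @export
cmc_integrate <- function(params, duration, dt = 1000 / 2048, drive = NULL,
                          seed = NULL, architecture = "fw_primary",
                          fs_out = 256, init = NULL, keep_states = FALSE) {
  stopifnot(duration > 0, dt > 0)
  rp <- resolve_params(params, architecture)
  comp <- rp$comp
  ss <- statespace_from_logs(comp, rp$logs)
  if (dt / 1000 > min(ss$tau_i, ss$tau_e))
    stop("dt must be smaller than the smallest conduction delay")
  fs_int <- 1000 / dt
  keep_every <- round(fs_int / fs_out)
  if (abs(keep_every - fs_int / fs_out) > 1e-9)
    stop("fs_out must divide the integration rate 1000/dt")
  n_steps <- ceiling(duration * fs_int)

  if (is.null(drive)) {
    eff <- effective_values(params)
    drive <- powerlaw_drive(n_steps + 1, fs_int,
                            amp = comp$config$input_scale,
                            exponent = eff["input_exp"], n_series = 2,
                            seed = seed)
    drive <- drive %*% diag(sqrt(eff[c("input_amp_s1", "input_amp_s2")]))
  }
  if (nrow(drive) < n_steps + 1) stop("drive series shorter than n_steps + 1")

  ed <- comp$edges
  w <- ed$sign * ed$mean * exp(rp$logs[ed$par])
  edges <- cbind(ed$tgt - 1, ed$src - 1, w, ed$grp)
  dw <- numeric(comp$np); dcol <- rep(-1L, comp$np)
  dw[comp$drive_gpop] <- 1
  dcol[comp$drive_gpop] <- 0:1
  if (is.null(init)) init <- numeric(comp$nx)

  X <- cmc_integrate_cpp(ss$kappa, edges, ss$gamma, ss$tau_i, ss$tau_e,
                         drive[seq_len(n_steps + 1), , drop = FALSE],
                         dw, as.integer(dcol), dt / 1000, init,
                         as.integer(keep_every))
  gain <- comp$gain_mean * exp(rp$logs[comp$gain_par])
  out <- rbind(gain[1] * X[comp$obs_gpop[1], ],
               gain[2] * X[comp$obs_gpop[2], ])
  res <- list(time = (seq_len(ncol(X)) - 1) / fs_out, output = out,
              fs = fs_out)
  if (keep_states) res$states <- X
  res
}
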