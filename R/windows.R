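# Locally stationary windowing and cross-spectral estimation.

#' Partition a segment into overlapping windows
#'
#' Maximal list of equal-length windows with the stated fractional overlap
#' covering `[0, duration]`; bounds are half-open `[start, end)` seconds.
#' Two 10-s segments with 2-s windows at 50% overlap give the 18-window
#' layout used around a state transition (9 pre + 9 post).
#'
#' @param duration segment length (s).
#' @param window_len window length (s).
#' @param overlap_frac fractional overlap in `[0, 1)`.
#' @return data frame with columns `start`, `end`.
#' @export
segment_windows <- function(duration, window_len, overlap_frac = 0.5) {
  if (!(window_len > 0 && window_len <= duration))
    stop("infeasible window geometry: need 0 < window_len <= duration")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  step <- window_len * (1 - overlap_frac)
  starts <- seq(0, duration - window_len + 1e-9, by = step)
  data.frame(start = starts, end = starts + window_len)
}

#' Windows around an onset
#'
#' Convenience layout: `pre` seconds before and `post` seconds after an
#' onset time, each partitioned by [segment_windows()], with segment labels
#' `"pre"` / `"ictal"`.
#'
#' @param onset onset time (s, in recording time).
#' @param pre,post segment durations (s).
#' @param window_len,overlap_frac window geometry.
#' @return data frame `start`, `end`, `segment`.
#' @export
epoch_windows <- function(onset, pre = 10, post = 10, window_len = 2,
                          overlap_frac = 0.5) {
  wpre <- segment_windows(pre, window_len, overlap_frac)
  wpost <- segment_windows(post, window_len, overlap_frac)
  rbind(
    data.frame(start = wpre$start + onset - pre, end = wpre$end + onset - pre,
               segment = "pre"),
    data.frame(start = wpost$start + onset, end = wpost$end + onset,
               segment = "ictal")
  )
}

#' Windowed cross-spectral container
#'
#' @param csd complex array channels x channels x frequencies x windows.
#' @param freq frequency grid (Hz).
#' @param windows data frame with `start`, `end` and optionally `segment`.
#' @param channels channel labels.
#' @param meta named list of estimation metadata.
#' @return object of class `windowed_csd`.
#' @export
windowed_csd <- function(csd, freq, windows, channels = NULL, meta = list()) {
  stopifnot(length(dim(csd)) == 4, dim(csd)[3] == length(freq),
            dim(csd)[4] == nrow(windows))
  if (is.unsorted(windows$start)) stop("windows must be time-ordered")
  if (is.null(windows$segment)) windows$segment <- NA_character_
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(csd)[1]))
  structure(list(csd = csd, freq = freq, windows = windows,
                 channels = channels, meta = meta),
            class = "windowed_csd")
}

#' @export
print.windowed_csd <- function(x, ...) {
  cat(sprintf("Windowed CSD: %d windows x %d frequencies (%g-%g Hz), %d channels\n",
              nrow(x$windows), length(x$freq), min(x$freq), max(x$freq),
              dim(x$csd)[1]))
  if (!all(is.na(x$windows$segment)))
    cat("Segments:", paste(sprintf("%s (%d)", unique(x$windows$segment),
        table(x$windows$segment)[unique(x$windows$segment)]), collapse = ", "),
        "\n")
  if (length(x$meta)) cat("Estimator:", x$meta$method %||% "?", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sine_tapers <- function(n, k) {
  t <- seq_len(n)
  sapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1)))
}

# One-sided cross-spectral density (units^2/Hz) of one multichannel segment.
csd_multitaper <- function(x, fs, grid, n_tapers) {
  n <- nrow(x); nc <- ncol(x)
  x <- sweep(x, 2, colMeans(x))
  W <- sine_tapers(n, n_tapers)
  E <- exp(-2i * pi * outer(seq_len(n) / fs, grid))   # n x nf
  G <- array(0 + 0i, c(nc, nc, length(grid)))
  for (k in seq_len(n_tapers)) {
    X <- t(x * W[, k]) %*% E                          # nc x nf
    for (f in seq_along(grid))
      G[, , f] <- G[, , f] + X[, f] %*% Conj(t(X[, f, drop = FALSE]))
  }
  2 * G / (fs * n_tapers)
}

# One-sided CSD from a vector-autoregressive fit (Yule-Walker), evaluated
# on the grid through the transfer function of the fitted filter.
csd_var <- function(x, fs, grid, order) {
  nc <- ncol(x)
  fit <- ar(x, aic = FALSE, order.max = order, method = "yule-walker",
            demean = TRUE)
  A <- fit$ar                                 # order x nc x nc
  Sig <- as.matrix(fit$var.pred)
  G <- array(0 + 0i, c(nc, nc, length(grid)))
  for (f in seq_along(grid)) {
    H <- diag(nc) + 0i
    for (j in seq_len(order))
      H <- H - matrix(A[j, , ], nc, nc) * exp(-2i * pi * grid[f] * j / fs)
    Hi <- solve(H)
    G[, , f] <- 2 * (Hi %*% Sig %*% Conj(t(Hi))) / fs
  }
  G
}

#' Estimate windowed cross-spectral densities
#'
#' Summarizes a recording by the complex cross-spectra of successive
#' windows.  Two estimators are provided: a vector-autoregressive spectral
#' estimate (default; smooth, suited to 2-s windows) and a sine-taper
#' multitaper cross-periodogram (nonparametric cross-check).  Spectra are
#' one-sided densities in (input units)^2/Hz; the estimator and its
#' order/taper settings are recorded in the metadata.
#'
#' @param rec a [recording()].
#' @param windows data frame `start`, `end` (s; half-open, recording time)
#'   and optional `segment` labels, e.g. from [epoch_windows()].
#' @param grid frequency grid (Hz).
#' @param method `"var"` or `"multitaper"`.
#' @param order VAR model order.
#' @param n_tapers number of sine tapers.
#' @return a [windowed_csd()].
#' @export
estimate_csd <- function(rec, windows, grid = frequency_grid(),
                         method = c("var", "multitaper"), order = 8,
                         n_tapers = 7) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "recording"))
  fs <- rec$rate
  nt <- ncol(rec$samples)
  nc <- nrow(rec$samples)
  if (any(windows$start < 0) || any(windows$end > nt / fs + 1e-9))
    stop("windows outside recording bounds")
  if (any(windows$end - windows$start < 1 / min(grid)))
    stop("window shorter than one cycle of the lowest modelled frequency")
  nf <- length(grid)
  nw <- nrow(windows)
  G <- array(0 + 0i, c(nc, nc, nf, nw))
  for (w in seq_len(nw)) {
    i0 <- floor(windows$start[w] * fs) + 1
    i1 <- floor(windows$end[w] * fs)
    x <- t(rec$samples[, i0:min(i1, nt), drop = FALSE])
    Gw <- switch(method,
                 var = csd_var(x, fs, grid, order),
                 multitaper = csd_multitaper(x, fs, grid, n_tapers))
    for (f in seq_len(nf))                       # enforce exact symmetry
      Gw[, , f] <- (Gw[, , f] + Conj(t(Gw[, , f]))) / 2
    G[, , , w] <- Gw
  }
  meta <- list(method = method,
               order = if (method == "var") order else NULL,
               n_tapers = if (method == "multitaper") n_tapers else NULL,
               rate = fs)
  windowed_csd(G, grid, windows, rec$labels, meta)
}

#' Serialize a windowed CSD to JSON
#'
#' Lossless structured-text serialization (dimensions, frequency grid,
#' window table, real and imaginary parts).
#'
#' @param x a [windowed_csd()].
#' @param path output path (`.json`).
#' @return the path / the restored object.
#' @export
write_windowed_csd <- function(x, path) {
  stopifnot(inherits(x, "windowed_csd"))
  obj <- list(dim = dim(x$csd), freq = x$freq, windows = x$windows,
              channels = x$channels, meta = x$meta,
              re = as.vector(Re(x$csd)), im = as.vector(Im(x$csd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_windowed_csd
#' @export
read_windowed_csd <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  csd <- array(complex(real = o$re, imaginary = o$im), dim = o$dim)
  windowed_csd(csd, o$freq, as.data.frame(o$windows), o$channels,
               as.list(o$meta))
}
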