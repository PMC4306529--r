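# Multichannel recordings: construction, I/O (EDF and delimited text),
# bipolar montage and zero-phase band-pass filtering.

#' Construct a multichannel recording
#'
#' @param samples numeric matrix, channels x time (microvolts).
#' @param rate sampling rate in Hz.
#' @param labels unique channel labels.
#' @param annotations optional list of epoch annotations (e.g. `onset`
#'   time in seconds, segment bounds).
#' @return object of class `recording`.
#' @export
recording <- function(samples, rate, labels = rownames(samples),
                      annotations = list()) {
  samples <- as.matrix(samples)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  if (rate <= 0) stop("sampling rate must be positive")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (length(labels) != nrow(samples))
    stop("number of labels does not match number of channels")
  rownames(samples) <- labels
  structure(list(samples = samples, rate = rate, labels = labels,
                 annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat("Channels:", paste(x$labels, collapse = ", "), "\n")
  if (length(x$annotations))
    cat("Annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Read a recording from EDF or delimited text
#'
#' Text files carry one column per channel with a header row of channel
#' labels; the sampling rate comes from a leading comment line of the form
#' `# sampling_rate: 256`, from a YAML sidecar `<path>.yaml` with a
#' `sampling_rate` key, or from the `rate` argument.  EDF files (European
#' Data Format, 16-bit) are parsed directly; all signals must share one
#' sampling rate.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @param rate sampling rate override for text input (Hz).
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "text"),
                           rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  switch(format, edf = read_edf(path), text = read_recording_text(path, rate))
}

read_recording_text <- function(path, rate = NULL) {
  first <- readLines(path, n = 1)
  skip <- 0
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("sampling_rate[:=]\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2) rate <- as.numeric(m[2])
    skip <- 1
  }
  if (is.null(rate)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      y <- yaml::read_yaml(sidecar)
      rate <- y$sampling_rate
    }
  }
  if (is.null(rate))
    stop("sampling rate missing: supply `rate`, a '# sampling_rate:' header ",
         "line, or a YAML sidecar")
  dat <- read.table(path, header = TRUE, sep = "", skip = skip,
                    check.names = FALSE)
  recording(t(as.matrix(dat)), rate = rate, labels = colnames(dat))
}

#' Write a recording as delimited text
#'
#' One column per channel, header row of labels, preceded by a
#' `# sampling_rate:` comment line, so the file round-trips through
#' [read_recording()].
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %.10g", rec$rate), con)
  writeLines(paste(rec$labels, collapse = "\t"), con)
  write.table(t(rec$samples), con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# --- EDF (European Data Format) ------------------------------------------

edf_field <- function(raw, at, len) {
  if (at + len - 1 > length(raw))
    stop("truncated EDF file: expected header field at byte offset ", at)
  trimws(rawToChar(raw[at:(at + len - 1)]))
}

#' @rdname read_recording
#' @export
read_edf <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 256) stop("truncated EDF file: header ends at byte offset ",
                              length(raw), ", need 256")
  n_rec <- as.integer(edf_field(raw, 237, 8))
  rec_dur <- as.numeric(edf_field(raw, 245, 8))
  ns <- as.integer(edf_field(raw, 253, 4))
  if (is.na(ns) || ns < 1) stop("invalid EDF: bad signal count field")
  hdr_len <- 256L + 256L * ns
  if (length(raw) < hdr_len)
    stop("truncated EDF file: signal headers end at byte offset ",
         length(raw), ", need ", hdr_len)
  sig_field <- function(off, len, i)  # per-signal fields are stored blockwise
    edf_field(raw, 256L + off * ns + (i - 1L) * len + 1L, len)
  labels <- vapply(1:ns, function(i) sig_field(0L, 16L, i), "")
  phys_min <- as.numeric(vapply(1:ns, function(i) sig_field(104L, 8L, i), ""))
  phys_max <- as.numeric(vapply(1:ns, function(i) sig_field(112L, 8L, i), ""))
  dig_min <- as.numeric(vapply(1:ns, function(i) sig_field(120L, 8L, i), ""))
  dig_max <- as.numeric(vapply(1:ns, function(i) sig_field(128L, 8L, i), ""))
  nsamp <- as.integer(vapply(1:ns, function(i) sig_field(216L, 8L, i), ""))

  keep <- labels != "EDF Annotations"
  if (length(unique(nsamp[keep])) != 1)
    stop("non-uniform sampling: EDF signals have different rates")
  need <- hdr_len + 2 * sum(nsamp) * n_rec
  if (length(raw) > hdr_len && length(raw) < need)
    stop("truncated EDF file: data end at byte offset ", length(raw),
         ", need ", need)
  ints <- readBin(raw[-seq_len(hdr_len)], "integer", n = sum(nsamp) * n_rec,
                  size = 2, endian = "little")
  rate <- nsamp[keep][1] / rec_dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offs <- cumsum(c(0, nsamp))
  out <- matrix(0, sum(keep), nsamp[keep][1] * n_rec)
  row <- 0
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    row <- row + 1
    for (r in seq_len(n_rec)) {
      d <- ints[(r - 1) * sum(nsamp) + offs[i] + seq_len(nsamp[i])]
      out[row, (r - 1) * nsamp[i] + seq_len(nsamp[i])] <-
        phys_min[i] + scale[i] * (d - dig_min[i])
    }
  }
  recording(out, rate = rate, labels = labels[keep])
}

#' Write a recording to EDF
#'
#' Minimal EDF writer (16-bit, one data record per second); mainly used to
#' build test fixtures and export simulations.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  fs <- rec$rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer rate")
  n_rec <- floor(ncol(rec$samples) / fs)
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin <- apply(x, 1, min) - 1e-6
  pmax <- apply(x, 1, max) + 1e-6
  dmin <- -32768; dmax <- 32767
  pad <- function(s, n) formatC(substr(s, 1, n), width = -n)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(as.character(256 + 256 * ns), 8), pad("", 44),
                pad(as.character(n_rec), 8), pad("1", 8),
                pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  blk <- function(vals, n) paste(vapply(vals, pad, "", n = n), collapse = "")
  writeChar(paste0(blk(rec$labels, 16), blk(rep("", ns), 80),
                   blk(rep("uV", ns), 8),
                   blk(formatC(pmin, format = "g", digits = 6), 8),
                   blk(formatC(pmax, format = "g", digits = 6), 8),
                   blk(rep(as.character(dmin), ns), 8),
                   blk(rep(as.character(dmax), ns), 8),
                   blk(rep("", ns), 80), blk(rep(as.character(fs), ns), 8),
                   blk(rep("", ns), 32)),
            con, eos = NULL)
  for (r in seq_len(n_rec)) for (i in seq_len(ns)) {
    seg <- x[i, (r - 1) * fs + seq_len(fs)]
    dig <- round(dmin + (seg - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Bipolar montage
#'
#' Re-references a recording to a series of bipolar derivations: each output
#' channel is the difference of a pair of input channels (first minus
#' second), labelled `"A-B"`.  Acts as a spatial filter rejecting
#' common-mode activity.
#'
#' @param rec a [recording()].
#' @param pairs list of length-2 character vectors of channel labels.
#' @return a [recording()] with one channel per pair.
#' @export
bipolar_montage <- function(rec, pairs) {
  stopifnot(inherits(rec, "recording"), length(pairs) >= 1)
  out <- matrix(0, length(pairs), ncol(rec$samples))
  labs <- character(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    if (length(pr) != 2) stop("each montage pair must have exactly 2 labels")
    miss <- setdiff(pr, rec$labels)
    if (length(miss)) stop("unknown channel label(s): ",
                           paste(miss, collapse = ", "))
    out[i, ] <- rec$samples[pr[1], ] - rec$samples[pr[2], ]
    labs[i] <- paste0(pr[1], "-", pr[2])
  }
  recording(out, rec$rate, labs, rec$annotations)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' giving zero phase distortion — cross-spectral phase relations, which the
#' model must explain, are preserved.  The high-pass edge removes DC.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz; `0 < low < high < rate / 2`.
#' @param order filter order (per direction).
#' @return the filtered [recording()].
#' @export
bandpass <- function(rec, low = 0.5, high = 48, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filt <- t(apply(rec$samples, 1, function(x) signal::filtfilt(bf, x)))
  recording(filt, rec$rate, rec$labels, rec$annotations)
}
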