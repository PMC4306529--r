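# Lossless real embedding of windowed complex cross-spectra: the data
# features fitted by the inversion.

#' Featurize windowed cross-spectra
#'
#' Maps a stack of Hermitian CSD matrices to a real vector: per window and
#' frequency, the real parts of the upper triangle including the diagonal
#' followed by the imaginary parts of the strict upper triangle (for two
#' channels: `Re G11, Re G22, Re G12, Im G12`).  The embedding is lossless;
#' an index map back to `(window, frequency, i, j, part)` is attached.
#'
#' @param data a [windowed_csd()] or a complex array
#'   channels x channels x frequencies x windows.
#' @return numeric vector of class `csd_features` with attributes `map`
#'   (index data frame), `dim4`, `freq`.
#' @param map build the index-map attribute (skipped in inner loops).
#' @export
featurize <- function(data, map = TRUE) {
  arr <- if (inherits(data, "windowed_csd")) data$csd else data
  stopifnot(length(dim(arr)) == 4)
  nc <- dim(arr)[1]; nf <- dim(arr)[3]; nw <- dim(arr)[4]
  ut <- which(upper.tri(diag(nc), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  st <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  st <- st[order(st[, 2], st[, 1]), , drop = FALSE]
  nre <- nrow(ut); nim <- nrow(st)
  blk <- matrix(0, nre + nim, nf * nw)
  flat <- matrix(arr, nc * nc, nf * nw)
  for (r in seq_len(nre))
    blk[r, ] <- Re(flat[(ut[r, 2] - 1) * nc + ut[r, 1], ])
  for (r in seq_len(nim))
    blk[nre + r, ] <- Im(flat[(st[r, 2] - 1) * nc + st[r, 1], ])
  y <- as.vector(blk)
  if (!map) return(structure(y, dim4 = dim(arr), class = "csd_features"))
  map <- data.frame(
    window = rep(seq_len(nw), each = (nre + nim) * nf),
    freq_index = rep(rep(seq_len(nf), each = nre + nim), nw),
    i = rep(c(ut[, 1], st[, 1]), nf * nw),
    j = rep(c(ut[, 2], st[, 2]), nf * nw),
    part = rep(c(rep("re", nre), rep("im", nim)), nf * nw)
  )
  structure(y, map = map, dim4 = dim(arr),
            freq = if (inherits(data, "windowed_csd")) data$freq else NULL,
            class = "csd_features")
}

#' @rdname featurize
#' @param y a `csd_features` vector (or any numeric vector with the same
#'   layout, given `dim`).
#' @param dim original array dimensions (taken from the `dim4` attribute
#'   when absent).
#' @return `defeaturize` returns the complex array.
#' @export
defeaturize <- function(y, dim = attr(y, "dim4")) {
  stopifnot(!is.null(dim), length(dim) == 4)
  nc <- dim[1]; nf <- dim[3]; nw <- dim[4]
  ut <- which(upper.tri(diag(nc), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  st <- which(upper.tri(diag(nc)), arr.ind = TRUE)
  st <- st[order(st[, 2], st[, 1]), , drop = FALSE]
  nre <- nrow(ut); nim <- nrow(st)
  blk <- matrix(as.numeric(y), nre + nim, nf * nw)
  flat <- matrix(0 + 0i, nc * nc, nf * nw)
  for (r in seq_len(nre)) {
    idx <- (ut[r, 2] - 1) * nc + ut[r, 1]
    flat[idx, ] <- flat[idx, ] + blk[r, ]
  }
  for (r in seq_len(nim)) {
    idx <- (st[r, 2] - 1) * nc + st[r, 1]
    flat[idx, ] <- flat[idx, ] + 1i * blk[nre + r, ]
  }
  arr <- array(flat, dim)
  for (w in seq_len(nw)) for (f in seq_len(nf)) {   # mirror lower triangle
    M <- arr[, , f, w]
    M[lower.tri(M)] <- Conj(t(M))[lower.tri(M)]
    arr[, , f, w] <- M
  }
  arr
}
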