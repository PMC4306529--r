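# Candidate change-models, polynomial temporal bases for slow parameter
# trajectories, Bayesian model comparison and updating.

change_factors <- c("intrinsic1", "intrinsic2", "forward", "backward")

#' Specify a change-model
#'
#' A candidate model is an extrinsic architecture (which source originates
#' the forward connection) plus four binary flags saying which couplings may
#' change over windows — intrinsic gain (superficial-pyramidal
#' self-inhibition) in each source, and the forward and backward extrinsic
#' strengths — together with the order of the polynomial temporal basis per
#' segment.
#'
#' @param architecture `"fw_primary"` (forward connection originates in the
#'   primary source) or `"bw_primary"`.
#' @param changes character subset of
#'   `c("intrinsic1", "intrinsic2", "forward", "backward")`, or a named/
#'   unnamed logical vector of length 4.
#' @param basis_order polynomial order per segment (default 3).
#' @param n_pre,n_post number of pre- and post-transition windows.
#' @return object of class `model_spec` with a stable identifier, e.g.
#'   `"FW-1100"`.
#' @export
model_spec <- function(architecture = "fw_primary", changes = character(),
                       basis_order = 3, n_pre = 9, n_post = 9) {
  architecture <- match.arg(architecture, cmc_architectures)
  if (is.logical(changes)) {
    stopifnot(length(changes) == 4)
    flags <- setNames(changes, change_factors)
  } else {
    stopifnot(all(changes %in% change_factors))
    flags <- setNames(change_factors %in% changes, change_factors)
  }
  stopifnot(basis_order >= 0, n_pre >= basis_order + 1,
            n_post >= basis_order + 1)
  id <- paste0(if (architecture == "fw_primary") "FW" else "BW", "-",
               paste(as.integer(flags), collapse = ""))
  structure(list(architecture = architecture, flags = flags,
                 basis_order = basis_order, n_pre = n_pre, n_post = n_post,
                 id = id),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat("Model", x$id, "—", x$architecture, "architecture;",
      if (length(on)) paste("changes in:", paste(on, collapse = ", "))
      else "no changing couplings (null model)",
      sprintf("; basis order %d over %d + %d windows\n",
              x$basis_order, x$n_pre, x$n_post))
  invisible(x)
}

#' Enumerate the candidate change-models
#'
#' All combinations of the four change factors (binary counting over
#' intrinsic source 1, intrinsic source 2, forward, backward), giving 16
#' models with stable identifiers.
#'
#' @inheritParams model_spec
#' @param factors factors to combine (default all four).
#' @return list of [model_spec()] objects.
#' @export
enumerate_models <- function(basis_order = 3, architecture = "fw_primary",
                             n_pre = 9, n_post = 9,
                             factors = change_factors) {
  k <- length(factors)
  lapply(0:(2^k - 1), function(i) {
    bits <- as.logical(bitwAnd(i, 2^((k - 1):0)) > 0)
    fl <- setNames(rep(FALSE, 4), change_factors)
    fl[factors] <- bits
    model_spec(architecture, fl, basis_order, n_pre, n_post)
  })
}

#' Polynomial temporal basis for slow trajectories
#'
#' Block design matrix mapping basis coefficients to per-window parameter
#' deviations: an independent orthonormal polynomial basis (constant through
#' `order`) for the pre- and post-transition segments, allowing a
#' discontinuity at the transition.  Columns are orthonormal within each
#' segment block and the matrix has full column rank.
#'
#' @param n_pre,n_post windows per segment.
#' @param order polynomial order.
#' @return matrix `(n_pre + n_post) x (2 (order + 1))`.
#' @export
temporal_basis <- function(n_pre, n_post, order = 3) {
  stopifnot(order >= 0)
  if (n_pre < order + 1 || n_post < order + 1)
    stop("rank-deficient basis: need at least order + 1 windows per segment")
  seg <- function(n) {
    X <- matrix(1 / sqrt(n), n, 1)
    if (order > 0) X <- cbind(X, poly(seq_len(n), order))
    X
  }
  Xp <- seg(n_pre); Xq <- seg(n_post)
  X <- matrix(0, n_pre + n_post, ncol(Xp) + ncol(Xq))
  X[seq_len(n_pre), seq_len(ncol(Xp))] <- Xp
  X[n_pre + seq_len(n_post), ncol(Xp) + seq_len(ncol(Xq))] <- Xq
  colnames(X) <- c(paste0("pre_c", 0:order), paste0("post_c", 0:order))
  X
}

# Map change flags to the underlying log-scaling parameter names.
flag_params <- function(config = cmc_config()) {
  edge <- config$free_intrinsic[1]
  c(intrinsic1 = paste0("int_", edge, "_s1"),
    intrinsic2 = paste0("int_", edge, "_s2"),
    forward = "ext_fw", backward = "ext_bw")
}

#' Expand base parameters into a per-window sequence
#'
#' Window `w` receives the base log-scalings with each flagged parameter
#' incremented by `basis[w, ] %*% coefficients` for its coefficient block;
#' unflagged parameters are identical across windows.
#'
#' @param base a [cmc_parameters()] object (the shared parameters).
#' @param coefficients named numeric vector of basis coefficients, names
#'   `traj_<flag>_<column>` as produced by [fit_cmc_csd()], or a matrix with
#'   one column per flagged factor.
#' @param basis design matrix from [temporal_basis()].
#' @param flags logical vector over the change factors.
#' @return matrix `n_windows x n_params` of log-scalings.
#' @export
expand_parameters <- function(base, coefficients, basis, flags) {
  stopifnot(inherits(base, "cmc_parameters"))
  fp <- flag_params(base$config)
  on <- names(flags)[flags]
  nb <- ncol(basis)
  logs <- matrix(rep(base$logs, each = nrow(basis)), nrow(basis),
                 length(base$logs), dimnames = list(NULL, names(base$logs)))
  if (!length(on)) {
    if (length(coefficients)) stop("coefficients given but no flag is set")
    return(logs)
  }
  if (is.matrix(coefficients)) {
    stopifnot(ncol(coefficients) == length(on), nrow(coefficients) == nb)
    B <- coefficients
  } else {
    if (length(coefficients) != nb * length(on))
      stop("coefficient length does not match flags x basis columns")
    B <- matrix(coefficients, nb, length(on))
  }
  dev <- basis %*% B
  for (k in seq_along(on)) logs[, fp[on[k]]] <- logs[, fp[on[k]]] + dev[, k]
  logs
}

#' Bayesian model comparison with evidence pooled over sessions
#'
#' Fixed-effects pooling: the pooled log evidence of a model is the sum of
#' its per-session variational free energies; posterior model probabilities
#' are softmax-normalized pooled evidences over the included models.
#' Models missing a session (e.g. non-convergent inversions) are excluded.
#' A log-evidence difference of 3 corresponds to odds of about 20:1.
#'
#' @param evidences numeric matrix models x sessions of free energies (NA
#'   marks a failed/missing inversion), with model identifiers as row
#'   names; or a data frame with columns `model`, `session`, `F`.
#' @param exclude optional character vector of model ids to exclude, with
#'   names giving reasons.
#' @return object of class `cmc_bms`: a table of pooled evidences and
#'   posterior probabilities plus the excluded models.
#' @export
compare_models <- function(evidences, exclude = NULL) {
  if (is.data.frame(evidences)) {
    stopifnot(all(c("model", "session", "F") %in% names(evidences)))
    M <- tapply(evidences$F, list(evidences$model, evidences$session),
                function(x) x[1])
  } else M <- as.matrix(evidences)
  if (is.null(rownames(M))) rownames(M) <- paste0("model", seq_len(nrow(M)))
  excluded <- rowSums(is.na(M)) > 0
  reasons <- ifelse(excluded, "missing session / non-convergent", "")
  if (!is.null(exclude)) {
    i <- rownames(M) %in% exclude
    excluded <- excluded | i
    reasons[i] <- if (!is.null(names(exclude)))
      names(exclude)[match(rownames(M)[i], exclude)] else "excluded"
  }
  pooled <- rowSums(M)
  prob <- rep(NA_real_, nrow(M))
  inc <- !excluded
  if (any(inc)) {
    z <- pooled[inc] - max(pooled[inc])
    prob[inc] <- exp(z) / sum(exp(z))
  }
  tab <- data.frame(model = rownames(M), pooled_F = pooled,
                    prob = prob, excluded = excluded, reason = reasons,
                    row.names = NULL)
  structure(list(table = tab[order(-tab$pooled_F), ], evidences = M,
                 n_sessions = ncol(M)),
            class = "cmc_bms")
}

#' @export
print.cmc_bms <- function(x, digits = 2, ...) {
  cat("Bayesian model comparison over", x$n_sessions, "session(s)\n")
  t <- x$table
  t$pooled_F <- round(t$pooled_F - max(t$pooled_F, na.rm = TRUE), digits)
  t$prob <- round(t$prob, 3)
  names(t)[2] <- "rel_log_evidence"
  print(t, row.names = FALSE)
  invisible(x)
}

#' Bayesian updating of priors from a previous session's posterior
#'
#' Carries the posterior means and variances of the base (shared)
#' parameters forward as the next session's priors, while session-specific
#' parameters (by default the electrode gains, which can change from
#' session to session) are reset to their original priors.  The full
#' posterior covariance of the carried block is attached as attribute
#' `"cov"` and used by [fit_cmc_csd()] when present.
#'
#' @param posterior a converged [fit_cmc_csd()] result.
#' @param priors the original `prior_spec`.
#' @param reset names of session-specific parameters to reset.
#' @return an updated `prior_spec` (with a `lmean` column holding the prior
#'   means of the log-scalings).
#' @export
bayesian_update <- function(posterior, priors,
                            reset = c("gain_1", "gain_2")) {
  stopifnot(inherits(posterior, "cmc_dcm"))
  if (!posterior$converged)
    stop("refusing to update from a non-converged posterior")
  validate_priors(priors)
  new <- priors
  if (is.null(new$lmean)) new$lmean <- 0
  base <- intersect(priors$name, names(posterior$posterior$mean))
  carried <- setdiff(base, reset)
  i <- match(carried, priors$name)
  pm <- posterior$posterior$mean[carried]
  pv <- diag(posterior$posterior$cov)[carried]
  est <- pv > 0
  new$lmean[i[est]] <- pm[est]
  new$var[i[est]] <- pv[est]
  cov <- matrix(0, nrow(new), nrow(new),
                dimnames = list(new$name, new$name))
  diag(cov) <- new$var
  cov[carried[est], carried[est]] <-
    posterior$posterior$cov[carried[est], carried[est]]
  attr(new, "cov") <- cov
  new
}

#' Extract posterior trajectories of the changing parameters
#'
#' Per-window posterior mean and 90% credible interval of the log-scaling
#' deviation of every changing parameter, obtained by propagating the
#' posterior of the basis coefficients through the temporal design matrix
#' (a linear transform of the Gaussian posterior).
#'
#' @param fit a [fit_cmc_csd()] result.
#' @param level credible level (default 0.90).
#' @return data frame of class `cmc_trajectory`: `window`, `segment`,
#'   `parameter`, `mean`, `sd`, `lo`, `hi`.
#' @export
extract_trajectories <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "cmc_dcm"))
  X <- fit$basis
  flags <- fit$model$flags
  on <- names(flags)[flags]
  if (!length(on))
    return(structure(data.frame(), class = c("cmc_trajectory", "data.frame")))
  z <- qnorm(1 - (1 - level) / 2)
  nw <- nrow(X)
  seg <- c(rep("pre", fit$model$n_pre), rep("ictal", fit$model$n_post))
  out <- do.call(rbind, lapply(on, function(fl) {
    cn <- paste0("traj_", fl, "_", colnames(X))
    mu <- fit$posterior$mean[cn]
    Sg <- fit$posterior$cov[cn, cn, drop = FALSE]
    m <- as.vector(X %*% mu)
    v <- rowSums((X %*% Sg) * X)
    data.frame(window = seq_len(nw), segment = seg, parameter = fl,
               mean = m, sd = sqrt(pmax(v, 0)),
               lo = m - z * sqrt(pmax(v, 0)), hi = m + z * sqrt(pmax(v, 0)))
  }))
  structure(out, class = c("cmc_trajectory", "data.frame"), level = level)
}
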