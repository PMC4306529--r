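# S3 methods for fitted CSD-DCM objects.

#' @export
print.cmc_dcm <- function(x, ...) {
  cat("Windowed CSD dynamic causal model fit\n")
  print(x$model)
  cat(sprintf("Free energy: %.2f nats (%s, %d accepted iterations)\n",
              x$F, if (x$converged) "converged" else "NOT converged",
              x$posterior$iterations))
  invisible(x)
}

#' Summarize a fitted CSD-DCM
#'
#' @param object a `cmc_dcm` fit.
#' @param ... unused.
#' @return list with the free-energy decomposition and a coefficient table
#'   (posterior mean, sd and 90% interval of every free parameter).
#' @export
summary.cmc_dcm <- function(object, ...) {
  p <- object$posterior
  free <- p$free
  est <- p$mean[free]
  sdv <- sqrt(pmax(diag(p$cov)[free], 0))
  z <- qnorm(0.95)
  tab <- data.frame(parameter = names(est), mean = est, sd = sdv,
                    lo90 = est - z * sdv, hi90 = est + z * sdv,
                    row.names = NULL)
  out <- list(model = object$model, F = object$F,
              accuracy = p$accuracy, complexity = p$complexity,
              converged = object$converged, lambda = p$lambda,
              coefficients = tab)
  class(out) <- "summary.cmc_dcm"
  out
}

#' @export
print.summary.cmc_dcm <- function(x, digits = 3, ...) {
  print(x$model)
  cat(sprintf("F = %.2f nats (accuracy %.2f, complexity %.2f); %s\n",
              x$F, x$accuracy, x$complexity,
              if (x$converged) "converged" else "NOT converged"))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cmc_dcm <- function(object, ...) {
  p <- object$posterior
  p$mean[p$free]
}

#' @export
vcov.cmc_dcm <- function(object, ...) {
  p <- object$posterior
  p$cov[p$free, p$free, drop = FALSE]
}

#' @export
logLik.cmc_dcm <- function(object, ...) {
  structure(object$F, df = length(object$posterior$free),
            class = "logLik", nobs = length(featurize(object$data)))
}

# per-window log-scaling matrix at the posterior mean
posterior_logs <- function(object) {
  pm <- object$posterior$mean
  base <- cmc_parameters(object$priors, config = object$config)
  base$logs[] <- pm[seq_along(base$logs)]
  on <- names(object$model$flags)[object$model$flags]
  coefs <- pm[-seq_along(base$logs)]
  expand_parameters(base, coefs, object$basis, object$model$flags)
}

#' Model-predicted cross-spectra at the posterior mean
#'
#' @param object a `cmc_dcm` fit.
#' @param ... unused.
#' @return a [windowed_csd()] of predictions.
#' @export
fitted.cmc_dcm <- function(object, ...) {
  logs <- posterior_logs(object)
  comp <- compile_model(object$priors, object$model$architecture,
                        object$config)
  pred <- array(0 + 0i, dim(object$data$csd))
  for (w in seq_len(nrow(logs)))
    pred[, , , w] <- predict_csd_logs(comp, logs[w, ], object$grid,
                                      guard = FALSE)
  windowed_csd(pred, object$grid, object$data$windows,
               object$data$channels, list(method = "model prediction"))
}

#' @export
residuals.cmc_dcm <- function(object, ...) {
  as.numeric(featurize(object$data)) - as.numeric(featurize(fitted(object)))
}

#' Simulate datasets from a fitted model
#'
#' Draws synthetic windowed-CSD datasets at the posterior-mean parameters,
#' with the fitted per-window trajectory treated as ground truth and noise
#' at the requested signal-to-noise ratio.
#'
#' @param object a `cmc_dcm` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param snr signal-to-noise (RMS amplitude) ratio.
#' @param ... unused.
#' @return a list of [generate_dataset()] results (length `nsim`).
#' @export
simulate.cmc_dcm <- function(object, nsim = 1, seed = 1, snr = 4, ...) {
  logs <- posterior_logs(object)
  lapply(seq_len(nsim), function(k) {
    generate_from_logs(logs, object$priors, object$config,
                       object$model$architecture, object$grid,
                       snr = snr, seed = seed + k - 1,
                       windows = object$data$windows)
  })
}

#' Plot a fitted CSD-DCM
#'
#' `type = "trajectories"` shows the posterior trajectories of the changing
#' couplings with credible bands; `"fit"` overlays observed and predicted
#' auto-spectra for selected windows; `"trace"` shows the free-energy
#' ascent.
#'
#' @param x a `cmc_dcm` fit.
#' @param type plot type.
#' @param windows window indices for `type = "fit"`.
#' @param ... passed to underlying plotting functions.
#' @export
plot.cmc_dcm <- function(x, type = c("trajectories", "fit", "trace"),
                         windows = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    plot(x$posterior$trace, type = "b", xlab = "accepted iteration",
         ylab = "free energy (nats)", ...)
    return(invisible(x))
  }
  if (type == "trajectories") {
    tr <- extract_trajectories(x)
    if (!nrow(tr)) { message("null model: no trajectories"); return(invisible(x)) }
    pars <- unique(tr$parameter)
    col <- setNames(grDevices::hcl.colors(length(pars), "Dark 3"), pars)
    plot(NA, xlim = range(tr$window), ylim = range(tr$lo, tr$hi),
         xlab = "window", ylab = "log-scaling deviation", ...)
    graphics::abline(v = x$model$n_pre + 0.5, lty = 3)
    for (p in pars) {
      d <- tr[tr$parameter == p, ]
      graphics::polygon(c(d$window, rev(d$window)), c(d$lo, rev(d$hi)),
                        col = grDevices::adjustcolor(col[p], 0.2), border = NA)
      graphics::lines(d$window, d$mean, col = col[p], lwd = 2)
    }
    graphics::legend("topright", legend = pars, col = col, lwd = 2, bty = "n")
    return(invisible(x))
  }
  pred <- fitted(x)
  if (is.null(windows)) windows <- c(1, nrow(x$data$windows))
  nc <- dim(x$data$csd)[1]
  op <- graphics::par(mfrow = c(1, nc)); on.exit(graphics::par(op))
  for (c in seq_len(nc)) {
    obs <- Re(x$data$csd[c, c, , windows, drop = FALSE])
    prd <- Re(pred$csd[c, c, , windows, drop = FALSE])
    graphics::matplot(x$grid, cbind(matrix(obs, length(x$grid)),
                                    matrix(prd, length(x$grid))),
                      type = "l", lty = rep(c(3, 1), each = length(windows)),
                      col = rep(seq_along(windows), 2), log = "y",
                      xlab = "frequency (Hz)",
                      ylab = sprintf("channel %d auto-spectrum", c), ...)
  }
  invisible(x)
}

#' Write a posterior summary to JSON
#'
#' Human-readable structured summary: free energy and its parts, posterior
#' means/sds of free parameters, noise precisions and settings.
#'
#' @param fit a `cmc_dcm`.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_posterior <- function(fit, path) {
  s <- summary(fit)
  obj <- list(model = fit$model$id, architecture = fit$model$architecture,
              F = fit$F, accuracy = s$accuracy, complexity = s$complexity,
              converged = fit$converged, lambda = s$lambda,
              coefficients = s$coefficients, settings = fit$settings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
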