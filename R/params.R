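#' @title Model parameters, priors and the log-scaling parameterization
#' @name cmc-parameters
#' @description
#' Every parameter of the two-source CMC model is expressed as a prior mean
#' on its natural scale (rates in Hz, delays in ms, gains dimensionless)
#' times the exponential of a dimensionless log-scaling.  Gaussian priors are
#' placed on the log-scalings, so every effective value is strictly positive
#' and a prior variance of zero fixes a parameter at its prior mean.
NULL

cmc_populations <- c("ss", "sp", "ii", "dp")

# Intrinsic (within-source) connection graph of the canonical microcircuit:
# four populations -- input cells (ss), superficial pyramidal (sp),
# inhibitory interneurons (ii) and deep pyramidal (dp).  Signs follow the
# laminar circuit: interneurons and self (recurrent) connections inhibit;
# projections from excitatory cells excite.  The recurrent self-inhibition
# of superficial pyramidal cells (sp -> sp) is the tracked intrinsic gain.
cmc_intrinsic_edges <- function() {
  data.frame(
    src  = c("ss", "sp", "ii", "ii", "ss", "dp", "sp", "ss", "ii", "dp"),
    tgt  = c("ss", "ss", "ss", "ii", "ii", "ii", "sp", "sp", "dp", "dp"),
    sign = c(-1,   -1,   -1,   -1,   +1,   +1,   -1,   +1,   -1,   -1),
    mean = c(1600, 800,  1600, 800,  800,  400,  800,  800,  400,  200),
    stringsAsFactors = FALSE
  )
}

# Extrinsic (between-source) laminar rules: forward connections originate in
# superficial pyramidal cells and target input cells (and, more weakly, deep
# pyramidal cells); backward connections originate in deep pyramidal cells
# and target superficial pyramidal cells (inhibitory, via absorbed
# interneurons) and inhibitory interneurons.  One strength parameter per
# direction scales all of its sub-edges.
cmc_extrinsic_edges <- function() {
  data.frame(
    type  = c("fw", "fw", "bw", "bw"),
    src   = c("sp", "sp", "dp", "dp"),
    tgt   = c("ss", "dp", "sp", "ii"),
    sign  = c(+1,   +1,   -1,   +1),
    relwt = c(1.0,  0.5,  1.0,  0.5),
    stringsAsFactors = FALSE
  )
}

#' Model configuration
#'
#' Collects the structural choices of the two-source CMC model that are
#' configuration rather than estimated parameters: the intrinsic wiring table
#' (edge signs and prior-mean rates in Hz), the laminar extrinsic rules,
#' which intrinsic edges receive a free log-scaling, which population is
#' driven by endogenous fluctuations, which population is observed, and the
#' split of measurement noise into channel-specific and common-mode parts.
#'
#' @param intrinsic data frame with columns `src`, `tgt`, `sign`, `mean`
#'   describing the within-source graph (defaults to the canonical
#'   microcircuit wiring).
#' @param extrinsic data frame with columns `type` (`"fw"`/`"bw"`), `src`,
#'   `tgt`, `sign`, `relwt` describing laminar extrinsic rules.
#' @param free_intrinsic character; names of intrinsic edges (as
#'   `"src_tgt"`) given a free log-scaling.  Defaults to the recurrent
#'   self-inhibition of superficial pyramidal cells.
#' @param drive_pop population receiving the endogenous drive.
#' @param obs_pop population whose depolarisation is observed.
#' @param noise_common_frac common-mode measurement-noise amplitude as a
#'   fraction of the channel-specific amplitude.
#' @param input_scale,noise_scale fixed structural constants converting the
#'   dimensionless input/noise amplitude parameters into spectral densities
#'   in measurement units.  The default noise scale places the measurement
#'   noise floor well below the in-band neuronal spectrum at prior means, as
#'   in intracranial recordings.
#' @return an object of class `cmc_config`.
#' @export
cmc_config <- function(intrinsic = cmc_intrinsic_edges(),
                       extrinsic = cmc_extrinsic_edges(),
                       free_intrinsic = "sp_sp",
                       drive_pop = "ss",
                       obs_pop = "sp",
                       noise_common_frac = 0.25,
                       input_scale = 1,
                       noise_scale = 1e-8) {
  stopifnot(all(c("src", "tgt", "sign", "mean") %in% names(intrinsic)),
            all(intrinsic$mean > 0),
            all(abs(intrinsic$sign) == 1),
            drive_pop %in% cmc_populations,
            obs_pop %in% cmc_populations,
            noise_common_frac >= 0)
  stopifnot(input_scale > 0, noise_scale > 0)
  structure(list(intrinsic = intrinsic, extrinsic = extrinsic,
                 free_intrinsic = free_intrinsic, drive_pop = drive_pop,
                 obs_pop = obs_pop, noise_common_frac = noise_common_frac,
                 input_scale = input_scale, noise_scale = noise_scale,
                 n_sources = 2L),
            class = "cmc_config")
}

param_names <- function(config = cmc_config()) {
  edge <- paste0("int_", config$intrinsic$src, "_", config$intrinsic$tgt)
  c(paste0(rep(edge, 2), "_s", rep(1:2, each = length(edge))),
    "ext_fw", "ext_bw",
    paste0("kappa_", rep(cmc_populations, 2), "_s", rep(1:2, each = 4)),
    "gamma", "delay_int", "delay_ext",
    "input_amp_s1", "input_amp_s2", "input_exp",
    "noise_amp", "noise_exp", "gain_1", "gain_2")
}

#' Default priors for the two-source CMC model
#'
#' Returns the prior specification used throughout: one row per parameter
#' with its prior mean on the natural scale and the prior variance of its
#' log-scaling.  Rates are in Hz, conduction delays in ms; the sigmoid slope,
#' spectral amplitudes/exponents and electrode gains are dimensionless.
#' Intrinsic connection strengths other than the recurrent self-inhibition
#' of superficial pyramidal cells are fixed (zero prior variance) by
#' default; all structural magnitudes are configurable through
#' [cmc_config()].
#'
#' @param config a [cmc_config()] object.
#' @return a data frame of class `prior_spec` with columns `name`, `mean`,
#'   `var`.
#' @examples
#' pr <- default_priors()
#' pr[pr$name == "delay_ext", ]   # extrinsic conduction delay: 8 ms
#' @export
default_priors <- function(config = cmc_config()) {
  nm <- param_names(config)
  ne <- nrow(config$intrinsic)
  mean <- c(rep(config$intrinsic$mean, 2),          # intrinsic rates (Hz)
            rep(1600, 2),                           # extrinsic rates (Hz)
            rep(c(500, 500, 1000 / 16, 1000 / 28), 2),  # kappa (Hz)
            2 / 3,                                  # sigmoid slope
            1, 8,                                   # delays (ms)
            1, 1, 1,                                # input amplitude / exponent
            1, 1,                                   # noise amplitude / exponent
            1, 1)                                   # electrode gains
  free_edge <- paste0("int_", config$free_intrinsic)
  int_names <- nm[seq_len(2 * ne)]
  int_var <- ifelse(sub("_s[12]$", "", int_names) %in% free_edge, 1 / 8, 0)
  var <- c(int_var,
           rep(1 / 8, 2),
           rep(1 / 16, 8),
           1 / 32, 1 / 32, 1 / 32,
           1 / 128, 1 / 128, 1 / 128,
           1 / 128, 1 / 128,
           1 / 8, 1 / 8)
  out <- data.frame(name = nm, mean = mean, var = var,
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_spec", "data.frame")
  out
}

validate_priors <- function(priors) {
  stopifnot(is.data.frame(priors),
            all(c("name", "mean", "var") %in% names(priors)))
  if (any(priors$mean <= 0)) stop("prior means must be strictly positive")
  if (any(priors$var < 0)) stop("prior variances must be non-negative")
  if (anyDuplicated(priors$name)) stop("duplicated parameter names in priors")
  invisible(priors)
}

#' Effective parameter value under the log-scaling parameterization
#'
#' @param prior_mean prior mean on the natural scale (must be positive).
#' @param log_scaling dimensionless log-scaling deviation.
#' @return `prior_mean * exp(log_scaling)`.
#' @examples
#' effective_value(10, 0)        # 10
#' effective_value(4, -log(2))   # 2
#' @export
effective_value <- function(prior_mean, log_scaling) {
  if (any(prior_mean <= 0)) stop("invalid prior: prior_mean must be positive")
  prior_mean * exp(log_scaling)
}

#' Centered sigmoid firing-rate response
#'
#' Population coupling is mediated by a sigmoid function of (delayed) mean
#' depolarisation.  The centered form (logistic minus one half) makes the
#' zero state a fixed point of the unforced system; the slope parameter is
#' the intrinsic gain of the population.
#'
#' @param v mean depolarisation (mV); vectorized.
#' @param slope sigmoid slope (dimensionless, > 0).
#' @return normalized firing rate in (-1/2, 1/2).
#' @export
sigmoid_response <- function(v, slope) {
  stopifnot(slope > 0)
  1 / (1 + exp(-slope * v)) - 0.5
}

#' Construct a CMC parameter set
#'
#' Bundles a prior specification with a vector of log-scaling deviations.
#' Missing log-scalings default to zero (parameters at their prior means).
#'
#' @param priors a `prior_spec` from [default_priors()] (or a modification).
#' @param logs named numeric vector of log-scalings; a subset of the prior
#'   names may be given.
#' @param config a [cmc_config()].
#' @return object of class `cmc_parameters`.
#' @export
cmc_parameters <- function(priors = default_priors(), logs = NULL,
                           config = cmc_config()) {
  validate_priors(priors)
  full <- setNames(numeric(nrow(priors)), priors$name)
  if (!is.null(logs)) {
    if (is.null(names(logs)) || !all(names(logs) %in% priors$name))
      stop("logs must be named with parameter names from the prior spec")
    full[names(logs)] <- logs
  }
  structure(list(logs = full, priors = priors, config = config),
            class = "cmc_parameters")
}

#' Effective (natural-scale) values of a parameter set
#'
#' @param params a `cmc_parameters` object.
#' @return named numeric vector, `mean * exp(log)` per parameter.
#' @export
effective_values <- function(params) {
  stopifnot(inherits(params, "cmc_parameters"))
  setNames(effective_value(params$priors$mean, params$logs), params$priors$name)
}

#' @export
print.cmc_parameters <- function(x, ...) {
  nz <- x$logs[x$logs != 0]
  cat("Two-source CMC parameter set:", length(x$logs), "parameters\n")
  if (length(nz)) {
    cat("Non-zero log-scalings:\n")
    print(round(nz, 4))
  } else cat("All log-scalings zero (prior means)\n")
  invisible(x)
}

#' Read or write a prior specification
#'
#' Priors serialize to a flat key-value file: for each parameter `name`,
#' entries `<name>.mean` and `<name>.var`.  Format (YAML or JSON) is chosen
#' by file extension.
#'
#' @param priors a `prior_spec` data frame.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_priors` returns a `prior_spec`; `write_priors` returns the
#'   path invisibly.
#' @export
write_priors <- function(priors, path) {
  validate_priors(priors)
  kv <- list()
  for (i in seq_len(nrow(priors))) {
    kv[[paste0(priors$name[i], ".mean")]] <- priors$mean[i]
    kv[[paste0(priors$name[i], ".var")]] <- priors$var[i]
  }
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(kv, path, precision = 15)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported prior file extension: ", path)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  kv <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
        else if (grepl("\\.json$", path)) jsonlite::read_json(path)
        else stop("unsupported prior file extension: ", path)
  nm <- unique(sub("\\.(mean|var)$", "", names(kv)))
  out <- data.frame(
    name = nm,
    mean = vapply(nm, function(n) as.numeric(kv[[paste0(n, ".mean")]]), 0),
    var  = vapply(nm, function(n) as.numeric(kv[[paste0(n, ".var")]]), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("prior_spec", "data.frame")
  validate_priors(out)
  out
}
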