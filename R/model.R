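# Wiring, equations of motion and linearization of the two-source CMC model.
#
# State convention: x = c(v, z) with v the mean depolarisation (mV) and z its
# first derivative for the 8 populations (2 sources x 4 populations, ordered
# ss, sp, ii, dp within source).  Each population obeys a second-order
# synaptic kernel driven by sigmoid-transformed, delayed presynaptic
# depolarisation:
#   dv/dt = z
#   dz/dt = kappa * (sum_e w_e * sig(v_src(t - tau_e)) + drive) -
#           2 kappa z - kappa^2 v

cmc_architectures <- c("fw_primary", "bw_primary")

pop_index <- function(source, pop) (source - 1L) * 4L + match(pop, cmc_populations)

# Precompute index structures mapping the flat log-scaling vector to the
# state-space matrices; called once per model/architecture, reused heavily.
compile_model <- function(priors, architecture = "fw_primary",
                          config = cmc_config()) {
  architecture <- match.arg(architecture, cmc_architectures)
  nm <- priors$name
  idx <- function(x) {
    i <- match(x, nm)
    if (anyNA(i)) stop("parameter(s) missing from priors: ",
                       paste(x[is.na(i)], collapse = ", "))
    i
  }
  np <- 4L * config$n_sources
  nx <- 2L * np

  # intrinsic edges, both sources
  ie <- config$intrinsic
  int <- do.call(rbind, lapply(1:2, function(s) {
    data.frame(tgt = pop_index(s, ie$tgt), src = pop_index(s, ie$src),
               sign = ie$sign, relwt = 1,
               par = idx(paste0("int_", ie$src, "_", ie$tgt, "_s", s)),
               grp = 0)
  }))

  # extrinsic edges follow the architecture: under "fw_primary" the primary
  # source (1) sends forward connections to the secondary source (2), which
  # reciprocates with backward connections; "bw_primary" is the reverse.
  ee <- config$extrinsic
  fw <- ee[ee$type == "fw", ]
  bw <- ee[ee$type == "bw", ]
  dir_edges <- function(sub, from, to, par_i) {
    data.frame(tgt = pop_index(to, sub$tgt), src = pop_index(from, sub$src),
               sign = sub$sign, relwt = sub$relwt, par = par_i, grp = 1)
  }
  ext <- if (architecture == "fw_primary") {
    rbind(dir_edges(fw, 1, 2, idx("ext_fw")), dir_edges(bw, 2, 1, idx("ext_bw")))
  } else {
    rbind(dir_edges(bw, 1, 2, idx("ext_bw")), dir_edges(fw, 2, 1, idx("ext_fw")))
  }
  edges <- rbind(int, ext)
  edges$mean <- priors$mean[edges$par] * edges$relwt

  kap_par <- idx(paste0("kappa_", rep(cmc_populations, 2),
                        "_s", rep(1:2, each = 4)))
  drive_gpop <- vapply(1:2, pop_index, 0L, pop = config$drive_pop)
  obs_gpop <- vapply(1:2, pop_index, 0L, pop = config$obs_pop)

  lin_idx <- function(r, c) (c - 1L) * nx + r   # column-major linear index

  list(
    architecture = architecture, config = config, np = np, nx = nx,
    edges = edges,
    idx_A_edge = lin_idx(np + edges$tgt, edges$src),
    is_int = edges$grp == 0,
    kap_par = kap_par, kap_mean = priors$mean[kap_par],
    gamma_par = idx("gamma"), gamma_mean = priors$mean[idx("gamma")],
    delay_par = idx(c("delay_int", "delay_ext")),
    delay_mean = priors$mean[idx(c("delay_int", "delay_ext"))],
    inamp_par = idx(c("input_amp_s1", "input_amp_s2")),
    inamp_mean = priors$mean[idx(c("input_amp_s1", "input_amp_s2"))],
    inexp_par = idx("input_exp"), inexp_mean = priors$mean[idx("input_exp")],
    namp_par = idx("noise_amp"), namp_mean = priors$mean[idx("noise_amp")],
    nexp_par = idx("noise_exp"), nexp_mean = priors$mean[idx("noise_exp")],
    gain_par = idx(c("gain_1", "gain_2")),
    gain_mean = priors$mean[idx(c("gain_1", "gain_2"))],
    drive_gpop = drive_gpop, obs_gpop = obs_gpop,
    idx_k2 = lin_idx(np + seq_len(np), seq_len(np)),
    idx_2k = lin_idx(np + seq_len(np), np + seq_len(np)),
    idx_I = lin_idx(seq_len(np), np + seq_len(np))
  )
}

# State-space matrices (A0 instantaneous, Ai/Ae delayed couplings, B input,
# L observation) from a full vector of log-scalings, linearized about a
# state x_star (zero by default, where the sigmoid slope is gamma/4).
statespace_from_logs <- function(comp, logs, x_star = NULL) {
  np <- comp$np; nx <- comp$nx
  kap <- unname(comp$kap_mean * exp(logs[comp$kap_par]))
  gam <- unname(comp$gamma_mean * exp(logs[comp$gamma_par]))

  A0 <- numeric(nx * nx)
  A0[comp$idx_I] <- 1
  A0[comp$idx_k2] <- -kap^2
  A0[comp$idx_2k] <- -2 * kap
  dim(A0) <- c(nx, nx)

  # sigmoid derivative at the expansion point, per presynaptic population
  if (is.null(x_star)) {
    sl <- rep(gam / 4, np)
  } else {
    s <- sigmoid_response(x_star[seq_len(np)], gam)
    sl <- gam * (0.25 - s^2)
  }
  w <- comp$edges$sign * comp$edges$mean * exp(logs[comp$edges$par]) *
    kap[comp$edges$tgt] * sl[comp$edges$src]

  Ai <- numeric(nx * nx); Ae <- numeric(nx * nx)
  ii <- comp$is_int
  Ai[comp$idx_A_edge[ii]] <- w[ii]
  Ae[comp$idx_A_edge[!ii]] <- w[!ii]
  dim(Ai) <- c(nx, nx); dim(Ae) <- c(nx, nx)

  B <- matrix(0, nx, 2)
  B[cbind(np + comp$drive_gpop, 1:2)] <- kap[comp$drive_gpop]

  L <- matrix(0, 2, nx)
  L[cbind(1:2, comp$obs_gpop)] <- comp$gain_mean * exp(logs[comp$gain_par])

  tau <- unname(comp$delay_mean * exp(logs[comp$delay_par]) / 1000)  # ms -> s
  list(A0 = A0, Ai = Ai, Ae = Ae, B = B, L = L,
       tau_i = tau[1], tau_e = tau[2], kappa = kap, gamma = gam)
}

resolve_params <- function(params, architecture = "fw_primary") {
  stopifnot(inherits(params, "cmc_parameters"))
  comp <- compile_model(params$priors, architecture, params$config)
  list(comp = comp, logs = params$logs)
}

#' Equations of motion of the two-source CMC model
#'
#' Time derivatives of the 16-dimensional state (depolarisation and its
#' derivative for 8 populations).  Couplings act through the centered
#' sigmoid of *delayed* presynaptic depolarisation; the delayed state is
#' supplied by the caller (defaulting to the current state, i.e. the
#' zero-delay evaluation used for equilibria).
#'
#' @param state numeric state vector `c(v, z)`, length 16.
#' @param params a [cmc_parameters()] object.
#' @param input exogenous drive per source (length 2).
#' @param state_delayed either a state vector used for all delayed lookups,
#'   or a function `function(tau_s)` returning the state at `t - tau_s`.
#' @param architecture extrinsic architecture, `"fw_primary"` or
#'   `"bw_primary"`.
#' @return numeric vector of time derivatives (states per second).
#' @export
cmc_motion <- function(state, params, input = c(0, 0),
                       state_delayed = state,
                       architecture = "fw_primary") {
  rp <- resolve_params(params, architecture)
  comp <- rp$comp
  if (length(state) != comp$nx)
    stop("malformed state: expected length ", comp$nx, ", got ", length(state))
  ss <- statespace_from_logs(comp, rp$logs)
  np <- comp$np
  v <- state[seq_len(np)]; z <- state[np + seq_len(np)]

  del <- if (is.function(state_delayed)) {
    list(i = state_delayed(ss$tau_i), e = state_delayed(ss$tau_e))
  } else {
    if (length(state_delayed) != comp$nx) stop("malformed delayed state")
    list(i = state_delayed, e = state_delayed)
  }
  ed <- comp$edges
  w <- ed$sign * ed$mean * exp(rp$logs[ed$par])
  vd <- ifelse(ed$grp == 0, del$i[ed$src], del$e[ed$src])
  contrib <- w * sigmoid_response(vd, ss$gamma)
  u <- as.vector(tapply(contrib, factor(ed$tgt, levels = seq_len(np)), sum))
  u[is.na(u)] <- 0
  u[comp$drive_gpop] <- u[comp$drive_gpop] + rep_len(input, 2)

  dz <- ss$kappa * u - 2 * ss$kappa * z - ss$kappa^2 * v
  unname(c(z, dz))
}

#' Fixed point of the unforced model
#'
#' Solves the equations of motion for an equilibrium under constant input by
#' damped Newton iteration (delays are immaterial at a stationary point).
#' With the centered sigmoid and zero input the origin is an exact fixed
#' point.
#'
#' @inheritParams cmc_motion
#' @param start starting state (defaults to the origin).
#' @param tol residual norm tolerance.
#' @param max_iter maximum Newton iterations.
#' @return list with `state` (the root), `residual` (max absolute derivative)
#'   and `iterations`.
#' @export
fixed_point <- function(params, architecture = "fw_primary", input = c(0, 0),
                        start = NULL, tol = 1e-10, max_iter = 100) {
  rp <- resolve_params(params, architecture)
  comp <- rp$comp
  x <- if (is.null(start)) numeric(comp$nx) else start
  f <- cmc_motion(x, params, input, x, architecture)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    ss <- statespace_from_logs(comp, rp$logs, x_star = x)
    A <- ss$A0 + ss$Ai + ss$Ae
    step <- tryCatch(solve(A, -f), error = function(e) NULL)
    if (is.null(step)) stop("fixed-point search failed: singular Jacobian")
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- cmc_motion(xn, params, input, xn, architecture)
      if (max(abs(fn)) < max(abs(f)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) >= tol)
    stop("fixed-point search did not converge (residual ",
         format(max(abs(f))), "); parameter set may be unstable")
  list(state = x, residual = max(abs(f)), iterations = it)
}

#' Linearization of the delay system about a fixed point
#'
#' Returns the state-space matrices of the linearized model: `A0`
#' (instantaneous terms), `Ai` and `Ae` (couplings conducted with the
#' intrinsic and extrinsic delay), input matrix `B` (endogenous drive to the
#' input cells), observation matrix `L` (electrode gain times superficial
#' pyramidal depolarisation) and the delays in seconds.
#'
#' @inheritParams cmc_motion
#' @param x_star expansion state (a fixed point); defaults to the origin.
#' @return list `A0, Ai, Ae, B, L, tau_i, tau_e, kappa, gamma`.
#' @export
cmc_statespace <- function(params, architecture = "fw_primary",
                           x_star = NULL) {
  rp <- resolve_params(params, architecture)
  statespace_from_logs(rp$comp, rp$logs, x_star = x_star)
}

# Largest real part over eigenvalues of the zero-delay system matrix; used
# as a stability guard (delays only add phase at the frequencies modelled).
stability_margin <- function(ss) {
  max(Re(eigen(ss$A0 + ss$Ai + ss$Ae, only.values = TRUE)$values))
}
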