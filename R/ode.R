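#' Deterministic rate of change dx/dt = S W(x, t)
#'
#' The mean-field (reaction-rate) equations: the stoichiometry matrix
#' applied to the propensity vector at a real-valued state. For the
#' constitutive model this expands to
#' \deqn{dR_n/dt = k_r - k_t R_n - \gamma_r R_n}
#' \deqn{dR_c/dt = k_t R_n - \gamma_r R_c}
#' \deqn{dP/dt   = k_p R_c - \gamma_p P.}
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param x real-valued state (molecule numbers).
#' @param t time (min); only used by the drug schedule.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @return numeric vector of time derivatives, one per species.
#' @export
odeRHS <- function(net, x, t = 0, schedule = NULL) {
  if (any(!is.finite(x))) stop("state must be finite (no NaN/Inf)")
  rates <- net@params[net@rateNames]
  if (!is.null(schedule)) {
    isTarget <- net@rateNames == net@drugTarget
    rates[isTarget] <- effectiveRate(rates[isTarget][1], t, schedule)
  }
  w <- rates
  for (mu in seq_along(w)) {
    nz <- which(net@orders[, mu] > 0L)
    for (i in nz) w[mu] <- w[mu] * choose(x[i], net@orders[i, mu])
  }
  drop(net@stoich %*% as.numeric(w))
}

# TRUE if every propensity is constant or linear in one species, so the
# mean equations are affine: dx/dt = M x + b.
isAffine <- function(net) all(colSums(net@orders) <= 1L)

# Affine decomposition (M, b) of S W(x) at fixed rates.
affineParts <- function(net, rates) {
  M <- ncol(net@stoich)
  N <- length(net@species)
  w0 <- numeric(M)
  W1 <- matrix(0, M, N)
  for (mu in seq_len(M)) {
    nz <- which(net@orders[, mu] > 0L)
    if (length(nz) == 0L) w0[mu] <- rates[mu]
    else W1[mu, nz] <- rates[mu]
  }
  list(M = net@stoich %*% W1, b = drop(net@stoich %*% w0))
}

segmentRates <- function(net, t, schedule) {
  rates <- net@params[net@rateNames]
  if (!is.null(schedule)) {
    isTarget <- net@rateNames == net@drugTarget
    rates[isTarget] <- effectiveRate(rates[isTarget][1], t, schedule)
  }
  rates
}

# Exact solution of the affine system on one segment via the augmented
# (N+1)-dimensional matrix exponential.
solveAffineSegment <- function(net, x0, t0, times, rates) {
  ap <- affineParts(net, rates)
  N <- length(x0)
  Aug <- rbind(cbind(ap$M, ap$b), 0)
  out <- matrix(NA_real_, length(times), N)
  for (i in seq_along(times)) {
    E <- as.matrix(Matrix::expm(Aug * (times[i] - t0)))
    out[i, ] <- drop(E %*% c(x0, 1))[seq_len(N)]
  }
  out
}

#' Solve the deterministic mean dynamics
#'
#' Integrates dx/dt = S W(x, t) over a time grid. With a drug schedule the
#' integration is split into segments [0, tDrug] and [tDrug, tMax] with an
#' exact state hand-off, so the rate discontinuity is never smoothed over
#' by the step controller. Networks whose propensities are all affine
#' (both built-in models) are solved exactly segment-by-segment with the
#' matrix exponential of the augmented affine system; other networks use
#' \code{deSolve::lsoda}.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param x0 initial state (defaults to all zeros).
#' @param times strictly increasing numeric grid (min).
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param method \code{"auto"} (matrix exponential when affine, else
#'   lsoda), \code{"expm"} or \code{"lsoda"}.
#' @param rtol,atol solver tolerances (lsoda only).
#' @return a trajectory data.frame with column \code{time} followed by one
#'   column per species.
#' @examples
#' net <- constitutiveModel()
#' traj <- solveODE(net, times = seq(0, 500, 10))
#' tail(traj, 1)  # approaches the analytic steady state
#' @export
solveODE <- function(net, x0 = NULL, times, schedule = NULL,
                     method = c("auto", "expm", "lsoda"),
                     rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  N <- length(net@species)
  if (is.null(x0)) x0 <- numeric(N)
  if (length(x0) != N) stop("x0 must have one entry per species")
  if (any(!is.finite(x0))) stop("x0 must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  useExpm <- switch(method, expm = TRUE, lsoda = FALSE, auto = isAffine(net))
  if (method == "expm" && !isAffine(net))
    stop("matrix-exponential path requires an affine (<= first order) network")

  t0 <- times[1]
  breaks <- t0
  if (!is.null(schedule) && schedule@tDrug > t0 &&
      schedule@tDrug < times[length(times)])
    breaks <- c(breaks, schedule@tDrug)
  breaks <- c(breaks, times[length(times)])

  out <- matrix(NA_real_, length(times), N)
  if (t0 == times[1]) out[1, ] <- x0
  x <- x0
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]; bnd <- breaks[s + 1]
    sel <- which(times > a & times <= bnd)
    segTimes <- unique(c(times[sel], bnd))
    rates <- segmentRates(net, a, schedule)
    if (useExpm) {
      seg <- solveAffineSegment(net, x, a, segTimes, rates)
    } else {
      rhs <- function(t, y, parms) {
        w <- rates
        for (mu in seq_along(w)) {
          nz <- which(net@orders[, mu] > 0L)
          for (i in nz) w[mu] <- w[mu] * choose(y[i], net@orders[i, mu])
        }
        list(drop(net@stoich %*% as.numeric(w)))
      }
      sol <- deSolve::lsoda(y = x, times = unique(c(a, segTimes)), func = rhs,
                            parms = NULL, rtol = rtol, atol = atol)
      seg <- sol[match(segTimes, sol[, 1]), -1, drop = FALSE]
    }
    if (length(sel)) out[sel, ] <- seg[match(times[sel], segTimes), ]
    x <- seg[match(bnd, segTimes), ]
  }
  traj <- data.frame(time = times, out)
  names(traj) <- c("time", net@species)
  traj
}

#' Closed-form steady state of the constitutive model
#'
#' Setting the net change to zero gives
#' \deqn{R_n^* = k_r / (\gamma_r + k_t), \quad
#'       R_c^* = k_t R_n^* / \gamma_r, \quad
#'       P^*   = k_p R_c^* / \gamma_p.}
#'
#' @param params named rates (see [defaultParameters()]).
#' @param k_t_effective optional export rate overriding \code{params["k_t"]},
#'   e.g. the post-drug rate \code{(1 - efficacy) * k_t}.
#' @return named numeric vector \code{c(Rn, Rc, P)}.
#' @examples
#' steadyState(defaultParameters())            # pre-drug
#' steadyState(defaultParameters(), 0.0083)    # under a 90%-effective drug
#' @export
steadyState <- function(params = defaultParameters(), k_t_effective = NULL) {
  checkParams(params, c("k_r", "k_t", "k_p", "gamma_r", "gamma_p"))
  kt <- if (is.null(k_t_effective)) params[["k_t"]] else k_t_effective
  if (kt < 0) stop("effective export rate must be nonnegative")
  if (params[["gamma_r"]] == 0 || params[["gamma_p"]] == 0)
    stop("steady state undefined: division by zero decay rate (gamma_r or gamma_p)")
  Rn <- params[["k_r"]] / (params[["gamma_r"]] + kt)
  Rc <- kt * Rn / params[["gamma_r"]]
  P <- params[["k_p"]] * Rc / params[["gamma_p"]]
  c(Rn = Rn, Rc = Rc, P = P)
}

#' Write a trajectory to CSV
#'
#' @param traj trajectory data.frame from [solveODE()].
#' @param file output path; header is \code{time,Rn,Rc,P} for the
#'   constitutive model.
#' @return \code{file}, invisibly.
#' @export
exportTrajectory <- function(traj, file) {
  utils::write.csv(traj, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
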