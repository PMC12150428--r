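#' Summarize per-cell counts into an observation set
#'
#' Snapshot observations for the Gaussian ODE likelihood: for each time
#' and species, the sample mean across cells and the sample SD (used as
#' the per-observation noise scale). SDs of zero (or single-cell times)
#' are floored at \code{sdFloor}.
#'
#' @param counts data.frame with columns cell, time, Rn, Rc, P (e.g. the
#'   ground truth of [generateDataset()] or the output of
#'   [quantifyStack()] bound over cells).
#' @param sdFloor minimum noise scale.
#' @return data.frame (ObservationSet) with columns time, species, mean,
#'   sd, sorted by time.
#' @export
summarizeCounts <- function(counts, sdFloor = 0.5) {
  species <- intersect(c("Rn", "Rc", "P"), names(counts))
  out <- do.call(rbind, lapply(split(counts, counts$time), function(d) {
    data.frame(time = d$time[1], species = species,
               mean = vapply(species, function(s) mean(d[[s]]), 0),
               sd = vapply(species, function(s) {
                 v <- stats::sd(d[[s]])
                 if (!is.finite(v) || v < sdFloor) sdFloor else v
               }, 0))
  }))
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  out
}

#' Gaussian ODE log-likelihood of snapshot observations
#'
#' Solves the deterministic model at the observation times (including the
#' drug schedule) and scores the observed per-time statistics under
#' independent Gaussians:
#' \deqn{\log L = -\tfrac12 \sum_{m,i} \log(2\pi\sigma_{mi}^2)
#'   - \sum_{m,i} (O_{mi}^{data} - O_{mi}^{model})^2 / (2\sigma_{mi}^2).}
#' With \code{sumOfSquares = TRUE} the parameter-independent constant is
#' dropped, leaving the negative weighted sum of squares.
#'
#' @param theta named positive rates (natural scale): k_r, k_t, k_p,
#'   gamma_r, gamma_p.
#' @param obs ObservationSet from [summarizeCounts()].
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param x0 initial state for the ODE (default zeros).
#' @param sumOfSquares drop the constant term.
#' @param model network constructor applied to \code{theta} (default
#'   [constitutiveModel()]).
#' @return log-likelihood (scalar); \code{-Inf} with a warning if the ODE
#'   solve fails.
#' @export
odeGaussianLoglik <- function(theta, obs, schedule = NULL, x0 = NULL,
                              sumOfSquares = FALSE,
                              model = constitutiveModel) {
  net <- try(model(theta), silent = TRUE)
  if (inherits(net, "try-error")) return(-Inf)
  times <- sort(unique(obs$time))
  traj <- try(solveODE(net, x0 = x0, times = times, schedule = schedule),
              silent = TRUE)
  if (inherits(traj, "try-error") || any(!is.finite(as.matrix(traj[-1])))) {
    warning("ODE solve failed; returning -Inf")
    return(-Inf)
  }
  model <- mapply(function(tm, sp) traj[match(tm, traj$time), sp],
                  obs$time, as.character(obs$species))
  quad <- sum((obs$mean - model)^2 / (2 * obs$sd^2))
  if (sumOfSquares) return(-quad)
  -0.5 * sum(log(2 * pi * obs$sd^2)) - quad
}

#' Log-prior in log10 parameter space
#'
#' Independent normal densities on the log10 rates (equivalently,
#' lognormal priors on the natural scale): default location -1 and scale
#' 2, i.e. each rate is guessed to lie within about two orders of
#' magnitude of 0.1/min.
#'
#' @param thetaLog10 named numeric vector of log10 rates.
#' @param location,scale prior mean(s) and SD(s) on the log10 scale
#'   (recycled).
#' @return log prior density (scalar).
#' @export
logPrior <- function(thetaLog10, location = -1, scale = 2) {
  sum(stats::dnorm(thetaLog10, mean = location, sd = scale, log = TRUE))
}

#' Unnormalized log-posterior in log10 space
#'
#' \code{logPrior(thetaLog10) + odeGaussianLoglik(10^thetaLog10, ...)}.
#'
#' @param thetaLog10 named log10 rates.
#' @param obs ObservationSet.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param location,scale prior hyperparameters (see [logPrior()]).
#' @param ... passed to [odeGaussianLoglik()].
#' @return unnormalized log-posterior density.
#' @export
logPosterior <- function(thetaLog10, obs, schedule = NULL,
                         location = -1, scale = 2, ...) {
  lp <- logPrior(thetaLog10, location, scale)
  ll <- odeGaussianLoglik(10^thetaLog10, obs, schedule = schedule, ...)
  lp + ll
}

#' Maximum likelihood estimation by multi-start local optimization
#'
#' Optimizes the Gaussian ODE log-likelihood over log10 parameters with
#' Nelder-Mead from several starts; returns the best optimum.
#'
#' @param obs ObservationSet from [summarizeCounts()].
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param start named log10 starting point (defaults to log10 of
#'   [defaultParameters()]).
#' @param nStarts number of starts; additional starts perturb \code{start}
#'   by N(0, 0.5) in log10 units.
#' @param seed RNG seed for the start perturbations.
#' @param control passed to [stats::optim()].
#' @return list with \code{estimate} (named rates, natural scale),
#'   \code{log10} (named log10 rates), \code{logLik}, \code{convergence}
#'   and \code{starts} (per-start log of objective values).
#' @export
maximizeLikelihood <- function(obs, schedule = NULL, start = NULL,
                               nStarts = 3, seed = 1,
                               control = list(maxit = 2000,
                                              reltol = 1e-10)) {
  if (is.null(start))
    start <- log10(defaultParameters())
  parNames <- names(start)
  set.seed(as.integer(seed))
  starts <- list(start)
  if (nStarts > 1)
    for (i in 2:nStarts)
      starts[[i]] <- start + stats::rnorm(length(start), 0, 0.5)
  obj <- function(th) {
    v <- odeGaussianLoglik(stats::setNames(10^th, parNames), obs,
                           schedule = schedule)
    if (!is.finite(v)) return(1e10)
    -v
  }
  fits <- lapply(starts, function(s) {
    out <- try(stats::optim(s, obj, method = "Nelder-Mead",
                            control = control), silent = TRUE)
    if (inherits(out, "try-error")) NULL else out
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("all optimization starts failed")
  vals <- vapply(fits[ok], function(f) f$value, 0)
  best <- fits[ok][[which.min(vals)]]
  # polish the winner
  best2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = control)
  if (best2$value < best$value) best <- best2
  list(estimate = stats::setNames(10^best$par, parNames),
       log10 = stats::setNames(best$par, parNames),
       logLik = -best$value, convergence = best$convergence,
       starts = data.frame(start = seq_along(fits)[ok], negLogLik = vals))
}

#' Metropolis-Hastings sampling of an unnormalized target
#'
#' Symmetric Gaussian random-walk proposals in log10-parameter space;
#' proposals are accepted with probability min(1, exp(delta log target)).
#' With \code{adapt = TRUE} the common proposal scale is tuned during
#' burn-in toward an acceptance rate near 0.3 and frozen afterwards, so
#' the recorded (post-burn-in) chain satisfies detailed balance.
#'
#' @param logTarget function of a named log10 parameter vector returning
#'   the unnormalized log density.
#' @param theta0 named log10 starting point.
#' @param proposalSd per-parameter proposal SDs (log10 units; recycled).
#' @param nIter total iterations (> burnIn).
#' @param seed RNG seed.
#' @param burnIn iterations discarded by [chainSummary()]; default 20\%.
#' @param adapt tune the proposal scale during burn-in.
#' @return a \linkS4class{PosteriorChain} holding all iterations;
#'   \code{accepted} counts post-burn-in acceptances.
#' @export
metropolisHastings <- function(logTarget, theta0, proposalSd = 0.05,
                               nIter = 10000, seed = 1,
                               burnIn = floor(0.2 * nIter), adapt = TRUE) {
  stopifnot(nIter > burnIn, burnIn >= 0)
  p <- length(theta0)
  sdVec <- rep_len(proposalSd, p)
  set.seed(as.integer(seed))
  samples <- matrix(NA_real_, nIter, p,
                    dimnames = list(NULL, names(theta0)))
  lp <- numeric(nIter)
  cur <- theta0
  curLp <- logTarget(cur)
  if (!is.finite(curLp)) stop("log target is not finite at theta0")
  accepted <- 0L
  accWindow <- 0L
  for (i in seq_len(nIter)) {
    prop <- cur + stats::rnorm(p, 0, sdVec)
    propLp <- logTarget(prop)
    if (is.finite(propLp) && log(stats::runif(1)) < propLp - curLp) {
      cur <- prop; curLp <- propLp
      if (i > burnIn) accepted <- accepted + 1L
      accWindow <- accWindow + 1L
    }
    samples[i, ] <- cur
    lp[i] <- curLp
    if (adapt && i <= burnIn && i %% 100 == 0) {
      rate <- accWindow / 100
      sdVec <- sdVec * exp(0.5 * (rate - 0.3))
      accWindow <- 0L
    }
    if (i == burnIn + 1000L && accepted == 0L)
      warning("no proposals accepted in the first 1000 post-burn-in steps")
  }
  new("PosteriorChain", samples = samples, logPost = lp,
      accepted = accepted, proposalSd = sdVec,
      burnIn = as.integer(burnIn), seed = as.numeric(seed))
}

setMethod("show", "PosteriorChain", function(object) {
  n <- nrow(object@samples)
  post <- n - object@burnIn
  cat("PosteriorChain:", n, "iterations (", object@burnIn, "burn-in ),",
      ncol(object@samples), "parameters; acceptance",
      sprintf("%.2f", object@accepted / post), "\n")
})

#' Acceptance rate of a chain (post burn-in)
#' @param chain a \linkS4class{PosteriorChain}.
#' @return fraction of accepted proposals after burn-in.
#' @export
acceptanceRate <- function(chain) {
  chain@accepted / (nrow(chain@samples) - chain@burnIn)
}

#' Posterior summaries of a Metropolis-Hastings chain
#'
#' Per-parameter means, SDs and central credible intervals on the log10
#' and natural scales, computed from the post-burn-in samples.
#'
#' @param chain a \linkS4class{PosteriorChain}.
#' @param level credible level(s), default 0.95.
#' @return data.frame with one row per parameter: mean/sd on both scales
#'   and interval bounds per level (columns \code{lo95}/\code{hi95} etc.,
#'   natural scale).
#' @export
chainSummary <- function(chain, level = 0.95) {
  post <- chain@samples[(chain@burnIn + 1):nrow(chain@samples), ,
                        drop = FALSE]
  if (nrow(post) < 100) stop("post-burn-in chain must have >= 100 samples")
  out <- data.frame(parameter = colnames(post),
                    mean_log10 = colMeans(post),
                    sd_log10 = apply(post, 2, stats::sd),
                    mean = colMeans(10^post),
                    median = apply(10^post, 2, stats::median))
  for (lv in level) {
    a <- (1 - lv) / 2
    q <- apply(10^post, 2, stats::quantile, probs = c(a, 1 - a))
    tag <- round(100 * lv)
    out[[paste0("lo", tag)]] <- q[1, ]
    out[[paste0("hi", tag)]] <- q[2, ]
  }
  rownames(out) <- NULL
  out
}

#' FSP snapshot log-likelihood of per-cell counts
#'
#' Treats every cell as an independent snapshot draw from the chemical
#' master equation solution at its observation time: the log-likelihood
#' is the sum over cells of the log FSP probability of the observed state.
#' Counts that fall outside the truncation (or have zero projected
#' probability) contribute the machine-epsilon floor and are flagged.
#'
#' @param theta named positive rates (natural scale).
#' @param cellCounts data.frame with columns time, Rn, Rc, P (one row per
#'   cell).
#' @param bounds FSP truncation bounds, e.g. \code{c(Rn = 80, Rc = 80,
#'   P = 120)}.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param tol FSP propagation tolerance.
#' @return log-likelihood with attribute \code{nFlagged} (number of cells
#'   floored).
#' @export
fspSnapshotLoglik <- function(theta, cellCounts, bounds, schedule = NULL,
                              tol = 1e-10) {
  net <- constitutiveModel(theta)
  space <- enumerateStates(bounds)
  times <- sort(unique(cellCounts$time))
  sol <- integrateFSP(net, space, p0 = NULL, times = c(0, times),
                      schedule = schedule, tol = tol)
  floorLog <- log(.Machine$double.xmin)
  ll <- 0; nFlagged <- 0L
  for (i in seq_len(nrow(cellCounts))) {
    it <- match(TRUE, abs(sol@times - cellCounts$time[i]) < 1e-9)
    x <- c(cellCounts$Rn[i], cellCounts$Rc[i], cellCounts$P[i])
    idx <- stateIndex(space, x)
    pr <- if (is.na(idx)) 0 else sol@probs[idx, it]
    if (pr <= 0) { ll <- ll + floorLog; nFlagged <- nFlagged + 1L }
    else ll <- ll + log(pr)
  }
  if (nFlagged > 0)
    warning(nFlagged, " cell(s) outside the truncation; floored")
  attr(ll, "nFlagged") <- nFlagged
  ll
}

#' Export a chain and its summary to CSV
#'
#' @param chain a \linkS4class{PosteriorChain}.
#' @param file chain CSV path; the summary is written alongside with
#'   suffix \code{_summary.csv}.
#' @return \code{file}, invisibly.
#' @export
exportChain <- function(chain, file) {
  df <- data.frame(iteration = seq_len(nrow(chain@samples)),
                   chain@samples, logPost = chain@logPost)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  sfile <- sub("\\.csv$", "_summary.csv", file)
  utils::write.csv(chainSummary(chain), sfile, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}
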