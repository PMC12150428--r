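#' One step of the Gillespie direct method
#'
#' Given the current state and two uniform(0,1) variates, returns the
#' waiting time \eqn{\tau = \log(1/u_1)/a_0(x)} (exponential with rate
#' equal to the total propensity \eqn{a_0}) and the reaction index, the
#' smallest k whose cumulative propensity reaches \eqn{u_2 a_0}
#' (categorical with weights \eqn{w_\mu/a_0}).
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param x current nonnegative state.
#' @param t current time (min).
#' @param u1,u2 uniform(0,1) variates.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @return list with \code{tau} (min) and \code{reaction} (index), or
#'   \code{tau = Inf} when no reaction can fire (a0 = 0).
#' @export
sampleNextEvent <- function(net, x, t = 0, u1, u2, schedule = NULL) {
  stopifnot(u1 > 0, u1 < 1, u2 > 0, u2 < 1)
  w <- propensities(net, x, t, schedule)
  a0 <- sum(w)
  if (a0 <= 0) return(list(tau = Inf, reaction = NA_integer_))
  tau <- log(1 / u1) / a0
  k <- which(cumsum(w) >= u2 * a0)[1]
  list(tau = tau, reaction = as.integer(k))
}

#' Simulate one stochastic trajectory (Gillespie direct method)
#'
#' Exact kinetic Monte Carlo simulation of the jump process defined by the
#' network: at each step the waiting time is exponential with rate
#' \eqn{a_0(x)} and the reaction is categorical with weights
#' \eqn{w_\mu/a_0}; the state updates by the fired reaction's
#' stoichiometry column. With a drug schedule the simulation pauses at
#' \code{tDrug}, switches the export rate, and re-draws the waiting time
#' (exact by memorylessness of the exponential). Seeded runs are exactly
#' reproducible.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param x0 nonnegative integer initial state (default all zeros).
#' @param tMax final time (min).
#' @param seed integer RNG seed.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param maxEvents event cap guarding against runaway simulations.
#' @return list of class \code{"JumpTrajectory"} with elements
#'   \code{times} (event times), \code{states} (state after each event,
#'   events x species), \code{x0}, \code{final} and \code{seed}.
#' @examples
#' net <- constitutiveModel()
#' trj <- runSSA(net, tMax = 100, seed = 1)
#' tail(trj$states, 1)
#' @export
runSSA <- function(net, x0 = NULL, tMax, seed, schedule = NULL,
                   maxEvents = 1e6) {
  stopifnot(is(net, "ReactionNetwork"))
  N <- length(net@species)
  if (is.null(x0)) x0 <- integer(N)
  if (length(x0) != N) stop("x0 must have one entry per species")
  if (any(x0 < 0) || any(x0 != round(x0)))
    stop("x0 must be nonnegative integers")
  rates <- as.numeric(net@params[net@rateNames])
  drugReaction <- -1L; tDrug <- Inf; postFactor <- 1
  if (!is.null(schedule)) {
    drugReaction <- which(net@rateNames == net@drugTarget)[1] - 1L
    tDrug <- schedule@tDrug
    postFactor <- 1 - schedule@efficacy
  }
  set.seed(as.integer(seed))
  res <- ssa_run_cpp(net@stoich, rates, net@orders, as.integer(x0),
                     0, tMax, drugReaction, tDrug, postFactor,
                     as.integer(maxEvents))
  colnames(res$states) <- net@species
  structure(list(times = res$times, states = res$states,
                 x0 = as.integer(x0), final = res$final, seed = seed,
                 tMax = tMax, species = net@species),
            class = "JumpTrajectory")
}

# State at each grid time: right-continuous piecewise-constant sampling
# (state after the last event at or before t).
sampleTrajectory <- function(trj, grid) {
  N <- length(trj$x0)
  idx <- findInterval(grid, trj$times)
  out <- matrix(NA_integer_, length(grid), N)
  zero <- idx == 0L
  if (any(zero)) out[zero, ] <- matrix(trj$x0, sum(zero), N, byrow = TRUE)
  if (any(!zero)) out[!zero, ] <- trj$states[idx[!zero], , drop = FALSE]
  colnames(out) <- trj$species
  out
}

#' Simulate an ensemble of independent trajectories
#'
#' Runs \code{n} independent SSA trajectories (replicate i is seeded with
#' \code{baseSeed + i}, so ensembles are order-independent and two runs
#' with the same base seed are identical) and samples each on a common
#' grid.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param x0 initial state (default all zeros).
#' @param tMax final time (min).
#' @param n number of trajectories (>= 1).
#' @param baseSeed base RNG seed.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param grid sampling grid (min); defaults to \code{seq(0, tMax,
#'   length.out = 41)}.
#' @return an \linkS4class{Ensemble}.
#' @examples
#' net <- constitutiveModel()
#' ens <- runEnsemble(net, tMax = 100, n = 20, baseSeed = 7)
#' apply(ens@samples[, dim(ens@samples)[2], ], 2, mean)
#' @export
runEnsemble <- function(net, x0 = NULL, tMax, n, baseSeed, schedule = NULL,
                        grid = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(grid)) grid <- seq(0, tMax, length.out = 41)
  if (any(grid < 0) || any(grid > tMax)) stop("grid must lie within [0, tMax]")
  N <- length(net@species)
  samples <- array(NA_integer_, dim = c(n, length(grid), N),
                   dimnames = list(NULL, NULL, net@species))
  for (i in seq_len(n)) {
    trj <- runSSA(net, x0, tMax, seed = baseSeed + i, schedule = schedule)
    samples[i, , ] <- sampleTrajectory(trj, grid)
  }
  new("Ensemble", times = grid, species = net@species, samples = samples,
      baseSeed = as.numeric(baseSeed))
}

setMethod("show", "Ensemble", function(object) {
  d <- dim(object@samples)
  cat("Ensemble of", d[1], "trajectories,", d[2], "grid times,",
      d[3], "species (base seed", object@baseSeed, ")\n")
})

#' Ensemble means and SDs on the sampling grid
#'
#' @param ens an \linkS4class{Ensemble}.
#' @return data.frame with time, then mean and sd per species.
#' @export
ensembleStats <- function(ens) {
  mu <- apply(ens@samples, c(2, 3), mean)
  sd <- apply(ens@samples, c(2, 3), stats::sd)
  out <- data.frame(time = ens@times, mu, sd)
  names(out) <- c("time", paste0("mean_", ens@species),
                  paste0("sd_", ens@species))
  out
}

#' Normalized histogram of an ensemble at a grid time
#'
#' The Monte-Carlo estimator of the state distribution,
#' \eqn{\hat p(x, t) =} (number of trajectories at x at time t) / N, with
#' sampling error of order \eqn{N^{-1/2}}. Defaults to 25 bins over
#' [0, 65].
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param t a time on the sampling grid (no interpolation of
#'   distributions is performed).
#' @param species species name.
#' @param bins number of bins.
#' @param range histogram range (counts).
#' @return data.frame with bin midpoints and probabilities summing to 1.
#' @export
ensembleHistogram <- function(ens, t, species, bins = 25, range = c(0, 65)) {
  it <- match(TRUE, abs(ens@times - t) < 1e-9)
  if (is.na(it))
    stop("t = ", t, " is not on the sampling grid")
  is <- match(species, ens@species)
  if (is.na(is)) stop("unknown species: ", species)
  x <- ens@samples[, it, is]
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  # clamp values outside the range into the edge bins
  x <- pmin(pmax(x, range[1]), range[2])
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(mid = h$mids, prob = h$counts / length(x))
}

#' Export ensemble grid samples as long-format CSV
#'
#' Columns: replicate, time, then one column per species.
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
exportEnsemble <- function(ens, file) {
  d <- dim(ens@samples)
  long <- do.call(rbind, lapply(seq_len(d[1]), function(i) {
    data.frame(replicate = i, time = ens@times, ens@samples[i, , ])
  }))
  names(long) <- c("replicate", "time", ens@species)
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
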