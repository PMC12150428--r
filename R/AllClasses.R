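#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib scxkit, .registration = TRUE
NULL

#' Mass-action reaction network
#'
#' A chemically reacting system defined by its species, integer
#' stoichiometry matrix \eqn{S} (one column per reaction), per-reaction
#' mass-action propensity specifications, and a rate-parameter map. The
#' propensity of reaction \eqn{\mu} at state \eqn{x} is
#' \eqn{w_\mu(x) = k_\mu \prod_i \binom{x_i}{o_{i\mu}}}, where
#' \eqn{o_{i\mu}} are the reactant orders, so for example a reaction
#' consuming two molecules of a species contributes the combinatorial
#' factor \eqn{x(x-1)/2}.
#'
#' @slot species character vector of species names (rows of \code{stoich}).
#' @slot stoich integer matrix, N species x M reactions; column \eqn{s_\mu}
#'   is the net population change when reaction \eqn{\mu} fires.
#' @slot rateNames character vector of length M naming the rate constant
#'   used by each reaction (names into \code{params}).
#' @slot orders integer matrix, N x M, reactant order of each species in
#'   each reaction.
#' @slot params named numeric vector of rate constants (units 1/min).
#' @slot drugTarget name of the rate constant modulated by a
#'   \linkS4class{DrugSchedule} (for these networks, \code{"k_t"}).
#' @seealso [constitutiveModel()], [twoStateModel()], [propensities()]
#' @export
setClass("ReactionNetwork",
  representation(species = "character", stoich = "matrix",
                 rateNames = "character", orders = "matrix",
                 params = "numeric", drugTarget = "character"))

setValidity("ReactionNetwork", function(object) {
  msg <- character(0)
  N <- length(object@species); M <- ncol(object@stoich)
  if (nrow(object@stoich) != N)
    msg <- c(msg, "stoich must have one row per species")
  if (length(object@rateNames) != M)
    msg <- c(msg, "rateNames must have one entry per reaction")
  if (!all(dim(object@orders) == dim(object@stoich)))
    msg <- c(msg, "orders must match stoich dimensions")
  if (!all(object@rateNames %in% names(object@params)))
    msg <- c(msg, "every propensity must reference a declared parameter")
  if (any(!is.finite(object@params)) || any(object@params <= 0))
    msg <- c(msg, "all rate parameters must be positive and finite")
  if (any(object@orders < 0))
    msg <- c(msg, "reactant orders must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Step-change drug schedule for mRNA export
#'
#' Models a drug applied at time \code{tDrug} that inhibits nuclear mRNA
#' export with efficacy \code{efficacy} = fraction of the export rate
#' removed: the target rate is \eqn{k_t} for \eqn{t < t_{drug}} and
#' \eqn{(1 - e)\,k_t} for \eqn{t \ge t_{drug}}, constant thereafter. A
#' 90\%-effective drug (\code{efficacy = 0.9}) leaves 10\% of the baseline
#' export rate.
#'
#' @slot tDrug time of drug application (min, >= 0).
#' @slot efficacy fraction of the export rate removed, in [0, 1].
#' @seealso [drugSchedule()], [effectiveRate()]
#' @export
setClass("DrugSchedule",
  representation(tDrug = "numeric", efficacy = "numeric"))

setValidity("DrugSchedule", function(object) {
  msg <- character(0)
  if (length(object@tDrug) != 1 || !is.finite(object@tDrug) || object@tDrug < 0)
    msg <- c(msg, "tDrug must be a single nonnegative time (min)")
  if (length(object@efficacy) != 1 || !is.finite(object@efficacy) ||
      object@efficacy < 0 || object@efficacy > 1)
    msg <- c(msg, "efficacy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Truncated state space for the finite state projection
#'
#' Lexicographic enumeration of the box \eqn{\{0..b_1\} \times \cdots
#' \times \{0..b_N\}} with the first species varying slowest, together
#' with the bijective state <-> integer index map used by the generator.
#'
#' @slot bounds named integer vector of per-species upper bounds.
#' @slot species species names (same order as bounds).
#' @slot states integer matrix (number of states x N), row i is the state
#'   with index i.
#' @seealso [enumerateStates()], [stateIndex()]
#' @export
setClass("StateSpace",
  representation(bounds = "integer", species = "character",
                 states = "matrix"))

setValidity("StateSpace", function(object) {
  msg <- character(0)
  if (any(object@bounds < 0)) msg <- c(msg, "bounds must be nonnegative")
  if (nrow(object@states) != prod(object@bounds + 1L))
    msg <- c(msg, "number of states must equal prod(bounds + 1)")
  if (length(msg)) msg else TRUE
})

#' Finite state projection solution of the chemical master equation
#'
#' Time-indexed probability vectors over a truncated state space plus the
#' absorbing-sink mass \eqn{g(t)}, which is the exact probability that the
#' process has left the truncation by time t and hence a certificate of
#' the truncation error.
#'
#' @slot space the \linkS4class{StateSpace} used.
#' @slot times numeric grid (min).
#' @slot probs matrix (number of states x number of times) of state
#'   probabilities.
#' @slot sink numeric vector, sink mass g(t) per grid time (nondecreasing).
#' @seealso [integrateFSP()], [sinkMass()], [marginalDistribution()],
#'   [fspMoments()]
#' @export
setClass("FSPSolution",
  representation(space = "StateSpace", times = "numeric",
                 probs = "matrix", sink = "numeric"))

setValidity("FSPSolution", function(object) {
  msg <- character(0)
  if (ncol(object@probs) != length(object@times))
    msg <- c(msg, "probs must have one column per time")
  if (length(object@sink) != length(object@times))
    msg <- c(msg, "sink must have one entry per time")
  if (any(object@probs < -1e-12))
    msg <- c(msg, "probabilities must be >= -1e-12")
  mass <- colSums(object@probs) + object@sink
  if (any(abs(mass - 1) > 1e-6))
    msg <- c(msg, "probability mass plus sink must equal 1 within 1e-6")
  if (any(diff(object@sink) < -1e-9))
    msg <- c(msg, "sink mass must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' Ensemble of stochastic trajectories sampled on a common grid
#'
#' @slot times common sampling grid (min).
#' @slot species species names.
#' @slot samples integer array (replicate x time x species), the state of
#'   each replicate at each grid time (right-continuous piecewise-constant
#'   sampling: the state after the last event at or before t).
#' @slot baseSeed seed from which per-replicate seeds were derived.
#' @seealso [runEnsemble()], [ensembleHistogram()]
#' @export
setClass("Ensemble",
  representation(times = "numeric", species = "character",
                 samples = "array", baseSeed = "numeric"))

setValidity("Ensemble", function(object) {
  d <- dim(object@samples)
  msg <- character(0)
  if (length(d) != 3) msg <- c(msg, "samples must be replicate x time x species")
  else {
    if (d[2] != length(object@times)) msg <- c(msg, "time dimension mismatch")
    if (d[3] != length(object@species)) msg <- c(msg, "species dimension mismatch")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic cell geometry
#'
#' A cell drawn as two circles: the nucleus strictly inside the cytosol,
#' both inside the image.
#'
#' @slot width,height image size in pixels.
#' @slot nucleusCenter,cytosolCenter (row, col) centers in pixels.
#' @slot nucleusRadius,cytosolRadius radii in pixels.
#' @seealso [cellGeometry()]
#' @export
setClass("CellGeometry",
  representation(width = "numeric", height = "numeric",
                 nucleusCenter = "numeric", nucleusRadius = "numeric",
                 cytosolCenter = "numeric", cytosolRadius = "numeric"))

setValidity("CellGeometry", function(object) {
  msg <- character(0)
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "image size must be positive")
  if (object@nucleusRadius <= 0 || object@cytosolRadius <= 0)
    msg <- c(msg, "radii must be positive")
  # nucleus strictly inside cytosol
  d <- sqrt(sum((object@nucleusCenter - object@cytosolCenter)^2))
  if (d + object@nucleusRadius >= object@cytosolRadius)
    msg <- c(msg, "nucleus circle must lie strictly inside the cytosol circle")
  cc <- object@cytosolCenter; r <- object@cytosolRadius
  if (cc[1] - r < 1 || cc[1] + r > object@height ||
      cc[2] - r < 1 || cc[2] + r > object@width)
    msg <- c(msg, "cytosol circle must lie inside the image")
  if (length(msg)) msg else TRUE
})

#' Two-channel synthetic image stack with ground truth
#'
#' @slot pixels numeric array (frame, channel, row, col); channel 1 is the
#'   RNA channel, channel 2 the protein channel; 16-bit intensity range.
#' @slot times frame times (min).
#' @slot molecules data.frame of per-frame ground-truth molecule records
#'   (frame, time, id, species, row, col).
#' @slot counts data.frame of per-frame true counts (time, Rn, Rc, P).
#' @slot geometry the \linkS4class{CellGeometry} used.
#' @seealso [simulateCellImages()], [generateDataset()]
#' @export
setClass("ImageStack",
  representation(pixels = "array", times = "numeric",
                 molecules = "data.frame", counts = "data.frame",
                 geometry = "CellGeometry"))

setValidity("ImageStack", function(object) {
  d <- dim(object@pixels)
  msg <- character(0)
  if (length(d) != 4) msg <- c(msg, "pixels must be frame x channel x row x col")
  else if (d[1] != length(object@times)) msg <- c(msg, "frame/time mismatch")
  if (length(msg)) msg else TRUE
})

#' Metropolis-Hastings posterior chain
#'
#' Samples in log10-parameter space with log-posterior values and
#' acceptance bookkeeping.
#'
#' @slot samples matrix (iterations x parameters), log10 scale.
#' @slot logPost log-posterior at each sample.
#' @slot accepted number of accepted proposals.
#' @slot proposalSd per-parameter random-walk proposal SDs (log10 units).
#' @slot burnIn number of initial iterations treated as burn-in.
#' @slot seed RNG seed used.
#' @seealso [metropolisHastings()], [chainSummary()]
#' @export
setClass("PosteriorChain",
  representation(samples = "matrix", logPost = "numeric",
                 accepted = "integer", proposalSd = "numeric",
                 burnIn = "integer", seed = "numeric"))

setValidity("PosteriorChain", function(object) {
  msg <- character(0)
  if (nrow(object@samples) != length(object@logPost))
    msg <- c(msg, "logPost must have one value per sample")
  if (object@accepted > nrow(object@samples))
    msg <- c(msg, "acceptance count cannot exceed iterations")
  if (any(!is.finite(object@logPost)))
    msg <- c(msg, "log-posterior values must be finite")
  if (length(msg)) msg else TRUE
})
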