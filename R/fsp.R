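#' Enumerate a truncated state space
#'
#' Lexicographic enumeration of \eqn{\{0..b_1\} \times \cdots \times
#' \{0..b_N\}}, first species slowest. The index map is the mixed-radix
#' encoding \eqn{i(x) = 1 + \sum_k x_k \prod_{l > k}(b_l + 1)} and
#' round-trips exactly.
#'
#' @param bounds named nonnegative integer vector of per-species upper
#'   bounds, e.g. \code{c(Rn = 80, Rc = 80, P = 120)}.
#' @return a \linkS4class{StateSpace}.
#' @examples
#' sp <- enumerateStates(c(Rn = 1, Rc = 1, P = 1))
#' nStates(sp)  # 8
#' @export
enumerateStates <- function(bounds) {
  if (any(bounds < 0) || any(bounds != round(bounds)))
    stop("bounds must be nonnegative integers")
  bounds <- as.integer(bounds)
  if (is.null(names(bounds)) && length(bounds) == 3)
    names(bounds) <- c("Rn", "Rc", "P")
  nb <- bounds + 1L
  N <- length(bounds)
  # expand.grid varies its FIRST factor fastest; pass species in reverse
  # so the last species varies fastest (first species slowest).
  g <- do.call(expand.grid, lapply(rev(nb), function(k) 0:(k - 1L)))
  states <- as.matrix(g[, rev(seq_len(N)), drop = FALSE])
  dimnames(states) <- list(NULL, names(bounds))
  storage.mode(states) <- "integer"
  new("StateSpace", bounds = bounds, species = names(bounds),
      states = states)
}

#' @describeIn nStates number of states in a truncated state space
#' @export
setMethod("nStates", "StateSpace",
          function(object) nrow(object@states))

#' @describeIn nStates number of retained states of an FSP solution
#' @export
setMethod("nStates", "FSPSolution",
          function(object) nrow(object@space@states))

#' @describeIn speciesNames species of a state space
#' @export
setMethod("speciesNames", "StateSpace", function(object) object@species)

setMethod("show", "StateSpace", function(object) {
  cat("StateSpace:", nrow(object@states), "states; bounds",
      paste(sprintf("%s<=%d", object@species, object@bounds),
            collapse = ", "), "\n")
})

#' Index of states in a state space
#'
#' @param space a \linkS4class{StateSpace}.
#' @param x a state vector, or a matrix with one state per row.
#' @return integer index (1-based); NA for states outside the bounds.
#' @export
stateIndex <- function(space, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nb <- space@bounds + 1L
  N <- length(nb)
  radix <- rev(cumprod(rev(c(nb[-1], 1L))))
  inside <- rowSums(x < 0 | x > matrix(space@bounds, nrow(x), N,
                                       byrow = TRUE)) == 0
  idx <- as.integer(x %*% radix) + 1L
  idx[!inside] <- NA_integer_
  idx
}

#' Build the FSP infinitesimal generator on a truncated state space
#'
#' The sparse matrix A with \eqn{A_{ij} = w_\mu(x_j)} whenever
#' \eqn{x_i = x_j + s_\mu} is retained, and
#' \eqn{A_{jj} = -\sum_\mu w_\mu(x_j)}. Flux from a retained state to a
#' state outside the bounds is implicitly routed to the absorbing sink:
#' those columns have a strictly negative sum, and the sink row
#' \eqn{-\mathbf{1}^T A} restores exact probability conservation.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param space a \linkS4class{StateSpace} over the network's species.
#' @param t time at which rates are evaluated (with \code{schedule}, pick
#'   a time on the segment of interest).
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @return a \code{dgCMatrix} of dimension nStates x nStates.
#' @export
buildGenerator <- function(net, space, t = 0, schedule = NULL) {
  stopifnot(is(net, "ReactionNetwork"), is(space, "StateSpace"))
  if (!identical(space@species, net@species))
    stop("state space species must match network species")
  states <- space@states
  n <- nrow(states)
  N <- ncol(states)
  nb <- space@bounds + 1L
  radix <- rev(cumprod(rev(c(nb[-1], 1L))))
  rates <- segmentRates(net, t, schedule)
  M <- ncol(net@stoich)

  ii <- vector("list", M + 1)
  jj <- vector("list", M + 1)
  xx <- vector("list", M + 1)
  diagTot <- numeric(n)
  jAll <- seq_len(n)
  for (mu in seq_len(M)) {
    w <- rep(rates[mu], n)
    nz <- which(net@orders[, mu] > 0L)
    for (i in nz) {
      o <- net@orders[i, mu]
      w <- w * if (o == 1L) states[, i] else choose(states[, i], o)
    }
    diagTot <- diagTot + w
    target <- states + matrix(net@stoich[, mu], n, N, byrow = TRUE)
    ok <- w > 0
    for (i in seq_len(N))
      ok <- ok & target[, i] >= 0L & target[, i] <= space@bounds[i]
    ti <- as.integer(target[ok, , drop = FALSE] %*% radix) + 1L
    ii[[mu]] <- ti
    jj[[mu]] <- jAll[ok]
    xx[[mu]] <- w[ok]
  }
  ii[[M + 1]] <- jAll
  jj[[M + 1]] <- jAll
  xx[[M + 1]] <- -diagTot
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# exp(A * tau) v by uniformization with l1 tail error <= tol.
expAtv <- function(A, v, tau, tol = 1e-10) {
  if (tau == 0) return(v)
  lambda <- max(-Matrix::diag(A)) * 1.0000001
  if (lambda <= 0) return(v)
  P <- A / lambda + Matrix::Diagonal(nrow(A))
  P <- methods::as(P, "CsparseMatrix")
  unif_expv_cpp(P@i, P@p, P@x, as.numeric(v), lambda * tau, tol)
}

#' Integrate the projected master equation
#'
#' Solves the sink-augmented linear ODE
#' \eqn{dP^{FSP}/dt = A_{JJ} P^{FSP}} on the truncated state space and
#' reports the sink mass \eqn{g(t) = 1 - \sum_x p(x, t)} at each grid
#' time. Each grid interval is propagated by the exact action of the
#' matrix exponential, computed by uniformization (a Poisson-weighted
#' power series of the substochastic matrix \eqn{I + A/\Lambda}, truncated
#' at a tail mass below \code{tol}); all arithmetic is on nonnegative
#' quantities so the solution cannot lose positivity. With a drug
#' schedule the generator is rebuilt with the post-drug export rate
#' exactly at \code{tDrug}.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param space a \linkS4class{StateSpace}; see [enumerateStates()].
#' @param p0 initial distribution: a probability vector over the retained
#'   states, or a single state vector (delta distribution). Defaults to a
#'   delta at the origin.
#' @param times nondecreasing grid (min) at which to record the solution.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param tol l1 truncation tolerance of the uniformized exponential per
#'   grid interval.
#' @return an \linkS4class{FSPSolution}.
#' @examples
#' net <- constitutiveModel()
#' sp <- enumerateStates(c(Rn = 12, Rc = 10, P = 25))
#' sol <- integrateFSP(net, sp, times = c(0, 5, 10))
#' sinkMass(sol)
#' @export
integrateFSP <- function(net, space, p0 = NULL, times, schedule = NULL,
                         tol = 1e-10) {
  stopifnot(is(space, "StateSpace"))
  n <- nrow(space@states)
  if (is.null(p0)) p0 <- integer(length(space@species))
  if (length(p0) == length(space@species) && all(p0 == round(p0)) &&
      (length(p0) != n || sum(p0) != 1)) {
    idx <- stateIndex(space, as.integer(p0))
    if (is.na(idx)) stop("initial state lies outside the bounds")
    p <- numeric(n); p[idx] <- 1
  } else {
    if (length(p0) != n) stop("p0 must have one entry per state")
    if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
      stop("p0 must be a probability vector (nonnegative, sums to 1)")
    p <- as.numeric(p0)
  }
  if (is.unsorted(times)) stop("times must be nondecreasing")

  tDrug <- if (is.null(schedule)) Inf else schedule@tDrug
  A_pre <- buildGenerator(net, space, t = 0, schedule = schedule)
  A_post <- NULL

  probs <- matrix(NA_real_, n, length(times))
  tcur <- times[1]
  probs[, 1] <- p
  if (length(times) > 1) {
    for (k in 2:length(times)) {
      tnext <- times[k]
      if (tcur < tDrug && tnext > tDrug) {
        p <- expAtv(A_pre, p, tDrug - tcur, tol)
        tcur <- tDrug
      }
      if (tcur >= tDrug) {
        if (is.null(A_post))
          A_post <- buildGenerator(net, space, t = tDrug, schedule = schedule)
        p <- expAtv(A_post, p, tnext - tcur, tol)
      } else {
        p <- expAtv(A_pre, p, tnext - tcur, tol)
      }
      tcur <- tnext
      probs[, k] <- p
    }
  }
  sink <- 1 - colSums(probs)
  sink[sink < 0] <- 0
  if (any(abs(colSums(probs) + pmax(sink, 0) - 1) > 1e-6))
    stop("numerical failure: probability mass defect exceeds 1e-6")
  new("FSPSolution", space = space, times = times, probs = probs,
      sink = sink)
}

#' @describeIn sinkMass truncation-error mass per grid time
#' @export
setMethod("sinkMass", "FSPSolution", function(object) {
  stats::setNames(object@sink, object@times)
})

setMethod("show", "FSPSolution", function(object) {
  cat("FSPSolution:", nrow(object@probs), "states x",
      length(object@times), "times; g(final) =",
      signif(object@sink[length(object@sink)], 3), "\n")
})

#' Expand the projection until the truncation error meets a tolerance
#'
#' Integrates on the current bounds and, whenever the final-time sink mass
#' exceeds \code{eps}, enlarges every bound by \code{growth} and restarts
#' (the FSP error decreases monotonically as states are added, so the loop
#' terminates for any reachable tolerance). Returns the first solution
#' with \eqn{g(t_{final}) \le eps}.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param p0 initial state vector (delta) or probability vector matching
#'   the initial bounds.
#' @param tFinal final time (min).
#' @param eps tolerance on \eqn{g(t_{final})} (> 0).
#' @param bounds initial per-species bounds.
#' @param growth additive bound increment per expansion (scalar or
#'   per-species).
#' @param maxStates cap on the state-space size; exceeding it raises an
#'   error reporting the last achieved g.
#' @param times optional recording grid (default \code{c(0, tFinal)}).
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param tol propagation tolerance, as in [integrateFSP()].
#' @return an \linkS4class{FSPSolution} with \code{g(tFinal) <= eps}.
#' @export
expandUntilTolerance <- function(net, p0 = NULL, tFinal, eps, bounds,
                                 growth = 10L, maxStates = 5e6,
                                 times = NULL, schedule = NULL,
                                 tol = 1e-10) {
  if (eps <= 0) stop("eps must be > 0")
  if (is.null(times)) times <- c(0, tFinal)
  if (abs(times[length(times)] - tFinal) > 1e-9)
    stop("times must end at tFinal")
  repeat {
    if (prod(bounds + 1) > maxStates)
      stop("bound cap reached (", prod(bounds + 1), " states > ", maxStates,
           " allowed); last g(tFinal) = ", signif(attr(bounds, "lastG"), 3))
    space <- enumerateStates(bounds)
    sol <- integrateFSP(net, space, p0 = p0, times = times,
                        schedule = schedule, tol = tol)
    g <- sol@sink[length(sol@sink)]
    if (g <= eps) return(sol)
    bounds <- bounds + growth
    attr(bounds, "lastG") <- g
  }
}

#' Marginal distribution over a subset of species
#'
#' Sums the joint FSP distribution over the left-out species. The total
#' mass of the marginal equals \eqn{1 - g(t)}.
#'
#' @param sol an \linkS4class{FSPSolution}.
#' @param t a grid time.
#' @param keep character vector of species to keep (one or more).
#' @return for one kept species, a numeric vector indexed by count
#'   0..bound; for several, an array with one dimension per kept species.
#' @export
marginalDistribution <- function(sol, t, keep) {
  it <- match(TRUE, abs(sol@times - t) < 1e-9)
  if (is.na(it)) stop("t = ", t, " is not on the solution grid")
  sp <- sol@space@species
  bad <- setdiff(keep, sp)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  nb <- sol@space@bounds + 1L
  # states are enumerated with the first species slowest, so the flat
  # vector reshapes into an array with dims rev(nb) (last species fastest)
  arr <- array(sol@probs[, it], dim = rev(nb))
  keepRevIdx <- length(sp) + 1L - match(keep, sp)  # dims of arr are reversed
  m <- apply(arr, sort(keepRevIdx), sum)
  if (length(keep) == 1L) {
    names(m) <- 0:(nb[match(keep, sp)] - 1L)
    return(m)
  }
  # apply() returns dims along sorted reversed-array margins, i.e. kept
  # species in reverse canonical order; permute to the requested order
  kept_sp <- sp[sort(match(keep, sp))]
  m <- aperm(m, rev(seq_along(kept_sp)))
  dimnames(m) <- lapply(kept_sp, function(s) 0:(nb[match(s, sp)] - 1L))
  names(dimnames(m)) <- kept_sp
  aperm(m, match(keep, kept_sp))
}

#' Moments of an FSP solution
#'
#' Means, variances and covariances of each species computed from the
#' joint distribution: \eqn{E\{R_n^a R_c^b P^c\} = \sum i^a j^b k^c
#' Pr(i,j,k)} and \eqn{\sigma_{xy} = E\{xy\} - E\{x\}E\{y\}}. Moments are
#' normalized by the retained mass \eqn{1 - g(t)} so they estimate the
#' conditional moments given the process has not left the projection.
#'
#' @param sol an \linkS4class{FSPSolution}.
#' @param t optional single grid time; default all grid times.
#' @return data.frame with one row per time: means (\code{mean_*}),
#'   variances (\code{var_*}) and pairwise covariances (\code{cov_*_*}).
#' @export
fspMoments <- function(sol, t = NULL) {
  idx <- if (is.null(t)) seq_along(sol@times) else {
    it <- match(TRUE, abs(sol@times - t) < 1e-9)
    if (is.na(it)) stop("t = ", t, " is not on the solution grid")
    it
  }
  st <- sol@space@states
  sp <- sol@space@species
  N <- length(sp)
  out <- lapply(idx, function(it) {
    p <- sol@probs[, it]
    mass <- sum(p)
    if (mass <= 0) stop("no retained mass at t = ", sol@times[it])
    p <- p / mass
    mu <- as.numeric(crossprod(st, p))
    xc <- sweep(st, 2, mu)
    cv <- crossprod(xc, xc * p)
    row <- c(time = sol@times[it],
             stats::setNames(mu, paste0("mean_", sp)),
             stats::setNames(diag(cv), paste0("var_", sp)))
    for (a in seq_len(N - 1)) for (b in (a + 1):N)
      row[paste0("cov_", sp[a], "_", sp[b])] <- cv[a, b]
    row
  })
  as.data.frame(do.call(rbind, out))
}

#' Export FSP probability snapshots as CSV
#'
#' One row per retained state: state index, species counts, probability.
#'
#' @param sol an \linkS4class{FSPSolution}.
#' @param t a grid time.
#' @param file output path.
#' @param dropZero drop states with probability below \code{1e-16}.
#' @return \code{file}, invisibly.
#' @export
exportDistribution <- function(sol, t, file, dropZero = TRUE) {
  it <- match(TRUE, abs(sol@times - t) < 1e-9)
  if (is.na(it)) stop("t = ", t, " is not on the solution grid")
  p <- sol@probs[, it]
  keep <- if (dropZero) p > 1e-16 else rep(TRUE, length(p))
  df <- data.frame(index = which(keep), sol@space@states[keep, , drop = FALSE],
                   probability = p[keep])
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
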