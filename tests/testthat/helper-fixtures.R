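# Shared fixtures: small networks and geometries used across test files.

tableRates <- function() defaultParameters()

# A scaled-down expression model whose stationary distribution has small
# means, so FSP tests run on a few thousand states.
smallRates <- function() {
  c(k_r = 0.5, k_t = 0.1, k_p = 0.2, gamma_r = 0.1, gamma_p = 0.5)
}

# Birth-only network (pure Poisson process) built directly; used for
# waiting-time statistics.
birthOnlyNet <- function(rate = 2) {
  new("ReactionNetwork", species = "X",
      stoich = matrix(1L, 1, 1, dimnames = list("X", "r1")),
      rateNames = "k_r",
      orders = matrix(0L, 1, 1, dimnames = list("X", "r1")),
      params = c(k_r = rate), drugTarget = "k_r")
}

# Bimolecular toy network: 2 A -> B at rate k, to exercise the
# combinatorial mass-action factor x(x-1)/2.
dimerNet <- function(k = 1) {
  new("ReactionNetwork", species = c("A", "B"),
      stoich = matrix(c(-2L, 1L), 2, 1, dimnames = list(c("A", "B"), "r1")),
      rateNames = "k",
      orders = matrix(c(2L, 0L), 2, 1, dimnames = list(c("A", "B"), "r1")),
      params = c(k = k), drugTarget = "k")
}

smallGeometry <- function() {
  cellGeometry(width = 160, height = 160, cytosolRadius = 60,
               nucleusRadius = 25)
}

# Dense brute-force FSP generator for tiny state spaces: an independent
# oracle for buildGenerator built state-by-state from first principles.
denseGeneratorOracle <- function(net, space, schedule = NULL, t = 0) {
  n <- nrow(space@states)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    x <- space@states[j, ]
    w <- propensities(net, x, t = t, schedule = schedule)
    A[j, j] <- -sum(w)
    for (mu in seq_along(w)) {
      if (w[mu] <= 0) next
      target <- x + net@stoich[, mu]
      idx <- stateIndex(space, target)
      if (!is.na(idx)) A[idx, j] <- A[idx, j] + w[mu]
    }
  }
  A
}
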