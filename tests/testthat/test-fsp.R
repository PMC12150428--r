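test_that("state enumeration and the index map round-trip", {
  sp <- enumerateStates(c(Rn = 1, Rc = 1, P = 1))
  expect_identical(nStates(sp), 8L)
  sp0 <- enumerateStates(c(Rn = 0, Rc = 0, P = 0))
  expect_identical(nStates(sp0), 1L)
  expect_identical(unname(sp0@states[1, ]), c(0L, 0L, 0L))
  expect_identical(stateIndex(sp0, c(0, 0, 0)), 1L)
  expect_error(enumerateStates(c(-1, 2, 2)), "nonnegative")

  set.seed(5)
  sp2 <- enumerateStates(c(Rn = 7, Rc = 4, P = 9))
  expect_identical(nStates(sp2), 8L * 5L * 10L)
  # round trip at random rows
  for (i in sample(nStates(sp2), 25))
    expect_identical(stateIndex(sp2, sp2@states[i, ]), i)
  # out-of-bounds states map to NA
  expect_identical(stateIndex(sp2, c(8, 0, 0)), NA_integer_)
  # lexicographic order, first species slowest
  expect_identical(unname(sp2@states[1:2, "P"]), 0:1)
  expect_identical(unname(sp2@states[nStates(sp2), ]), c(7L, 4L, 9L))
})

test_that("the sparse generator matches a brute-force dense construction", {
  net <- constitutiveModel(tableRates())
  sp <- enumerateStates(c(Rn = 4, Rc = 3, P = 5))
  A <- buildGenerator(net, sp)
  expect_equal(as.matrix(A), denseGeneratorOracle(net, sp),
               tolerance = 1e-12, ignore_attr = TRUE)
  # transcription out of the empty state
  i000 <- stateIndex(sp, c(0, 0, 0))
  i100 <- stateIndex(sp, c(1, 0, 0))
  expect_equal(A[i100, i000], 2)
  expect_equal(A[i000, i000], -2)
  # probability conservation: column sums are -(flux to the sink) <= 0
  cs <- Matrix::colSums(A)
  expect_true(all(cs <= 1e-12))
  # interior states with no boundary-crossing reaction conserve exactly
  expect_lt(abs(cs[i000]), 1e-12)
  # under the drug the export entries shrink by 1 - efficacy
  Ad <- buildGenerator(net, sp, t = 130, schedule = drugSchedule(120, 0.9))
  i110 <- stateIndex(sp, c(1, 1, 0))
  expect_equal(Ad[stateIndex(sp, c(0, 1, 0)), i100], 0.0083)
})

test_that("FSP integration matches the dense matrix exponential", {
  net <- constitutiveModel(smallRates())
  sp <- enumerateStates(c(Rn = 6, Rc = 6, P = 8))
  sol <- integrateFSP(net, sp, times = c(0, 3, 9))
  A <- buildGenerator(net, sp)
  p0 <- numeric(nStates(sp)); p0[1] <- 1
  for (k in 2:3) {
    pd <- as.numeric(Matrix::expm(A * sol@times[k]) %*% p0)
    expect_lt(max(abs(sol@probs[, k] - pd)), 1e-9)
  }
})

test_that("sink mass starts at zero, never decreases, and conserves mass", {
  net <- constitutiveModel(tableRates())
  sp <- enumerateStates(c(Rn = 10, Rc = 8, P = 15))
  sol <- integrateFSP(net, sp, times = seq(0, 40, 10),
                      schedule = drugSchedule(20, 0.9))
  g <- sinkMass(sol)
  expect_identical(unname(g[1]), 0)
  expect_true(all(diff(g) >= -1e-12))
  expect_true(all(abs(colSums(sol@probs) + sol@sink - 1) < 1e-8))
  expect_true(all(sol@probs >= -1e-12))
})

test_that("marginals preserve retained mass and collapse deltas", {
  net <- constitutiveModel(tableRates())
  sp <- enumerateStates(c(Rn = 6, Rc = 7, P = 8))
  # delta initial distribution at (3, 4, 5)
  sol <- integrateFSP(net, sp, p0 = c(3, 4, 5), times = c(0, 2))
  mRn <- marginalDistribution(sol, 0, "Rn")
  expect_equal(unname(mRn[as.character(3)]), 1)
  expect_equal(sum(mRn), 1)
  m2 <- marginalDistribution(sol, 2, c("Rn", "Rc"))
  expect_equal(sum(m2), 1 - sinkMass(sol)[[2]], tolerance = 1e-10)
  expect_identical(unname(dim(m2)), c(7L, 8L))
  # joint marginal over reordered species transposes consistently
  m2b <- marginalDistribution(sol, 2, c("Rc", "Rn"))
  expect_equal(m2b, t(m2), ignore_attr = TRUE)
  # full marginal over one species agrees with summing the joint
  expect_equal(unname(marginalDistribution(sol, 2, "Rc")),
               unname(colSums(m2)))
  expect_error(marginalDistribution(sol, 2, "Q"), "unknown species")
  expect_error(marginalDistribution(sol, 1.23, "Rn"), "grid")
})

test_that("moments of a delta are exact and match the state", {
  net <- constitutiveModel(tableRates())
  sp <- enumerateStates(c(Rn = 6, Rc = 7, P = 8))
  sol <- integrateFSP(net, sp, p0 = c(3, 4, 5), times = c(0, 1))
  m <- fspMoments(sol, t = 0)
  expect_equal(unname(unlist(m[1, c("mean_Rn", "mean_Rc", "mean_P")])),
               c(3, 4, 5))
  expect_equal(unname(unlist(m[1, c("var_Rn", "var_Rc", "var_P",
                                    "cov_Rn_Rc", "cov_Rn_P",
                                    "cov_Rc_P")])),
               rep(0, 6))
})

test_that("stationary mRNA marginals are Poisson with the birth-death means", {
  p <- smallRates()
  net <- constitutiveModel(p)
  sp <- enumerateStates(c(Rn = 15, Rc = 15, P = 20))
  tEnd <- 80  # ~8 half-lives of the slowest mode at these rates
  sol <- integrateFSP(net, sp, times = c(0, tEnd))
  g <- sinkMass(sol)[[2]]
  ss <- steadyState(p)
  for (s in c("Rn", "Rc")) {
    m <- marginalDistribution(sol, tEnd, s)
    pois <- stats::dpois(0:(length(m) - 1), ss[[s]])
    tv <- 0.5 * (sum(abs(m - pois)) + (1 - sum(pois)))
    expect_lt(tv, 1e-3 + g)
  }
  # protein is over-dispersed: Fano factor > 1
  mom <- fspMoments(sol, t = tEnd)
  expect_gt(mom$var_P / mom$mean_P, 1)
  expect_equal(mom$var_Rn / mom$mean_Rn, 1, tolerance = 0.02)
})

test_that("FSP means agree with the ODE for an affine network", {
  net <- constitutiveModel(smallRates())
  sp <- enumerateStates(c(Rn = 14, Rc = 14, P = 18))
  times <- c(0, 10, 30, 60)
  sol <- integrateFSP(net, sp, times = times)
  mom <- fspMoments(sol)
  ode <- solveODE(net, times = times)
  expect_lt(max(abs(as.matrix(mom[, 2:4]) - as.matrix(ode[, 2:4]))), 0.05)
})

test_that("the FSP is a lower bound on empirical SSA frequencies", {
  net <- constitutiveModel(smallRates())
  sp <- enumerateStates(c(Rn = 10, Rc = 10, P = 12))
  tObs <- 15
  sol <- integrateFSP(net, sp, times = c(0, tObs))
  nSSA <- 2000
  ens <- runEnsemble(net, tMax = tObs, n = nSSA, baseSeed = 77,
                     grid = c(0, tObs))
  xs <- ens@samples[, 2, ]
  inside <- xs[, 1] <= 10 & xs[, 2] <= 10 & xs[, 3] <= 12
  idx <- stateIndex(sp, xs[inside, , drop = FALSE])
  freq <- tabulate(idx, nStates(sp)) / nSSA
  se <- sqrt(pmax(freq * (1 - freq), 1e-9) / nSSA)
  checks <- order(-sol@probs[, 2])[1:50]  # spot-check the likeliest states
  expect_true(all(sol@probs[checks, 2] <= freq[checks] + 4 * se[checks]
                  + 1e-6))
})

test_that("expanding the projection reduces the sink mass to tolerance", {
  net <- constitutiveModel(smallRates())
  # generous bounds: returns immediately with the initial projection
  sol <- expandUntilTolerance(net, tFinal = 10, eps = 0.5,
                              bounds = c(Rn = 12, Rc = 12, P = 15))
  expect_identical(nStates(sol), 13L * 13L * 16L)
  # tight bounds force expansion; the contract guarantees g <= eps
  sol2 <- expandUntilTolerance(net, tFinal = 30, eps = 1e-3,
                               bounds = c(Rn = 2, Rc = 2, P = 2),
                               growth = 4L)
  expect_lte(sinkMass(sol2)[[2]], 1e-3)
  expect_gt(nStates(sol2), 27L)
  # monotonicity: enlarging the bounds never increases g
  sA <- integrateFSP(net, enumerateStates(c(Rn = 4, Rc = 4, P = 5)),
                     times = c(0, 20))
  sB <- integrateFSP(net, enumerateStates(c(Rn = 6, Rc = 6, P = 7)),
                     times = c(0, 20))
  expect_lte(sinkMass(sB)[[2]], sinkMass(sA)[[2]])
  # unreachable tolerance under a state cap raises an informative error
  expect_error(expandUntilTolerance(net, tFinal = 30, eps = 1e-12,
                                    bounds = c(Rn = 1, Rc = 1, P = 1),
                                    growth = 2L, maxStates = 200),
               "cap")
  expect_error(expandUntilTolerance(net, tFinal = 10, eps = 0,
                                    bounds = c(Rn = 2, Rc = 2, P = 2)),
               "eps")
})

test_that("FSP snapshots export one row per retained state", {
  net <- constitutiveModel(smallRates())
  sp <- enumerateStates(c(Rn = 3, Rc = 3, P = 3))
  sol <- integrateFSP(net, sp, times = c(0, 5))
  f <- tempfile(fileext = ".csv")
  exportDistribution(sol, 5, f, dropZero = FALSE)
  df <- utils::read.csv(f)
  expect_identical(nrow(df), nStates(sp))
  expect_equal(sum(df$probability), 1 - sinkMass(sol)[[2]],
               tolerance = 1e-10)
})
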