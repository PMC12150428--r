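makeObs <- function(schedule = NULL, sdval = 1,
                    times = c(10, 60, 110, 130, 160, 200)) {
  net <- constitutiveModel(tableRates())
  traj <- solveODE(net, times = times, schedule = schedule)
  do.call(rbind, lapply(c("Rn", "Rc", "P"), function(s)
    data.frame(time = times, species = s, mean = traj[[s]], sd = sdval)))
}

test_that("the Gaussian log-likelihood has its textbook form", {
  sch <- drugSchedule(120, 0.9)
  obs <- makeObs(sch, sdval = 2)
  # data equal to the model leaves only the normalization constant
  ll <- odeGaussianLoglik(tableRates(), obs, schedule = sch)
  expect_equal(ll, -0.5 * sum(log(2 * pi * obs$sd^2)), tolerance = 1e-8)
  expect_equal(odeGaussianLoglik(tableRates(), obs, schedule = sch,
                                 sumOfSquares = TRUE), 0, tolerance = 1e-8)
  # a single residual of 2 at sd 2 contributes (2)^2/(2*4) = 0.5
  obs2 <- obs; obs2$mean[1] <- obs2$mean[1] + 2
  expect_equal(odeGaussianLoglik(tableRates(), obs2, schedule = sch,
                                 sumOfSquares = TRUE), -0.5,
               tolerance = 1e-8)
  # doubling all sigmas with fixed residuals divides the quadratic by 4
  obs4 <- obs2; obs4$sd <- 4
  expect_equal(odeGaussianLoglik(tableRates(), obs4, schedule = sch,
                                 sumOfSquares = TRUE), -0.5 / 4,
               tolerance = 1e-8)
  # invalid rates propagate as -Inf
  expect_identical(odeGaussianLoglik(c(k_r = -1, tableRates()[-1]), obs),
                   -Inf)
})

test_that("the log-prior is a symmetric normal in log10 space", {
  th <- rep(-1, 5)
  peak <- logPrior(th, location = -1, scale = 2)
  expect_equal(peak, 5 * stats::dnorm(0, 0, 2, log = TRUE))
  # per-parameter peak density is 1/(2 sqrt(2 pi)) at scale 2
  expect_equal(exp(peak / 5), 1 / (2 * sqrt(2 * pi)))
  expect_equal(logPrior(-1 + 0.7, -1, 2), logPrior(-1 - 0.7, -1, 2))
  expect_gt(peak, logPrior(th + 1, -1, 2))
})

test_that("the log-posterior is exactly prior plus likelihood", {
  sch <- drugSchedule(120, 0.9)
  obs <- makeObs(sch)
  th <- log10(tableRates()) + 0.05
  expect_equal(logPosterior(th, obs, schedule = sch),
               logPrior(th) + odeGaussianLoglik(10^th, obs, schedule = sch))
  expect_true(is.finite(logPosterior(log10(tableRates()) - 1, obs,
                                     schedule = sch)))
})

test_that("MLE recovers generating rates from noise-free mean data", {
  sch <- drugSchedule(120, 0.9)
  obs <- makeObs(sch, sdval = 1)
  fit <- maximizeLikelihood(obs, schedule = sch, seed = 1, nStarts = 2)
  truth <- tableRates()
  expect_lt(max(abs(fit$estimate / truth - 1)), 0.01)
  # optimality: no worse than the generating parameters
  expect_gte(fit$logLik + 1e-6,
             odeGaussianLoglik(truth, obs, schedule = sch))
  # restarting from the optimum is a fixed point
  fit2 <- maximizeLikelihood(obs, schedule = sch, start = fit$log10,
                             nStarts = 1, seed = 1)
  expect_lt(max(abs(fit2$log10 - fit$log10)), 1e-3)
})

test_that("Metropolis-Hastings behaves on analytic targets", {
  # constant target: every proposal is accepted
  ch <- metropolisHastings(function(th) 0, c(x = 0), proposalSd = 0.1,
                           nIter = 500, seed = 2, burnIn = 100,
                           adapt = FALSE)
  expect_equal(acceptanceRate(ch), 1)
  # 1D standard normal target: moments recovered
  ch2 <- metropolisHastings(function(th) -0.5 * th^2, c(x = 0),
                            proposalSd = 1.5, nIter = 50000, seed = 3,
                            burnIn = 5000, adapt = FALSE)
  post <- ch2@samples[-(1:5000), 1]
  expect_lt(abs(mean(post)), 0.05)
  expect_lt(abs(stats::var(post) - 1), 0.1)
  # seeded reproducibility
  ch3 <- metropolisHastings(function(th) -0.5 * th^2, c(x = 0),
                            proposalSd = 1.5, nIter = 2000, seed = 7)
  ch4 <- metropolisHastings(function(th) -0.5 * th^2, c(x = 0),
                            proposalSd = 1.5, nIter = 2000, seed = 7)
  expect_identical(ch3@samples, ch4@samples)
})

test_that("chain summaries degenerate correctly and nest by level", {
  sam <- matrix(rep(c(-1, 0.5), each = 300), 300, 2,
                dimnames = list(NULL, c("a", "b")))
  ch <- new("PosteriorChain", samples = sam, logPost = rep(0, 300),
            accepted = 0L, proposalSd = c(0.1, 0.1), burnIn = 100L,
            seed = 1)
  s <- chainSummary(ch)
  expect_equal(s$sd_log10, c(0, 0))
  expect_equal(s$lo95, s$hi95)
  # wider levels contain narrower ones
  set.seed(9)
  sam2 <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  ch2 <- new("PosteriorChain", samples = sam2, logPost = rep(0, 1000),
             accepted = 500L, proposalSd = c(1, 1), burnIn = 0L, seed = 1)
  s2 <- chainSummary(ch2, level = c(0.5, 0.95))
  expect_true(all(s2$lo95 <= s2$lo50 & s2$hi50 <= s2$hi95))
})

test_that("FSP snapshot likelihood is additive and peaks at the truth", {
  p <- smallRates()
  sch <- NULL
  bounds <- c(Rn = 12, Rc = 12, P = 15)
  # a cell observed at time 0 under the delta initial distribution
  zero <- data.frame(time = 0, Rn = 0, Rc = 0, P = 0)
  expect_equal(as.numeric(fspSnapshotLoglik(p, zero, bounds)), 0)
  # independence: two identical cells double the log-likelihood
  one <- data.frame(time = 20, Rn = 3, Rc = 2, P = 1)
  two <- rbind(one, one)
  expect_equal(as.numeric(fspSnapshotLoglik(p, two, bounds)),
               2 * as.numeric(fspSnapshotLoglik(p, one, bounds)),
               tolerance = 1e-10)
  # cells outside the truncation are floored and flagged
  far <- data.frame(time = 20, Rn = 50, Rc = 0, P = 0)
  expect_warning(llFar <- fspSnapshotLoglik(p, far, bounds), "outside")
  expect_identical(attr(llFar, "nFlagged"), 1L)
  # Gibbs inequality: data sampled from the model scores higher at the
  # generating rates than at doubled transcription
  net <- constitutiveModel(p)
  sp <- enumerateStates(bounds)
  sol <- integrateFSP(net, sp, times = c(0, 25))
  set.seed(12)
  draws <- sample.int(nStates(sp), 200, replace = TRUE,
                      prob = pmax(sol@probs[, 2], 0))
  cells <- data.frame(time = 25, Rn = sp@states[draws, 1],
                      Rc = sp@states[draws, 2], P = sp@states[draws, 3])
  pAlt <- p; pAlt["k_r"] <- 2 * pAlt["k_r"]
  expect_gt(as.numeric(fspSnapshotLoglik(p, cells, bounds)),
            as.numeric(fspSnapshotLoglik(pAlt, cells, bounds)))
})

test_that("count summaries produce per-time means and floored SDs", {
  counts <- data.frame(cell = rep(1:3, 2), time = rep(c(5, 10), each = 3),
                       Rn = c(1, 2, 3, 4, 4, 4), Rc = 0:5, P = rep(2, 6))
  obs <- summarizeCounts(counts)
  expect_identical(nrow(obs), 6L)
  expect_equal(obs$mean[obs$time == 5 & obs$species == "Rn"], 2)
  expect_equal(obs$sd[obs$time == 10 & obs$species == "Rn"], 0.5)  # floored
  expect_equal(obs$sd[obs$time == 5 & obs$species == "Rn"], 1)
})
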