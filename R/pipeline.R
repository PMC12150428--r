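#' Default pipeline configuration
#'
#' A single structured configuration drives every stage: model parameters
#' and drug schedule, simulator settings, quantification settings,
#' inference settings, seeds and output directory.
#'
#' @return nested named list with sections \code{model}, \code{drug},
#'   \code{simulator}, \code{quantification}, \code{inference},
#'   \code{seed}, \code{outdir}.
#' @export
defaultPipelineConfig <- function() {
  list(
    model = list(type = "constitutive", k_r = 2, k_t = 0.083, k_p = 0.5,
                 gamma_r = 0.05, gamma_p = 0.25, k_on = 0.2, k_off = 0.2),
    drug = list(t_drug = 120, efficacy = 0.9),
    simulator = list(n_cells = 30,
                     frame_times = c(10, 60, 110, 130, 160, 200),
                     width = 512, height = 512,
                     cytosol_radius = 180, nucleus_radius = 80,
                     psf_sigma = 1.5, amplitude_rna = 150,
                     amplitude_protein = 120,
                     background_outside = 10, background_cytosol = 25,
                     background_nucleus = 35, noise_sd = 4, step_sd = 4),
    quantification = list(smooth_k = 5, dilation_radius = 3,
                          spot_diameter = 5, mass_threshold = 300),
    inference = list(n_iter = 10000, burn_in = 2000, proposal_sd = 0.05,
                     prior_location = -1, prior_scale = 2, n_starts = 3),
    seed = 1,
    outdir = "scxkit_output")
}

validateConfigSection <- function(cfg, section, template) {
  unknown <- setdiff(names(cfg[[section]]), names(template[[section]]))
  if (length(unknown))
    stop("unknown key(s) in config section '", section, "': ",
         paste(unknown, collapse = ", "))
}

#' Read and validate a pipeline configuration file
#'
#' YAML key: value text. Unknown keys are rejected with their section
#' named; missing keys take their defaults; rates must be positive.
#'
#' @param file config path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  template <- defaultPipelineConfig()
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (s in intersect(names(cfg), names(template)))
    if (is.list(template[[s]])) validateConfigSection(cfg, s, template)
  cfg <- utils::modifyList(template, cfg)
  rates <- unlist(cfg$model[c("k_r", "k_t", "k_p", "gamma_r", "gamma_p",
                              "k_on", "k_off")])
  bad <- names(rates)[!is.finite(rates) | rates <= 0]
  if (length(bad))
    stop("invalid rate in config section 'model': ",
         paste(bad, collapse = ", "), " (must be positive)")
  if (cfg$drug$efficacy < 0 || cfg$drug$efficacy > 1)
    stop("invalid value for key 'drug$efficacy': must lie in [0, 1]")
  cfg
}

#' Write a pipeline configuration file (canonical ordering)
#'
#' Emits the configuration in the canonical section/key order of
#' [defaultPipelineConfig()], so that emit(parse(emit(c))) == emit(c).
#'
#' @param cfg configuration list.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writePipelineConfig <- function(cfg, file) {
  template <- defaultPipelineConfig()
  cfg <- utils::modifyList(template, cfg)
  canon <- template
  for (s in names(template)) {
    canon[[s]] <- if (is.list(template[[s]]))
      cfg[[s]][names(template[[s]])] else cfg[[s]]
  }
  yaml::write_yaml(canon, file)
  invisible(file)
}

configSeed <- function(cfg, seed) {
  if (!is.null(seed)) as.integer(seed) else as.integer(cfg$seed)
}

configHash <- function(cfg) {
  # small order-independent content hash embedded in artifacts
  s <- yaml::as.yaml(cfg)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

stageLog <- function(outdir, stage, seed, cfg, t0) {
  line <- sprintf("[%s] stage=%s seed=%d config_hash=%d elapsed=%.1fs",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed,
                  configHash(cfg), as.numeric(proc.time()[3] - t0))
  cat(line, "\n", file = file.path(outdir, "pipeline.log"), append = TRUE)
  message(line)
}

#' Run one pipeline stage
#'
#' Stages: \describe{
#'   \item{simulate-images}{render the synthetic dataset with ground truth
#'     (TIFFs + CSVs).}
#'   \item{quantify}{segment + detect spots on the rendered TIFFs and
#'     write \code{counts.csv} and \code{spots.csv}.}
#'   \item{simulate-model}{solve the ODE and an SSA ensemble for the
#'     configured model; write trajectories.}
#'   \item{fit-mle}{maximum-likelihood fit to \code{counts.csv}.}
#'   \item{fit-mcmc}{Metropolis-Hastings posterior sampling; writes the
#'     chain and its summary.}
#'   \item{report}{collects fit results into a structured text report.}
#' }
#' Every artifact directory gets a \code{pipeline.log} line recording the
#' stage, seed and config hash.
#'
#' @param stage one of the stage names above.
#' @param config configuration list or path to a YAML config.
#' @param seed overrides \code{config$seed} if given.
#' @param outdir overrides \code{config$outdir} if given.
#' @return invisible list of artifact paths; stops with an actionable
#'   error when an upstream artifact is missing.
#' @export
runStage <- function(stage = c("simulate-images", "quantify",
                               "simulate-model", "fit-mle", "fit-mcmc",
                               "report"),
                     config = defaultPipelineConfig(), seed = NULL,
                     outdir = NULL) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else utils::modifyList(defaultPipelineConfig(), config)
  seed <- configSeed(cfg, seed)
  outdir <- if (!is.null(outdir)) outdir else cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t0 <- proc.time()[3]
  sim <- cfg$simulator
  schedule <- if (cfg$drug$efficacy > 0)
    drugSchedule(cfg$drug$t_drug, cfg$drug$efficacy) else NULL
  params <- unlist(cfg$model[c("k_r", "k_t", "k_p", "gamma_r", "gamma_p",
                               "k_on", "k_off")])
  net <- if (identical(cfg$model$type, "two_state")) twoStateModel(params)
         else constitutiveModel(params)

  artifacts <- switch(stage,
    "simulate-images" = {
      ds <- generateDataset(
        config = list(nCells = sim$n_cells, model = cfg$model$type,
                      params = as.list(params),
                      tDrug = cfg$drug$t_drug, efficacy = cfg$drug$efficacy,
                      frameTimes = sim$frame_times, width = sim$width,
                      height = sim$height,
                      cytosolRadius = sim$cytosol_radius,
                      nucleusRadius = sim$nucleus_radius,
                      psfSigma = sim$psf_sigma,
                      amplitudeRna = sim$amplitude_rna,
                      amplitudeProtein = sim$amplitude_protein,
                      backgroundOutside = sim$background_outside,
                      backgroundCytosol = sim$background_cytosol,
                      backgroundNucleus = sim$background_nucleus,
                      noiseSd = sim$noise_sd, stepSd = sim$step_sd),
        seed = seed, outdir = outdir)
      list(tiffs = list.files(outdir, "^cell_.*\\.tif$", full.names = TRUE),
           groundTruth = file.path(outdir, "ground_truth_counts.csv"))
    },
    "quantify" = {
      tiffs <- list.files(outdir, "^cell_.*\\.tif$", full.names = TRUE)
      if (!length(tiffs))
        stop("no cell TIFFs found in '", outdir,
             "'; run stage 'simulate-images' first")
      q <- cfg$quantification
      res <- lapply(seq_along(tiffs), function(i) {
        px <- readImageStack(tiffs[i])
        out <- quantifyStack(px, times = sim$frame_times, k = q$smooth_k,
                             dilationRadius = q$dilation_radius,
                             diameter = q$spot_diameter,
                             massThreshold = q$mass_threshold)
        list(counts = cbind(cell = i, out$counts),
             spots = if (nrow(out$spots))
               cbind(cell = i, out$spots) else NULL)
      })
      counts <- do.call(rbind, lapply(res, `[[`, "counts"))
      spots <- do.call(rbind, Filter(Negate(is.null),
                                     lapply(res, `[[`, "spots")))
      utils::write.csv(counts, file.path(outdir, "counts.csv"),
                       row.names = FALSE, quote = FALSE)
      if (!is.null(spots))
        utils::write.csv(spots, file.path(outdir, "spots.csv"),
                         row.names = FALSE, quote = FALSE)
      list(counts = file.path(outdir, "counts.csv"),
           spots = file.path(outdir, "spots.csv"))
    },
    "simulate-model" = {
      times <- seq(0, max(sim$frame_times), by = 1)
      traj <- solveODE(net, times = times, schedule = schedule)
      exportTrajectory(traj, file.path(outdir, "ode_trajectory.csv"))
      ens <- runEnsemble(net, tMax = max(times), n = 100, baseSeed = seed,
                         schedule = schedule,
                         grid = seq(0, max(times), by = 5))
      exportEnsemble(ens, file.path(outdir, "ssa_ensemble.csv"))
      list(ode = file.path(outdir, "ode_trajectory.csv"),
           ssa = file.path(outdir, "ssa_ensemble.csv"))
    },
    "fit-mle" = {
      cfile <- file.path(outdir, "counts.csv")
      if (!file.exists(cfile))
        stop("missing '", cfile, "'; run stage 'quantify' first")
      counts <- utils::read.csv(cfile)
      obs <- summarizeCounts(counts)
      fit <- maximizeLikelihood(obs, schedule = schedule,
                                nStarts = cfg$inference$n_starts,
                                seed = seed)
      out <- data.frame(parameter = names(fit$estimate),
                        estimate = unname(fit$estimate),
                        log10 = unname(fit$log10))
      utils::write.csv(out, file.path(outdir, "mle.csv"),
                       row.names = FALSE, quote = FALSE)
      list(mle = file.path(outdir, "mle.csv"))
    },
    "fit-mcmc" = {
      cfile <- file.path(outdir, "counts.csv")
      if (!file.exists(cfile))
        stop("missing '", cfile, "'; run stage 'quantify' first")
      counts <- utils::read.csv(cfile)
      obs <- summarizeCounts(counts)
      inf <- cfg$inference
      target <- function(th) logPosterior(th, obs, schedule = schedule,
                                          location = inf$prior_location,
                                          scale = inf$prior_scale)
      chain <- metropolisHastings(target, log10(defaultParameters()),
                                  proposalSd = inf$proposal_sd,
                                  nIter = inf$n_iter, seed = seed,
                                  burnIn = inf$burn_in)
      exportChain(chain, file.path(outdir, "chain.csv"))
      list(chain = file.path(outdir, "chain.csv"),
           summary = file.path(outdir, "chain_summary.csv"))
    },
    "report" = {
      mfile <- file.path(outdir, "mle.csv")
      sfile <- file.path(outdir, "chain_summary.csv")
      if (!file.exists(mfile) && !file.exists(sfile))
        stop("nothing to report; run 'fit-mle' and/or 'fit-mcmc' first")
      lines <- c("scxkit fit report",
                 sprintf("seed: %d", seed),
                 sprintf("config_hash: %d", configHash(cfg)))
      if (file.exists(mfile)) {
        m <- utils::read.csv(mfile)
        lines <- c(lines, "", "maximum likelihood estimates (1/min):",
                   sprintf("  %-8s %.5g", m$parameter, m$estimate))
      }
      if (file.exists(sfile)) {
        s <- utils::read.csv(sfile)
        lines <- c(lines, "", "posterior (mean [95% CI], 1/min):",
                   sprintf("  %-8s %.5g [%.5g, %.5g]", s$parameter,
                           s$mean, s$lo95, s$hi95))
      }
      writeLines(lines, file.path(outdir, "report.txt"))
      list(report = file.path(outdir, "report.txt"))
    })
  stageLog(outdir, stage, seed, cfg, t0)
  invisible(artifacts)
}
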