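#' Construct a synthetic cell geometry
#'
#' Defaults: 512 x 512 px image, concentric circles with cytosol radius
#' 180 px and nucleus radius 80 px.
#'
#' @param width,height image size (px).
#' @param cytosolRadius,nucleusRadius radii (px).
#' @param cytosolCenter,nucleusCenter (row, col) centers (px); default the
#'   image center, concentric.
#' @return a \linkS4class{CellGeometry}.
#' @export
cellGeometry <- function(width = 512, height = 512,
                         cytosolRadius = 180, nucleusRadius = 80,
                         cytosolCenter = c(height / 2, width / 2),
                         nucleusCenter = cytosolCenter) {
  new("CellGeometry", width = as.numeric(width), height = as.numeric(height),
      nucleusCenter = as.numeric(nucleusCenter),
      nucleusRadius = as.numeric(nucleusRadius),
      cytosolCenter = as.numeric(cytosolCenter),
      cytosolRadius = as.numeric(cytosolRadius))
}

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf("CellGeometry %gx%g px; nucleus r=%g at (%g,%g); cytosol r=%g at (%g,%g)\n",
              object@height, object@width, object@nucleusRadius,
              object@nucleusCenter[1], object@nucleusCenter[2],
              object@cytosolRadius, object@cytosolCenter[1],
              object@cytosolCenter[2]))
})

# Reflect a point into the nucleus disk (species Rn).
reflectIntoNucleus <- function(pos, geom) {
  d <- pos - geom@nucleusCenter
  r <- sqrt(sum(d^2))
  R <- geom@nucleusRadius - 1e-6
  if (r > R && r > 0) {
    rNew <- 2 * R - r
    if (rNew < 0) rNew <- stats::runif(1, 0, R)
    pos <- geom@nucleusCenter + d / r * rNew
  }
  pos
}

# Reflect a point into the cytosolic annulus (species Rc, P): inside the
# cytosol circle and outside the nucleus circle.
reflectIntoCytosol <- function(pos, geom) {
  for (it in 1:8) {
    d <- pos - geom@cytosolCenter
    r <- sqrt(sum(d^2))
    Rout <- geom@cytosolRadius - 1e-6
    if (r > Rout && r > 0) {
      pos <- geom@cytosolCenter + d / r * (2 * Rout - r)
    }
    dn <- pos - geom@nucleusCenter
    rn <- sqrt(sum(dn^2))
    Rin <- geom@nucleusRadius + 1e-6
    if (rn < Rin) {
      if (rn == 0) dn <- c(1, 0)
      rn <- max(rn, 1e-9)
      pos <- geom@nucleusCenter + dn / rn * min(2 * Rin - rn,
                                                geom@cytosolRadius - 1)
      next
    }
    d <- pos - geom@cytosolCenter
    if (sqrt(sum(d^2)) <= Rout) break
  }
  pos
}

randomNucleusPoint <- function(geom) {
  r <- geom@nucleusRadius * sqrt(stats::runif(1))
  th <- stats::runif(1, 0, 2 * pi)
  geom@nucleusCenter + r * c(cos(th), sin(th))
}

# Classify each reaction of the network by its effect on (Rn, Rc, P).
classifyReactions <- function(net) {
  sp <- net@species
  get <- function(s) if (s %in% sp) net@stoich[s, ] else rep(0L, ncol(net@stoich))
  dRn <- get("Rn"); dRc <- get("Rc"); dP <- get("P")
  type <- character(ncol(net@stoich))
  type[dRn == 1L & dRc == 0L & dP == 0L] <- "transcription"
  type[dRn == -1L & dRc == 1L] <- "export"
  type[dP == 1L] <- "translation"
  type[dRn == -1L & dRc == 0L & dP == 0L] <- "decayRn"
  type[dRc == -1L & dRn == 0L] <- "decayRc"
  type[dP == -1L] <- "decayP"
  type[type == ""] <- "other"
  type
}

#' Simulate molecules with positions inside a cell
#'
#' Couples an exact SSA realization of the expression network to a spatial
#' layer: transcription births a nuclear mRNA at a uniform random nucleus
#' position; export converts a uniformly chosen nuclear mRNA to a
#' cytosolic one placed just outside the nuclear boundary; translation
#' births a protein near its template cytosolic mRNA; decay removes a
#' uniformly chosen molecule of the species. Between events every live
#' molecule performs a 2D Gaussian random walk (per-axis step SD
#' \code{stepSd} per \code{subStep} minutes) reflected at its compartment
#' boundary: nuclear mRNA stays inside the nucleus, cytosolic mRNA and
#' protein stay in the annulus between nucleus and cytosol.
#'
#' Per-frame species counts equal the SSA state at the frame time exactly,
#' by construction.
#'
#' @param net a \linkS4class{ReactionNetwork} (constitutive or two-state).
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param frameTimes snapshot times (min).
#' @param seed RNG seed (drives both the SSA and the spatial layer).
#' @param geometry a \linkS4class{CellGeometry}.
#' @param stepSd diffusion step SD (px) per \code{subStep} minutes.
#' @param subStep diffusion sub-step length (min).
#' @param translationJitter SD (px) of the displacement between a
#'   cytosolic mRNA and the proteins it templates (newly released proteins
#'   appear in the template's vicinity, not on top of it).
#' @param proteinStepFactor multiplier on \code{stepSd} for protein
#'   molecules, which are much smaller than mRNP particles and diffuse
#'   correspondingly faster.
#' @param x0 initial state; default all zeros (two-state: one inactive
#'   gene).
#' @return list with \code{records} (data.frame: frame, time, id, species,
#'   row, col) and \code{counts} (data.frame: time, Rn, Rc, P).
#' @export
simulateMolecules <- function(net, schedule = NULL, frameTimes, seed,
                              geometry = cellGeometry(), stepSd = 4,
                              subStep = 1, translationJitter = 15,
                              proteinStepFactor = 2.5, x0 = NULL) {
  if (any(frameTimes < 0)) stop("frame times must be nonnegative")
  tMax <- max(frameTimes)
  if (is.null(x0)) {
    x0 <- integer(length(net@species))
    if ("Goff" %in% net@species) x0[match("Goff", net@species)] <- 1L
  }
  trj <- runSSA(net, x0, tMax, seed = seed, schedule = schedule)
  rtype <- classifyReactions(net)
  # reconstruct which reaction fired at each event from the state deltas
  stM <- trj$states
  prev <- rbind(trj$x0, stM[-nrow(stM), , drop = FALSE])
  if (nrow(stM) == 0) prev <- stM

  # molecule registry
  id <- integer(0); species <- character(0)
  row <- numeric(0); col <- numeric(0)
  nextId <- 1L

  randomCytosolPoint <- function() {
    # uniform in the annulus between nucleus and cytosol
    repeat {
      r <- geometry@cytosolRadius * sqrt(stats::runif(1))
      if (r > geometry@nucleusRadius + 1e-6) break
    }
    th <- stats::runif(1, 0, 2 * pi)
    geometry@cytosolCenter + r * c(cos(th), sin(th))
  }

  birth <- function(sp, pos) {
    id <<- c(id, nextId); nextId <<- nextId + 1L
    species <<- c(species, sp)
    row <<- c(row, pos[1]); col <<- c(col, pos[2])
  }
  kill <- function(i) {
    id <<- id[-i]; species <<- species[-i]
    row <<- row[-i]; col <<- col[-i]
  }
  diffuseAll <- function(dt) {
    nmol <- length(id)
    if (nmol == 0 || dt <= 0) return(invisible())
    sd <- stepSd * sqrt(dt / subStep) *
      ifelse(species == "P", proteinStepFactor, 1)
    row <<- row + stats::rnorm(nmol, 0, sd)
    col <<- col + stats::rnorm(nmol, 0, sd)
    for (i in seq_len(nmol)) {
      pos <- c(row[i], col[i])
      pos <- if (species[i] == "Rn") reflectIntoNucleus(pos, geometry)
             else reflectIntoCytosol(pos, geometry)
      row[i] <<- pos[1]; col[i] <<- pos[2]
    }
  }
  applyEvent <- function(e) {
    d <- stM[e, ] - prev[e, ]
    k <- which(colSums(abs(net@stoich - d)) == 0)[1]
    switch(rtype[k],
      transcription = birth("Rn", randomNucleusPoint(geometry)),
      export = {
        cand <- which(species == "Rn")
        i <- cand[sample.int(length(cand), 1)]
        ang <- atan2(col[i] - geometry@nucleusCenter[2],
                     row[i] - geometry@nucleusCenter[1])
        r <- geometry@nucleusRadius + 5
        species[i] <<- "Rc"
        row[i] <<- geometry@nucleusCenter[1] + r * cos(ang)
        col[i] <<- geometry@nucleusCenter[2] + r * sin(ang)
      },
      translation = {
        cand <- which(species == "Rc")
        pos <- if (length(cand)) {
          i <- cand[sample.int(length(cand), 1)]
          reflectIntoCytosol(c(row[i], col[i]) +
                               stats::rnorm(2, 0, translationJitter),
                             geometry)
        } else reflectIntoCytosol(geometry@nucleusCenter +
                                    c(geometry@nucleusRadius + 5, 0),
                                  geometry)
        birth("P", pos)
      },
      decayRn = { cand <- which(species == "Rn")
                  kill(cand[sample.int(length(cand), 1)]) },
      decayRc = { cand <- which(species == "Rc")
                  kill(cand[sample.int(length(cand), 1)]) },
      decayP = { cand <- which(species == "P")
                 kill(cand[sample.int(length(cand), 1)]) },
      other = invisible())
  }

  # place any initial molecules: nuclear mRNA uniformly in the nucleus,
  # cytosolic species uniformly in the annulus
  for (s in c("Rn", "Rc", "P")) {
    n0 <- if (s %in% net@species) x0[match(s, net@species)] else 0L
    for (q in seq_len(n0))
      birth(s, if (s == "Rn") randomNucleusPoint(geometry)
               else randomCytosolPoint())
  }

  checkpoints <- sort(unique(c(seq(0, tMax, by = subStep), frameTimes, tMax)))
  frameTimes <- sort(frameTimes)
  records <- vector("list", length(frameTimes))
  eventPtr <- 1L
  nEvents <- length(trj$times)
  tcur <- 0
  for (cp in checkpoints) {
    while (eventPtr <= nEvents && trj$times[eventPtr] <= cp) {
      applyEvent(eventPtr)
      eventPtr <- eventPtr + 1L
    }
    diffuseAll(cp - tcur)
    tcur <- cp
    fidx <- which(abs(frameTimes - cp) < 1e-9)
    for (f in fidx) {
      records[[f]] <- if (length(id))
        data.frame(frame = f, time = frameTimes[f], id = id,
                   species = species, row = row, col = col)
      else data.frame(frame = integer(0), time = numeric(0),
                      id = integer(0), species = character(0),
                      row = numeric(0), col = numeric(0))
    }
  }
  records <- do.call(rbind, records)
  gridStates <- sampleTrajectory(trj, frameTimes)
  pick <- function(s) if (s %in% colnames(gridStates)) gridStates[, s] else 0L
  counts <- data.frame(time = frameTimes, Rn = pick("Rn"), Rc = pick("Rc"),
                       P = pick("P"))
  list(records = records, counts = counts)
}

regionLabels <- function(geom) {
  H <- geom@height; W <- geom@width
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dn2 <- (rr - geom@nucleusCenter[1])^2 + (cc - geom@nucleusCenter[2])^2
  dc2 <- (rr - geom@cytosolCenter[1])^2 + (cc - geom@cytosolCenter[2])^2
  lab <- matrix(0L, H, W)
  lab[dc2 <= geom@cytosolRadius^2] <- 1L
  lab[dn2 <= geom@nucleusRadius^2] <- 2L
  lab
}

#' Render one two-channel fluorescence frame
#'
#' Background = per-region base level (outside / cytosol / nucleus) plus
#' iid Gaussian pixel noise; each molecule adds an unnormalized 2D
#' Gaussian kernel of width \code{psfSigma} and peak \code{amplitudes}
#' (nuclear and cytosolic mRNA go to the RNA channel, protein to the
#' protein channel); intensities are clipped to the 16-bit range
#' [0, 65535] and rounded. The integrated signal of an isolated spot is
#' amplitude * 2 pi * psfSigma^2.
#'
#' @param records data.frame of molecules (species, row, col) for one
#'   frame.
#' @param geometry a \linkS4class{CellGeometry}.
#' @param psfSigma point-spread Gaussian SD (px).
#' @param amplitudes named peak intensities: \code{c(rna = , protein = )}.
#' @param background named per-region mean levels:
#'   \code{c(outside = , cytosol = , nucleus = )}.
#' @param noiseSd Gaussian pixel-noise SD.
#' @param seed optional RNG seed for the noise field.
#' @return numeric array (2 channels, height, width); channel 1 RNA,
#'   channel 2 protein.
#' @export
renderFrame <- function(records, geometry = cellGeometry(), psfSigma = 1.5,
                        amplitudes = c(rna = 150, protein = 120),
                        background = c(outside = 10, cytosol = 25,
                                       nucleus = 35),
                        noiseSd = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  H <- geometry@height; W <- geometry@width
  lab <- regionLabels(geometry)
  base <- matrix(background[lab + 1L], H, W)
  img <- array(0, dim = c(2, H, W))
  for (ch in 1:2)
    img[ch, , ] <- base + matrix(stats::rnorm(H * W, 0, noiseSd), H, W)

  if (nrow(records)) {
    wr <- ceiling(4 * psfSigma)
    for (i in seq_len(nrow(records))) {
      ch <- if (records$species[i] == "P") 2L else 1L
      amp <- if (ch == 2L) amplitudes[["protein"]] else amplitudes[["rna"]]
      r0 <- max(1, floor(records$row[i] - wr))
      r1 <- min(H, ceiling(records$row[i] + wr))
      c0 <- max(1, floor(records$col[i] - wr))
      c1 <- min(W, ceiling(records$col[i] + wr))
      if (r0 > r1 || c0 > c1) next
      dr <- (r0:r1) - records$row[i]
      dc <- (c0:c1) - records$col[i]
      kern <- amp * exp(-outer(dr^2, dc^2, "+") / (2 * psfSigma^2))
      img[ch, r0:r1, c0:c1] <- img[ch, r0:r1, c0:c1] + kern
    }
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

#' Simulate a full image stack for one cell
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @param frameTimes snapshot times (min).
#' @param seed RNG seed.
#' @param geometry a \linkS4class{CellGeometry}.
#' @param ... rendering options passed to [renderFrame()] (psfSigma,
#'   amplitudes, background, noiseSd) and spatial options passed to
#'   [simulateMolecules()] (stepSd, subStep).
#' @return an \linkS4class{ImageStack}.
#' @export
simulateCellImages <- function(net, schedule = NULL,
                               frameTimes = c(10, 60, 110, 130, 160, 200),
                               seed, geometry = cellGeometry(), ...) {
  dots <- list(...)
  simArgs <- dots[names(dots) %in% c("stepSd", "subStep", "x0",
                                     "translationJitter",
                                     "proteinStepFactor")]
  renArgs <- dots[names(dots) %in% c("psfSigma", "amplitudes", "background",
                                     "noiseSd")]
  sim <- do.call(simulateMolecules,
                 c(list(net = net, schedule = schedule,
                        frameTimes = frameTimes, seed = seed,
                        geometry = geometry), simArgs))
  H <- geometry@height; W <- geometry@width
  px <- array(0, dim = c(length(frameTimes), 2, H, W))
  for (f in seq_along(frameTimes)) {
    rec <- sim$records[sim$records$frame == f, , drop = FALSE]
    px[f, , , ] <- do.call(renderFrame,
                           c(list(records = rec, geometry = geometry,
                                  seed = seed * 1000L + f), renArgs))
  }
  new("ImageStack", pixels = px, times = sort(frameTimes),
      molecules = sim$records, counts = sim$counts, geometry = geometry)
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat("ImageStack:", d[1], "frames x", d[2], "channels x", d[3], "x", d[4],
      "px; times", paste(object@times, collapse = ", "), "min\n")
})

#' Default dataset configuration
#'
#' The study conditions of the synthetic experiment: 30 cells imaged at
#' six snapshot times bracketing the drug application at 120 min, with the
#' baseline rates of [defaultParameters()] and a 90\%-effective export
#' inhibitor.
#'
#' @return named list of settings understood by [generateDataset()].
#' @export
defaultDatasetConfig <- function() {
  list(nCells = 30,
       model = "constitutive",
       params = as.list(defaultParameters()),
       tDrug = 120, efficacy = 0.9,
       frameTimes = c(10, 60, 110, 130, 160, 200),
       width = 512, height = 512,
       cytosolRadius = 180, nucleusRadius = 80,
       psfSigma = 1.5,
       amplitudeRna = 150, amplitudeProtein = 120,
       backgroundOutside = 10, backgroundCytosol = 25, backgroundNucleus = 35,
       noiseSd = 4, stepSd = 4)
}

#' Generate a synthetic imaging dataset with ground truth
#'
#' Simulates \code{nCells} independent cells and renders two-channel
#' snapshots at the configured times. If \code{outdir} is given, writes
#' one channel-interleaved multi-frame 16-bit TIFF per cell
#' (\code{cell_###.tif}; frame order RNA, protein, RNA, protein, ...), a
#' ground-truth counts CSV (\code{ground_truth_counts.csv}: cell, time,
#' Rn, Rc, P) and a per-molecule positions CSV. Identical seeds produce
#' byte-identical TIFFs.
#'
#' @param config settings list; see [defaultDatasetConfig()]. Missing
#'   entries take their defaults.
#' @param seed base RNG seed; cell i uses seed + i.
#' @param outdir optional output directory (created if needed).
#' @return invisible list with \code{stacks} (list of
#'   \linkS4class{ImageStack}) and \code{counts} (ground-truth
#'   data.frame: cell, time, Rn, Rc, P).
#' @export
generateDataset <- function(config = defaultDatasetConfig(), seed,
                            outdir = NULL) {
  cfg <- utils::modifyList(defaultDatasetConfig(), config)
  params <- unlist(cfg$params)
  net <- if (identical(cfg$model, "two_state"))
    twoStateModel(params) else constitutiveModel(params)
  schedule <- if (!is.null(cfg$tDrug) && cfg$efficacy > 0)
    drugSchedule(cfg$tDrug, cfg$efficacy) else NULL
  geom <- cellGeometry(width = cfg$width, height = cfg$height,
                       cytosolRadius = cfg$cytosolRadius,
                       nucleusRadius = cfg$nucleusRadius)
  stacks <- vector("list", cfg$nCells)
  counts <- vector("list", cfg$nCells)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  for (i in seq_len(max(cfg$nCells, 0))) {
    st <- simulateCellImages(net, schedule, cfg$frameTimes,
                             seed = seed + i, geometry = geom,
                             psfSigma = cfg$psfSigma,
                             amplitudes = c(rna = cfg$amplitudeRna,
                                            protein = cfg$amplitudeProtein),
                             background = c(outside = cfg$backgroundOutside,
                                            cytosol = cfg$backgroundCytosol,
                                            nucleus = cfg$backgroundNucleus),
                             noiseSd = cfg$noiseSd, stepSd = cfg$stepSd)
    stacks[[i]] <- st
    counts[[i]] <- cbind(cell = i, st@counts)
    if (!is.null(outdir))
      writeImageStack(st, file.path(outdir, sprintf("cell_%03d.tif", i)))
  }
  counts <- if (cfg$nCells > 0) do.call(rbind, counts)
  else data.frame(cell = integer(0), time = numeric(0), Rn = integer(0),
                  Rc = integer(0), P = integer(0))
  if (!is.null(outdir)) {
    utils::write.csv(counts, file.path(outdir, "ground_truth_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    mol <- do.call(rbind, lapply(seq_along(stacks), function(i)
      if (nrow(stacks[[i]]@molecules))
        cbind(cell = i, stacks[[i]]@molecules)))
    if (!is.null(mol))
      utils::write.csv(mol, file.path(outdir, "ground_truth_molecules.csv"),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(list(stacks = stacks, counts = counts))
}

#' Write an image stack as a channel-interleaved multi-frame 16-bit TIFF
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeImageStack <- function(stack, file) {
  d <- dim(stack@pixels)
  frames <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) for (ch in seq_len(d[2])) {
    frames[[k]] <- stack@pixels[f, ch, , ] / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(frames, file, bits.per.sample = 16L)
  invisible(file)
}

#' Read a channel-interleaved two-channel TIFF stack
#'
#' @param file path to a TIFF written by [writeImageStack()] or any
#'   two-channel interleaved stack.
#' @param times optional frame times to attach.
#' @return numeric array (frame, channel, row, col) on the 16-bit scale.
#' @export
readImageStack <- function(file, times = NULL) {
  frames <- tiff::readTIFF(file, all = TRUE)
  if (length(frames) %% 2 != 0)
    stop("expected an even number of TIFF directories (2 channels per frame)")
  nf <- length(frames) / 2
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  px <- array(0, dim = c(nf, 2, H, W))
  for (f in seq_len(nf)) {
    px[f, 1, , ] <- round(frames[[2 * f - 1]] * 65535)
    px[f, 2, , ] <- round(frames[[2 * f]] * 65535)
  }
  attr(px, "times") <- times
  px
}
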