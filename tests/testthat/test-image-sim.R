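test_that("cell geometry is validated", {
  g <- cellGeometry()
  expect_s4_class(g, "CellGeometry")
  expect_lt(pi * g@nucleusRadius^2, pi * g@cytosolRadius^2)
  expect_error(cellGeometry(nucleusRadius = 200), "inside the cytosol")
  # off-center nucleus that still fits is accepted
  g2 <- cellGeometry(nucleusCenter = c(300, 256))
  expect_s4_class(g2, "CellGeometry")
  expect_error(cellGeometry(cytosolRadius = 300), "inside the image")
})

test_that("molecule records reproduce the SSA counts exactly and stay in their compartments", {
  net <- constitutiveModel(tableRates())
  sch <- drugSchedule(60, 0.9)
  geom <- cellGeometry()
  sim <- simulateMolecules(net, sch, frameTimes = c(20, 50, 90), seed = 21,
                           geometry = geom)
  for (f in 1:3) {
    rec <- sim$records[sim$records$frame == f, ]
    expect_identical(sum(rec$species == "Rn"), as.integer(sim$counts$Rn[f]))
    expect_identical(sum(rec$species == "Rc"), as.integer(sim$counts$Rc[f]))
    expect_identical(sum(rec$species == "P"), as.integer(sim$counts$P[f]))
    dn <- sqrt((rec$row - geom@nucleusCenter[1])^2 +
               (rec$col - geom@nucleusCenter[2])^2)
    dc <- sqrt((rec$row - geom@cytosolCenter[1])^2 +
               (rec$col - geom@cytosolCenter[2])^2)
    expect_true(all(dn[rec$species == "Rn"] <= geom@nucleusRadius + 1e-6))
    expect_true(all(dn[rec$species != "Rn"] >= geom@nucleusRadius - 1e-6))
    expect_true(all(dc[rec$species != "Rn"] <= geom@cytosolRadius + 1e-6))
  }
  # counts match an identically seeded plain SSA run
  trj <- runSSA(net, tMax = 90, seed = 21, schedule = sch)
  idx <- findInterval(c(20, 50, 90), trj$times)
  expect_identical(as.integer(sim$counts$Rn), unname(trj$states[idx, "Rn"]))
})

test_that("with zero diffusion, nuclear mRNA positions persist between frames", {
  net <- constitutiveModel(tableRates())
  sim <- simulateMolecules(net, NULL, frameTimes = c(30, 34), seed = 5,
                           stepSd = 0)
  f1 <- sim$records[sim$records$frame == 1 & sim$records$species == "Rn", ]
  f2 <- sim$records[sim$records$frame == 2 & sim$records$species == "Rn", ]
  shared <- intersect(f1$id, f2$id)
  expect_gt(length(shared), 0)
  expect_equal(f1$row[match(shared, f1$id)], f2$row[match(shared, f2$id)])
  expect_equal(f1$col[match(shared, f1$id)], f2$col[match(shared, f2$id)])
})

test_that("random-walk mean squared displacement grows as 2 k sigma^2", {
  # effectively unconfined: a huge nucleus and many long-lived molecules
  geom <- cellGeometry(width = 5000, height = 5000, cytosolRadius = 2400,
                       nucleusRadius = 2000)
  tiny <- c(k_r = 1e-9, k_t = 1e-9, k_p = 1e-9, gamma_r = 1e-9,
            gamma_p = 1e-9)
  net <- constitutiveModel(tiny)
  k <- 10; sigma <- 2
  sim <- simulateMolecules(net, NULL, frameTimes = c(0, k), seed = 31,
                           geometry = geom, stepSd = sigma, subStep = 1,
                           x0 = c(1000L, 0L, 0L))
  f0 <- sim$records[sim$records$frame == 1, ]
  f1 <- sim$records[sim$records$frame == 2, ]
  m <- match(f0$id, f1$id)
  dr <- f1$row[m] - f0$row; dc <- f1$col[m] - f0$col
  msd <- mean(dr^2 + dc^2)
  expect_equal(msd, 2 * k * sigma^2, tolerance = 0.1)
})

test_that("rendering produces background plus Gaussian spots", {
  geom <- smallGeometry()
  none <- data.frame(frame = integer(0), time = numeric(0), id = integer(0),
                     species = character(0), row = numeric(0),
                     col = numeric(0))
  bg <- c(outside = 10, cytosol = 25, nucleus = 35)
  img <- renderFrame(none, geom, background = bg, noiseSd = 4, seed = 2)
  lab <- scxkit:::regionLabels(geom)
  for (region in 0:2) {
    px <- img[1, , ][lab == region]
    se <- 4 / sqrt(length(px))
    expect_lt(abs(mean(px) - bg[region + 1]), 3 * se + 0.5)  # 0.5: rounding
  }
  # one molecule, zero noise, zero background: Gaussian integral
  one <- data.frame(frame = 1, time = 0, id = 1L, species = "Rn",
                    row = 80.0, col = 77.0)
  img1 <- renderFrame(one, geom, psfSigma = 1.5,
                      amplitudes = c(rna = 150, protein = 120),
                      background = c(outside = 0, cytosol = 0, nucleus = 0),
                      noiseSd = 0)
  pk <- which(img1[1, , ] == max(img1[1, , ]), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - c(80, 77))), 1)
  expect_equal(sum(img1[1, , ]), 150 * 2 * pi * 1.5^2, tolerance = 0.02)
  expect_equal(sum(img1[2, , ]), 0)  # Rn renders in the RNA channel only
  # zero amplitudes leave pure background
  img0 <- renderFrame(one, geom, amplitudes = c(rna = 0, protein = 0),
                      background = bg, noiseSd = 0)
  expect_equal(max(img0[1, , ]), 35)
})

test_that("dataset generation is seed-deterministic and writes ground truth", {
  cfg <- list(nCells = 2, frameTimes = c(10, 30), width = 160, height = 160,
              cytosolRadius = 60, nucleusRadius = 25, tDrug = 20,
              efficacy = 0.9)
  d1 <- tempfile(); d2 <- tempfile()
  generateDataset(cfg, seed = 8, outdir = d1)
  generateDataset(cfg, seed = 8, outdir = d2)
  f1 <- list.files(d1, "\\.tif$", full.names = TRUE)
  f2 <- list.files(d2, "\\.tif$", full.names = TRUE)
  expect_identical(length(f1), 2L)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  gt <- utils::read.csv(file.path(d1, "ground_truth_counts.csv"))
  expect_identical(names(gt), c("cell", "time", "Rn", "Rc", "P"))
  expect_identical(nrow(gt), 4L)
  # different seed changes the data
  generateDataset(cfg, seed = 9, outdir = d2)
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f2))))
  # empty dataset
  d0 <- generateDataset(list(nCells = 0), seed = 1)
  expect_identical(nrow(d0$counts), 0L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the drug depresses cytosolic mRNA in ground-truth counts", {
  net <- constitutiveModel(tableRates())
  sch <- drugSchedule(120, 0.9)
  rcDrug <- rcCtrl <- numeric(30)
  for (i in 1:30) {
    rcDrug[i] <- simulateMolecules(net, sch, frameTimes = 200,
                                   seed = 500 + i)$counts$Rc
    rcCtrl[i] <- simulateMolecules(net, NULL, frameTimes = 200,
                                   seed = 500 + i)$counts$Rc
  }
  # post-drug steady state drops Rc from ~25 to ~5.7
  expect_lt(mean(rcDrug), mean(rcCtrl) - 2 * stats::sd(rcCtrl))
})

test_that("image stacks round-trip through 16-bit TIFF", {
  net <- constitutiveModel(tableRates())
  st <- simulateCellImages(net, NULL, frameTimes = c(10, 20), seed = 3,
                           geometry = smallGeometry())
  f <- tempfile(fileext = ".tif")
  writeImageStack(st, f)
  px <- readImageStack(f)
  expect_identical(dim(px), c(2L, 2L, 160L, 160L))
  expect_lt(max(abs(px - st@pixels)), 0.51)  # 16-bit quantization only
})
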