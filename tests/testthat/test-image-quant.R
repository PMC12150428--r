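test_that("Gaussian smoothing preserves means and reduces variance", {
  const <- matrix(7, 40, 40)
  expect_equal(gaussianSmooth(const, 5), const, tolerance = 1e-12)
  # impulse response is the (unit-sum) kernel itself
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussianSmooth(imp, 5)
  expect_equal(sum(sm), 1, tolerance = 1e-10)
  # the impulse response is the normalized kernel itself (center crop)
  g <- exp(-(-2:2)^2 / 2)  # sigma = k/5 = 1
  kern <- outer(g, g); kern <- kern / sum(kern)
  expect_equal(sm[9:13, 9:13], kern, tolerance = 1e-10,
               ignore_attr = TRUE)
  set.seed(3)
  noise <- matrix(rnorm(4000, 100, 10), 50, 80)
  sm2 <- gaussianSmooth(noise, 5)
  expect_lt(stats::var(as.numeric(sm2)), stats::var(as.numeric(noise)))
  interior <- sm2[10:40, 10:70]
  expect_lt(abs(mean(interior) / mean(noise[10:40, 10:70]) - 1), 1e-3)
  expect_error(gaussianSmooth(noise, 4), "odd")
  expect_error(gaussianSmooth(noise, 17), "between")
})

test_that("threshold binarization assigns the boundary to the foreground", {
  img <- matrix(c(10, 200, 100, 99), 2, 2)
  expect_identical(thresholdBinarize(img, 100),
                   matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_true(all(thresholdBinarize(img, 0) == 1L))
  expect_true(all(thresholdBinarize(img, 201) == 0L))
})

test_that("multi-Otsu matches an exhaustive search oracle", {
  set.seed(4)
  img <- matrix(0, 60, 60)
  img[, 1:20] <- 10; img[, 21:40] <- 100; img[, 41:60] <- 200
  img <- img + rnorm(3600, 0, 1)

  # independent brute-force oracle over all threshold pairs on the same
  # 64-bin histogram
  nb <- 64
  edges <- seq(min(img), max(img), length.out = nb + 1)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  bin <- pmin(pmax(findInterval(img, edges, rightmost.closed = TRUE), 1), nb)
  h <- tabulate(bin, nb) / length(img)
  bcv <- function(cuts) {
    groups <- findInterval(seq_len(nb), cuts + 0.5) + 1
    sum(vapply(split(seq_len(nb), groups), function(ix) {
      w <- sum(h[ix]); if (w == 0) return(0)
      mu <- sum(h[ix] * mids[ix]) / w
      w * mu^2
    }, 0))
  }
  best <- c(0, 0); bestv <- -Inf
  for (a in 1:(nb - 2)) for (b in (a + 1):(nb - 1))
    if (bcv(c(a, b)) > bestv) { bestv <- bcv(c(a, b)); best <- c(a, b) }
  th <- multiOtsu(img, classes = 3, nbins = nb)
  expect_equal(th, edges[best + 1], tolerance = 1e-12)

  # the class map recovers the true regions almost perfectly
  lab <- matrix(findInterval(img, th), 60, 60)
  truth <- matrix(rep(0:2, each = 20), 60, 60, byrow = TRUE)
  expect_gt(mean(lab == truth), 0.999)

  # two classes reduce to classic Otsu (brute force over one threshold)
  best1 <- which.max(vapply(1:(nb - 1), function(a) bcv(a), 0))
  expect_equal(multiOtsu(img, classes = 2, nbins = nb), edges[best1 + 1],
               tolerance = 1e-12)

  # histogram-only: permuting pixels leaves thresholds unchanged
  perm <- matrix(sample(img), 60, 60)
  expect_equal(multiOtsu(perm, classes = 3, nbins = nb), th)
  expect_error(multiOtsu(matrix(5, 4, 4)), "degenerate")
})

test_that("mask dilation with a disk grows monotonically", {
  m <- matrix(0L, 21, 21); m[11, 11] <- 1L
  expect_identical(dilateMask(m, 0), m)
  d2 <- dilateMask(m, 2)
  expect_true(all(d2[m == 1L] == 1L))          # output contains input
  brush <- EBImage::makeBrush(5, shape = "disc")
  expect_identical(sum(d2), as.integer(sum(brush)))  # the disk itself
  expect_identical(d2[9:13, 9:13], matrix(as.integer(brush), 5, 5))
  areas <- vapply(0:4, function(r) sum(dilateMask(m, r)), 0L)
  expect_true(all(diff(areas) > 0))
  expect_error(dilateMask(m, -1), ">= 0")
})

test_that("spot detection finds isolated Gaussians with subpixel accuracy", {
  mkimg <- function(centers, amp = 100, sigma = 1.5, size = 64) {
    img <- matrix(0, size, size)
    for (k in seq_len(nrow(centers))) {
      rr <- outer((1:size - centers[k, 1])^2, (1:size - centers[k, 2])^2,
                  "+")
      img <- img + amp * exp(-rr / (2 * sigma^2))
    }
    img
  }
  one <- mkimg(cbind(30.3, 41.7))
  sp <- detectSpots(one, diameter = 5, massThreshold = 50)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$row - 30.3), 0.5)
  expect_lt(abs(sp$col - 41.7), 0.5)
  two <- mkimg(rbind(c(20, 20), c(20, 40)))
  expect_identical(nrow(detectSpots(two, massThreshold = 50)), 2L)
  # below the mass threshold nothing is reported
  dim_img <- mkimg(cbind(30, 30), amp = 1)
  expect_identical(nrow(detectSpots(dim_img, massThreshold = 50)), 0L)
  # translation equivariance for whole-pixel shifts
  base <- mkimg(cbind(25.2, 33.8))
  shift <- mkimg(cbind(25.2 + 7, 33.8 + 5))
  a <- detectSpots(base, massThreshold = 50)
  b <- detectSpots(shift, massThreshold = 50)
  expect_equal(b$row - a$row, 7, tolerance = 1e-6)
  expect_equal(b$col - a$col, 5, tolerance = 1e-6)
  expect_error(detectSpots(one, diameter = 4), "odd")
})

test_that("spots are assigned to compartments by mask lookup", {
  lab <- matrix(0L, 40, 40)
  lab[, 15:40] <- 1L          # cytosol band (includes the dilated ring)
  lab[15:25, 25:35] <- 2L     # nucleus block
  sp <- data.frame(row = c(20, 5, 20), col = c(30, 5, 16),
                   mass = c(1, 1, 1))
  out <- assignCompartments(sp, lab)
  expect_identical(out$compartment, c("nucleus", "outside", "cytosol"))
})

test_that("segmentation and counting recover a rendered cell", {
  net <- constitutiveModel(tableRates())
  sch <- drugSchedule(120, 0.9)
  st <- simulateCellImages(net, sch, seed = 11)
  q <- quantifyStack(st)
  # nucleus mask against the true nucleus disk
  geom <- st@geometry
  rr <- matrix(seq_len(512), 512, 512); cc <- t(rr)
  trueNuc <- (rr - 256)^2 + (cc - 256)^2 <= 80^2
  nuc <- q$masks$labels == 2L
  iou <- sum(nuc & trueNuc) / sum(nuc | trueNuc)
  expect_gt(iou, 0.9)
  # per-compartment totals across the six frames within 10% for this cell
  for (s in c("Rn", "Rc", "P"))
    expect_lt(abs(sum(q$counts[[s]]) / sum(st@counts[[s]]) - 1), 0.1)
})

test_that("an empty image yields an empty spot table and zero counts", {
  px <- array(0, dim = c(1, 2, 64, 64))
  px[1, 1, , ] <- 10; px[1, 2, , ] <- 10
  sp <- detectSpots(px[1, 1, , ])
  expect_identical(nrow(sp), 0L)
  h <- countHistogram(c(3, 7, 7, 40), bins = 25, range = c(0, 65))
  expect_identical(nrow(h), 25L)
  expect_identical(sum(h$count), 4L)
})
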