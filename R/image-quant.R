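#' Gaussian smoothing with an odd square kernel
#'
#' Convolution with a normalized 2D Gaussian kernel of size k x k
#' (SD = k/5), replicate boundary. A unit-sum kernel preserves the image
#' mean away from the border.
#'
#' @param image numeric matrix.
#' @param k odd kernel size in pixels, 3 to 15.
#' @return smoothed matrix of the same size.
#' @export
gaussianSmooth <- function(image, k = 5) {
  if (k %% 2 == 0) stop("kernel size k must be odd")
  if (k < 3 || k > 15) stop("kernel size k must be between 3 and 15")
  sigma <- k / 5
  half <- (k - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  as.matrix(EBImage::filter2(image, kern, boundary = "replicate"))
}

#' Binarize an image at an intensity threshold
#'
#' Pixels below \code{I_ts} become 0, pixels at or above it become 1
#' (the boundary value is assigned to the foreground).
#'
#' @param image numeric matrix.
#' @param I_ts intensity threshold.
#' @return integer 0/1 matrix.
#' @export
thresholdBinarize <- function(image, I_ts) {
  out <- matrix(0L, nrow(image), ncol(image))
  out[image >= I_ts] <- 1L
  out
}

#' Multi-class Otsu thresholding
#'
#' Finds the \code{classes - 1} intensity thresholds that maximize the
#' between-class variance of the image histogram (exhaustive search over
#' threshold combinations, using cumulative moment tables). With
#' \code{classes = 2} this is classic Otsu thresholding. The result
#' depends only on the intensity histogram, not on pixel positions.
#'
#' @param image numeric matrix.
#' @param classes number of classes (2 or 3).
#' @param nbins number of histogram bins.
#' @return numeric vector of \code{classes - 1} thresholds on the
#'   intensity scale; pixels with value < threshold fall in the lower
#'   class.
#' @export
multiOtsu <- function(image, classes = 3, nbins = 256) {
  rng <- range(image)
  if (diff(rng) == 0)
    stop("degenerate histogram: constant image has no Otsu thresholds")
  if (!classes %in% c(2, 3)) stop("classes must be 2 or 3")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  bin <- pmin(pmax(findInterval(image, edges, rightmost.closed = TRUE), 1L),
              nbins)
  h <- tabulate(bin, nbins) / length(image)
  # cumulative zeroth and first moments
  P <- cumsum(h)
  Mu <- cumsum(h * mids)
  classStat <- function(a, b) {
    # between-class contribution w * mu^2 of bins (a, b]
    w <- P[b] - if (a >= 1) P[a] else 0
    m <- Mu[b] - if (a >= 1) Mu[a] else 0
    ifelse(w > 0, m^2 / w, 0)
  }
  if (classes == 2) {
    t1 <- seq_len(nbins - 1)
    crit <- classStat(0, t1) + vapply(t1, function(a) classStat(a, nbins), 0)
    best <- which.max(crit)
    return(edges[best + 1])
  }
  best <- c(1L, 2L); bestCrit <- -Inf
  for (a in 1:(nbins - 2)) {
    s1 <- classStat(0, a)
    bs <- (a + 1):(nbins - 1)
    crit <- s1 + vapply(bs, function(b) classStat(a, b), 0) +
      vapply(bs, function(b) classStat(b, nbins), 0)
    j <- which.max(crit)
    if (crit[j] > bestCrit) { bestCrit <- crit[j]; best <- c(a, bs[j]) }
  }
  edges[best + 1]
}

#' Dilate a binary mask with a disk structuring element
#'
#' Morphological dilation; the output always contains the input, and the
#' dilated area is nondecreasing in the radius.
#'
#' @param mask 0/1 matrix.
#' @param radius disk radius (px); 0 returns the mask unchanged.
#' @return 0/1 integer matrix.
#' @export
dilateMask <- function(mask, radius) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  out <- EBImage::dilate(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)),
                         brush)
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

#' Segment a cell image into background, cytosol and nucleus
#'
#' Smooths the image (Gaussian kernel \code{k}), applies 3-class Otsu
#' thresholding, takes the largest connected component of the brightest
#' class as the nucleus (the rendered nuclear background is the brightest
#' region; isolated bright specks from spots are reassigned to the
#' cytosol), fills holes, and dilates the cytosol mask by
#' \code{dilationRadius} to ensure complete coverage of the cell edge.
#'
#' @param image numeric matrix (typically the protein channel).
#' @param k smoothing kernel size (odd px).
#' @param dilationRadius cytosol dilation radius (px).
#' @return a list with \code{labels} (0 background / 1 cytosol /
#'   2 nucleus), \code{thresholds} (the two Otsu cuts) and
#'   \code{dilationRadius}.
#' @export
segmentCell <- function(image, k = 5, dilationRadius = 3) {
  sm <- gaussianSmooth(image, k)
  th <- multiOtsu(sm, classes = 3)
  lab <- matrix(0L, nrow(sm), ncol(sm))
  lab[sm >= th[1]] <- 1L
  bright <- sm >= th[2]
  # nucleus = largest connected component of the brightest class
  cc <- EBImage::bwlabel(matrix(as.numeric(bright), nrow(sm), ncol(sm)))
  nuc <- matrix(0L, nrow(sm), ncol(sm))
  if (max(cc) >= 1) {
    sizes <- tabulate(cc[cc > 0])
    biggest <- which.max(sizes)
    nucMask <- cc == biggest
    nucMask <- EBImage::fillHull(matrix(as.numeric(nucMask), nrow(sm),
                                        ncol(sm))) > 0
    nuc[nucMask] <- 1L
  }
  lab[bright & nuc == 0L] <- 1L            # bright specks -> cytosol
  cyto <- dilateMask(matrix(as.integer(lab >= 1L), nrow(sm), ncol(sm)),
                     dilationRadius)
  cyto <- EBImage::fillHull(matrix(as.numeric(cyto), nrow(sm), ncol(sm))) > 0
  out <- matrix(0L, nrow(sm), ncol(sm))
  out[cyto] <- 1L
  out[nuc == 1L] <- 2L
  list(labels = out, thresholds = th, dilationRadius = dilationRadius)
}

dogFilter <- function(image, diameter) {
  s1 <- diameter / 4
  s2 <- diameter
  kSize <- 2 * ceiling(3 * s2) + 1
  half <- (kSize - 1) / 2
  gk <- function(s) {
    g <- exp(-((-half):half)^2 / (2 * s^2))
    k <- outer(g, g); k / sum(k)
  }
  as.matrix(EBImage::filter2(image, gk(s1) - gk(s2), boundary = "replicate"))
}

#' Detect diffraction-limited spots
#'
#' Band-pass (difference of Gaussians at SDs diameter/4 and diameter),
#' local maxima with minimum separation equal to the particle diameter,
#' integrated mass of the (positive part of the) band-passed image over
#' the diameter window, mass thresholding, and subpixel centroid
#' refinement within the window.
#'
#' @param image numeric matrix (one channel, 16-bit scale).
#' @param diameter odd particle size in pixels (>= 3).
#' @param massThreshold minimum integrated band-passed mass for a spot to
#'   be kept. The default is calibrated to the package's rendering
#'   defaults (spot peak >= 120 on a noise SD of 4); lower it for dimmer
#'   spots.
#' @return data.frame (SpotTable) with columns row, col (subpixel) and
#'   mass; zero rows when nothing is detected.
#' @export
detectSpots <- function(image, diameter = 5, massThreshold = 300) {
  if (diameter %% 2 == 0 || diameter < 3)
    stop("diameter must be odd and >= 3")
  dog <- dogFilter(image, diameter)
  dog[dog < 0] <- 0
  # local maxima: pixel equals the running max over a diameter-sized disk
  brush <- EBImage::makeBrush(diameter, shape = "disc")
  mx <- EBImage::dilate(dog, brush)
  isMax <- dog >= mx - 1e-9 & dog > 0
  half <- (diameter - 1) / 2
  H <- nrow(image); W <- ncol(image)
  cand <- which(isMax, arr.ind = TRUE)
  # exclude candidates whose window would leave the image
  keep <- cand[, 1] > half & cand[, 1] <= H - half &
    cand[, 2] > half & cand[, 2] <= W - half
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), mass = numeric(0)))
  rows <- numeric(0); cols <- numeric(0); mass <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; cl <- cand[i, 2]
    win <- dog[(r - half):(r + half), (cl - half):(cl + half)]
    m <- sum(win)
    if (m < massThreshold) next
    dr <- (-half):half
    rows <- c(rows, r + sum(dr * rowSums(win)) / m)
    cols <- c(cols, cl + sum(dr * colSums(win)) / m)
    mass <- c(mass, m)
  }
  if (length(rows) >= 2) {
    # the dilation-based maximum test enforces the minimum separation;
    # this pass only deduplicates plateau ties (equal maxima side by side)
    ord <- order(-mass)
    sel <- logical(length(rows))
    for (i in ord) {
      ok <- TRUE
      for (j in which(sel))
        if ((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2 < 2.25) {
          ok <- FALSE; break
        }
      sel[i] <- ok
    }
    keep <- sort(which(sel))
    rows <- rows[keep]; cols <- cols[keep]; mass <- mass[keep]
  }
  data.frame(row = rows, col = cols, mass = mass)
}

#' Assign detected spots to cellular compartments
#'
#' Labels each spot by the segmentation value at its rounded centroid:
#' nucleus, cytosol or outside. Nucleus takes precedence where the dilated
#' cytosol overlaps it (the nucleus label overwrites cytosol in the label
#' image).
#'
#' @param spots SpotTable from [detectSpots()].
#' @param masks segmentation from [segmentCell()] (or a 0/1/2 label
#'   matrix).
#' @return the SpotTable with an added \code{compartment} column
#'   (\code{"nucleus"}, \code{"cytosol"} or \code{"outside"}).
#' @export
assignCompartments <- function(spots, masks) {
  lab <- if (is.list(masks)) masks$labels else masks
  comp <- character(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    r <- min(max(round(spots$row[i]), 1), nrow(lab))
    cl <- min(max(round(spots$col[i]), 1), ncol(lab))
    comp[i] <- c("outside", "cytosol", "nucleus")[lab[r, cl] + 1L]
  }
  spots$compartment <- comp
  spots
}

#' Quantify one two-channel image stack
#'
#' Full pipeline for one cell: segment on the smoothed protein channel,
#' detect spots per frame and channel, assign compartments, and tabulate
#' counts: RNA-channel spots in the nucleus are nuclear mRNA, RNA-channel
#' spots in the cytosol are cytosolic mRNA, and protein-channel spots in
#' either compartment are protein (a \code{P_cytosol} column reports the
#' cytosol-only convention).
#'
#' @param pixels array (frame, channel, row, col) on the 16-bit scale, as
#'   from [readImageStack()] or an \linkS4class{ImageStack}'s pixels.
#' @param times frame times (min); default frame indices.
#' @param k smoothing kernel for segmentation.
#' @param dilationRadius cytosol dilation (px).
#' @param diameter spot diameter (px).
#' @param massThreshold spot mass threshold; see [detectSpots()].
#' @return list with \code{counts} (data.frame: time, Rn, Rc, P,
#'   P_cytosol), \code{spots} (data.frame with frame, time, channel, row,
#'   col, mass, compartment) and \code{masks} (per-frame list from
#'   [segmentCell()], first frame only unless \code{perFrameMasks}).
#' @param perFrameMasks segment each frame separately (default: segment
#'   the first frame and reuse, as the geometry is fixed).
#' @export
quantifyStack <- function(pixels, times = NULL, k = 5, dilationRadius = 3,
                          diameter = 5, massThreshold = 300,
                          perFrameMasks = FALSE) {
  if (is(pixels, "ImageStack")) {
    if (is.null(times)) times <- pixels@times
    pixels <- pixels@pixels
  }
  d <- dim(pixels)
  if (is.null(times)) times <- seq_len(d[1])
  masks <- segmentCell(pixels[1, 2, , ], k = k,
                       dilationRadius = dilationRadius)
  spots <- list()
  counts <- data.frame(time = times, Rn = 0L, Rc = 0L, P = 0L,
                       P_cytosol = 0L)
  for (f in seq_len(d[1])) {
    if (perFrameMasks && f > 1)
      masks <- segmentCell(pixels[f, 2, , ], k = k,
                           dilationRadius = dilationRadius)
    for (ch in 1:2) {
      sp <- detectSpots(pixels[f, ch, , ], diameter = diameter,
                        massThreshold = massThreshold)
      sp <- assignCompartments(sp, masks)
      if (nrow(sp))
        spots[[length(spots) + 1]] <-
          cbind(frame = f, time = times[f],
                channel = c("rna", "protein")[ch], sp)
      if (ch == 1) {
        counts$Rn[f] <- sum(sp$compartment == "nucleus")
        counts$Rc[f] <- sum(sp$compartment == "cytosol")
      } else {
        counts$P[f] <- sum(sp$compartment %in% c("nucleus", "cytosol"))
        counts$P_cytosol[f] <- sum(sp$compartment == "cytosol")
      }
    }
  }
  spots <- if (length(spots)) do.call(rbind, spots)
  else data.frame(frame = integer(0), time = numeric(0),
                  channel = character(0), row = numeric(0),
                  col = numeric(0), mass = numeric(0),
                  compartment = character(0))
  list(counts = counts, spots = spots, masks = masks)
}

#' Histogram of per-cell counts
#'
#' Default 25 bins over [0, 65].
#'
#' @param counts integer vector of per-cell counts.
#' @param bins number of bins.
#' @param range histogram range.
#' @return data.frame with bin midpoints and cell counts per bin (sums to
#'   the number of cells).
#' @export
countHistogram <- function(counts, bins = 25, range = c(0, 65)) {
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  x <- pmin(pmax(counts, range[1]), range[2])
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
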