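# Synthetic fluorescence images of infected cells and the two
# quantifications applied to them: a bisecting-line intensity profile
# and the bouquet:nucleus DNA-signal ratio.

#' Generate a synthetic DAPI image of an infected cell
#'
#' Draws a rod-shaped (capsule) cell mask with one Gaussian DNA blob
#' at mid-cell, the phage nucleus, and zero or more punctate foci in
#' the flanking cytosol emulating DNA-filled capsid bouquets.
#' Additive Gaussian noise is clipped at zero. Setting
#' \code{bouquetAmplitude = 0} emulates the endonuclease-treated
#' condition in which filled capsids never accumulate. Consumes the
#' current RNG stream.
#'
#' @param cellLength cell length in microns (> 0).
#' @param nucleusAmplitude peak intensity of the nuclear blob.
#' @param bouquetAmplitude peak intensity of each bouquet focus
#'   (0 disables foci).
#' @param noiseSd additive Gaussian noise sd.
#' @param pixelSize microns per pixel (default 0.05).
#' @param cellWidth cell width in microns.
#' @param nFoci bouquet foci per flank.
#' @param nucleusSigma,focusSigma Gaussian widths in microns.
#' @return A [CellImage-class].
#' @examples
#' set.seed(1)
#' img <- genCellImage(4, 1, 0.8, noiseSd = 0.02)
#' bouquetNucleusRatio(img)
#' @export
genCellImage <- function(cellLength = 4, nucleusAmplitude = 1,
                         bouquetAmplitude = 0.8, noiseSd = 0.02,
                         pixelSize = 0.05, cellWidth = 1,
                         nFoci = 2L, nucleusSigma = 0.4,
                         focusSigma = 0.12) {
  .assert(cellLength > 0, "cellLength must be > 0")
  .assert(nucleusAmplitude >= 0 && bouquetAmplitude >= 0,
    "amplitudes must be >= 0")
  .assert(noiseSd >= 0, "noiseSd must be >= 0")

  marginPx <- 4L
  lenPx <- ceiling(cellLength / pixelSize)
  widPx <- ceiling(cellWidth / pixelSize)
  nx <- lenPx + 2L * marginPx
  ny <- widPx + 2L * marginPx
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  radius <- widPx / 2
  halfAxis <- lenPx / 2 - radius  # capsule: cylinder part half-length

  xs <- matrix(rep(seq_len(nx), each = ny), nrow = ny)
  ys <- matrix(rep(seq_len(ny), times = nx), nrow = ny)
  # distance to the axial segment [cx - halfAxis, cx + halfAxis] x {cy}
  dx <- pmax(abs(xs - cx) - halfAxis, 0)
  dy <- ys - cy
  mask <- sqrt(dx^2 + dy^2) <= radius

  sigN <- nucleusSigma / pixelSize
  img <- nucleusAmplitude * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigN^2))

  if (bouquetAmplitude > 0 && nFoci > 0L) {
    sigF <- focusSigma / pixelSize
    # foci live between the nucleus (3 sigma) and the poles; one focus
    # per equal-width bin keeps foci from overlapping each other
    inner <- 3 * sigN
    outer <- max(inner + 1, lenPx / 2 - radius / 2)
    binW <- (outer - inner) / nFoci
    pad <- min(1.5 * sigF, binW / 2.5)
    for (side in c(-1, 1)) {
      offs <- inner + (seq_len(nFoci) - 1L) * binW +
        runif(nFoci, pad, binW - pad)
      # alternate sides of the axis so adjacent foci stay separated
      yoff <- (radius / 4) * rep_len(c(-1, 1), nFoci) +
        runif(nFoci, -radius / 12, radius / 12)
      for (f in seq_len(nFoci)) {
        fx <- cx + side * offs[f]; fy <- cy + yoff[f]
        img <- img + bouquetAmplitude *
          exp(-((xs - fx)^2 + (ys - fy)^2) / (2 * sigF^2))
      }
    }
  }
  if (noiseSd > 0) img <- img + rnorm(length(img), sd = noiseSd)
  img[!mask] <- 0
  img[img < 0] <- 0

  axis <- rbind(c(cx - lenPx / 2 + 1, cy), c(cx + lenPx / 2 - 1, cy))
  cellImage(img, pixelSize = pixelSize, mask = mask, axis = axis)
}

#' Intensity profile along the cell's long axis
#'
#' Samples the image along the long axis at 1-pixel steps with
#' bilinear interpolation, averaging over a band of
#' \code{bandWidth} parallel lines offset perpendicular to the axis
#' (single-pixel lines are noise-dominated; the default band is 3
#' pixels wide). Positions are reported in microns from the first
#' axis endpoint.
#'
#' @param image a [CellImage-class].
#' @param bandWidth odd number of parallel sampling lines (default 3).
#' @return data.frame with strictly increasing \code{position}
#'   (microns) and non-negative \code{intensity}.
#' @examples
#' set.seed(1)
#' pr <- lineProfile(genCellImage(4, 1, 0, noiseSd = 0))
#' pr$position[which.max(pr$intensity)] # ~ mid-cell
#' @export
lineProfile <- function(image, bandWidth = 3L) {
  stopifnot(is(image, "CellImage"))
  .assert(bandWidth >= 1L && bandWidth %% 2L == 1L,
    "bandWidth must be odd and >= 1")
  img <- image@intensity
  d <- dim(img)
  ax <- image@axis
  p1 <- ax[1L, ]; p2 <- ax[2L, ]
  .assert(all(c(p1, p2) >= 1) && p1[1L] <= d[2L] && p2[1L] <= d[2L] &&
    p1[2L] <= d[1L] && p2[2L] <= d[1L], "axis outside image")
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  .assert(len > 0, "axis endpoints coincide")
  u <- v / len                       # unit vector along the axis
  w <- c(-u[2L], u[1L])              # perpendicular unit vector
  steps <- seq(0, len, by = 1)
  offs <- seq_len(bandWidth) - (bandWidth + 1L) / 2

  acc <- numeric(length(steps))
  for (o in offs) {
    px <- p1[1L] + steps * u[1L] + o * w[1L]
    py <- p1[2L] + steps * u[2L] + o * w[2L]
    px <- pmin(pmax(px, 1), d[2L])
    py <- pmin(pmax(py, 1), d[1L])
    # interp2 takes x = columns, y = rows of Z
    acc <- acc + pracma::interp2(x = seq_len(d[2L]), y = seq_len(d[1L]),
      Z = img, xp = px, yp = py, method = "linear")
  }
  data.frame(position = steps * image@pixelSize,
    intensity = acc / bandWidth)
}

#' Bouquet-to-nucleus DNA signal ratio
#'
#' Segments the phage nucleus as the connected supra-Otsu-threshold
#' region containing the brightest mid-cell pixel; the bouquet
#' regions are the cell-mask pixels lying axially between the
#' nucleus boundary and the cell poles. The ratio of mean bouquet to
#' mean nucleus intensity is invariant to rescaling the whole image.
#' For degenerate images in which Otsu segmentation fails (uniform
#' intensity, empty or mask-wide foreground) the fixed-fraction
#' fallback takes the central third of the cell's axial extent as
#' the nucleus; \code{method = "central"} forces that mode.
#'
#' @param image a [CellImage-class].
#' @param method \code{"otsu"} (default, with automatic fallback) or
#'   \code{"central"}.
#' @return list (class \code{"RegionRatio"}) with
#'   \code{bouquetMean}, \code{nucleusMean}, \code{ratio},
#'   \code{method} (the mode actually used), and \code{nucleusFound}.
#'   When no supra-threshold nucleus exists and the image carries no
#'   signal at all, \code{nucleusFound} is \code{FALSE} and the
#'   ratio is \code{NA} (a "no nucleus" result, not an error).
#' @examples
#' set.seed(1)
#' bouquetNucleusRatio(genCellImage(4, 1, 0.8, noiseSd = 0))
#' @export
bouquetNucleusRatio <- function(image, method = c("otsu", "central")) {
  stopifnot(is(image, "CellImage"))
  method <- match.arg(method)
  img <- image@intensity
  mask <- image@mask
  d <- dim(img)
  ax <- image@axis
  u <- (ax[2L, ] - ax[1L, ])
  u <- u / sqrt(sum(u^2))
  xs <- matrix(rep(seq_len(d[2L]), each = d[1L]), nrow = d[1L])
  ys <- matrix(rep(seq_len(d[1L]), times = d[2L]), nrow = d[1L])
  # axial coordinate of every pixel (projection onto the long axis)
  axial <- (xs - ax[1L, 1L]) * u[1L] + (ys - ax[1L, 2L]) * u[2L]

  noNucleus <- function() structure(list(bouquetMean = NA_real_,
    nucleusMean = NA_real_, ratio = NA_real_, method = method,
    nucleusFound = FALSE), class = "RegionRatio")

  nucleus <- NULL
  usedMethod <- method
  if (method == "otsu") {
    mx <- max(img[mask])
    if (mx > 0 && stats::var(img[mask]) > 0) {
      th <- EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
      fg <- img > th & mask
      if (any(fg) && sum(fg) < sum(mask)) {
        labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
        labels <- EBImage::imageData(labels)
        # seed: brightest pixel in the central third of the axial extent
        rng <- range(axial[mask])
        centralThird <- mask & axial >= rng[1L] + diff(rng) / 3 &
          axial <= rng[2L] - diff(rng) / 3
        seedPool <- which(centralThird & fg)
        if (!length(seedPool)) seedPool <- which(fg)
        seed <- seedPool[which.max(img[seedPool])]
        lab <- labels[seed]
        if (lab > 0) nucleus <- labels == lab & mask
      }
    }
    if (is.null(nucleus)) {
      if (max(img[mask]) == 0) return(noNucleus())
      usedMethod <- "central"   # degenerate segmentation: fallback
    }
  } else {
    usedMethod <- "central"
  }
  if (is.null(nucleus)) {
    rng <- range(axial[mask])
    nucleus <- mask & axial >= rng[1L] + diff(rng) / 3 &
      axial <= rng[2L] - diff(rng) / 3
  }
  if (!any(nucleus)) return(noNucleus())

  axRange <- range(axial[nucleus])
  bouquet <- mask & !nucleus & (axial < axRange[1L] | axial > axRange[2L])
  nucleusMean <- mean(img[nucleus])
  bouquetMean <- if (any(bouquet)) mean(img[bouquet]) else 0
  if (nucleusMean <= 0) return(noNucleus())
  structure(list(
    bouquetMean = bouquetMean,
    nucleusMean = nucleusMean,
    ratio = bouquetMean / nucleusMean,
    method = usedMethod,
    nucleusFound = TRUE
  ), class = "RegionRatio")
}

#' @export
print.RegionRatio <- function(x, ...) {
  if (!x$nucleusFound) {
    cat("RegionRatio: no nucleus detected\n")
  } else {
    cat(sprintf(
      "RegionRatio (%s): bouquet %.4g / nucleus %.4g = %.4g\n",
      x$method, x$bouquetMean, x$nucleusMean, x$ratio))
  }
  invisible(x)
}

#' Run a two-cohort bouquet-ratio experiment
#'
#' Generates \code{n} control cells (bouquet foci present) and
#' \code{n} treated cells (no foci; nuclear amplitude doubled,
#' mirroring the roughly two-fold nuclear DNA increase when capsid
#' packaging is blocked), computes the bouquet:nucleus ratio for
#' each, and compares the cohorts with an unpaired t-test.
#'
#' @param n cells per cohort.
#' @param nucleusAmplitude control nuclear amplitude.
#' @param bouquetAmplitude control focus amplitude.
#' @param noiseSd additive noise sd.
#' @param seed RNG seed.
#' @return list with \code{controlRatios}, \code{treatedRatios} and
#'   the [unpairedTTest()] result in \code{test}.
#' @export
bouquetRatioExperiment <- function(n = 50L, nucleusAmplitude = 1,
                                   bouquetAmplitude = 0.8,
                                   noiseSd = 0.02, seed = 1L) {
  withr::with_seed(seed, {
    ctrl <- vapply(seq_len(n), function(i)
      bouquetNucleusRatio(genCellImage(4, nucleusAmplitude,
        bouquetAmplitude, noiseSd))$ratio, numeric(1L))
    trt <- vapply(seq_len(n), function(i)
      bouquetNucleusRatio(genCellImage(4, 2 * nucleusAmplitude, 0,
        noiseSd))$ratio, numeric(1L))
    list(controlRatios = ctrl, treatedRatios = trt,
      test = unpairedTTest(ctrl, trt))
  })
}
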