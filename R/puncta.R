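#' Mask sub-threshold pixels
#'
#' Marks pixels below \code{floor} as ignored (NA), mirroring 32-bit
#' NaN-masking of basal background: downstream means, sums and areas exclude
#' ignored pixels, and an all-ignored ROI reports a missing value rather
#' than zero.
#'
#' @param image numeric matrix
#' @param floor intensity floor (>= 0); pixels strictly below it are ignored
#' @return matrix with ignored pixels set to NA
#' @export
maskSubthreshold <- function(image, floor) {
  stopifnot(floor >= 0)
  image[image < floor] <- NA_real_
  image
}

#' Detect dsDNA puncta as local maxima in cytosolic ROIs
#'
#' Finds local maxima above \code{peakMin} in a Chebyshev window of
#' half-width \code{minSeparationPx} (so accepted peaks are at least that far
#' apart; plateau ties go to the first pixel in row/column order), keeps
#' those falling inside a cytosolic ROI, and integrates each punctum over a
#' fixed square patch of half-width \code{patchR} pixels (NA pixels are
#' excluded from the patch sum). The fixed patch keeps the quantal intensity
#' distribution unit-additive.
#'
#' In crowded fields the overlapping tails of neighbouring puncta raise a
#' local pedestal under every patch; with \code{localBgRing > 0} the median
#' of the square ring just outside the patch is subtracted from each patch
#' pixel (ring-median local background, the usual spot-quantification
#' correction), which removes that pedestal while leaving the quantal
#' structure of the intensities intact.
#'
#' @param image numeric matrix, background-subtracted puncta channel
#' @param cytosol integer cytosolic label matrix (a \code{CellROIMap}
#'   cytosol slot, or any label matrix)
#' @param peakMin minimum peak height (a.u., > 0)
#' @param minSeparationPx minimum peak separation, pixels
#' Maxima are located on a lightly Gaussian-smoothed copy of the image
#' (\code{smoothSigma} pixels; 0 disables smoothing), the standard guard
#' against single-pixel noise maxima; intensities are always integrated on
#' the unsmoothed image. \code{peakMin} therefore applies to the smoothed
#' peak height.
#'
#' @param patchR integration patch half-width, pixels
#' @param localBgRing width of the local-background ring outside the patch,
#'   pixels (0 disables the correction)
#' @param smoothSigma Gaussian smoothing sigma for peak finding, pixels
#' @return data.frame per punctum: x, y (0-based px), peak (smoothed
#'   height), integrated intensity, localBg, cell (owning label id, 0
#'   outside all ROIs). The patch radius is recorded in attribute "patchR".
#' @export
detectPuncta <- function(image, cytosol, peakMin, minSeparationPx = 2,
                         patchR = 2, localBgRing = 2, smoothSigma = 1) {
  stopifnot(is.matrix(image), peakMin > 0, minSeparationPx >= 1, patchR >= 0)
  det <- if (smoothSigma > 0) {
    sm <- image
    sm[is.na(sm)] <- 0
    sm <- EBImage::gblur(sm, sigma = smoothSigma)
    sm[is.na(image)] <- NA_real_
    sm
  } else image
  pk <- .localMaxima(det, as.integer(minSeparationPx), peakMin)
  if (nrow(pk) > 0) {
    lab <- cytosol[cbind(pk$y + 1L, pk$x + 1L)]
    keep <- lab > 0
    pk <- pk[keep, , drop = FALSE]
    lab <- lab[keep]
    pat <- .patchIntegrate(image, pk$x, pk$y, as.integer(patchR),
                           as.integer(localBgRing))
    out <- data.frame(x = pk$x, y = pk$y, peak = pk$peak,
                      intensity = pat$intensity, localBg = pat$localBg,
                      cell = as.integer(lab))
  } else {
    out <- data.frame(x = integer(0), y = integer(0), peak = numeric(0),
                      intensity = numeric(0), localBg = numeric(0),
                      cell = integer(0))
  }
  attr(out, "patchR") <- patchR
  out
}

#' Summed punctum intensity per cell
#'
#' One row per cell id present in \code{cellIds}; cells without puncta get a
#' sum of zero. The grand total equals the sum of all assigned punctum
#' intensities exactly.
#'
#' @param puncta data.frame from \code{\link{detectPuncta}} (columns cell,
#'   intensity); rows with cell id 0 (outside all ROIs) are dropped
#' @param cellIds cell ids to report; defaults to the ids present in
#'   \code{puncta}
#' @return data.frame (cell, punctaSum, nPuncta)
#' @export
sumPunctaPerCell <- function(puncta, cellIds = NULL) {
  p <- puncta[puncta$cell > 0, , drop = FALSE]
  if (is.null(cellIds)) cellIds <- sort(unique(p$cell))
  sums <- rep(0, length(cellIds))
  cnts <- rep(0L, length(cellIds))
  if (nrow(p) > 0) {
    agg <- tapply(p$intensity, p$cell, sum)
    cnt <- tapply(p$intensity, p$cell, length)
    m <- match(as.integer(names(agg)), cellIds)
    ok <- !is.na(m)
    sums[m[ok]] <- as.numeric(agg)[ok]
    cnts[m[ok]] <- as.integer(cnt)[ok]
  }
  data.frame(cell = cellIds, punctaSum = sums, nPuncta = cnts)
}

#' Thresholded area per ROI
#'
#' Area of supra-floor pixels per labelled ROI, in square micrometres; the
#' per-cell "mitochondrial mass" proxy when applied to a mitochondrial dye
#' channel with cytosolic ROIs.
#'
#' @param image numeric matrix
#' @param label integer label matrix
#' @param floor intensity floor (>= 0); pixels strictly above it count
#' @param pixelSizeUm micrometres per pixel
#' @return data.frame (cell, areaUm2)
#' @export
thresholdedAreaPerCell <- function(image, label, floor, pixelSizeUm = 1.24) {
  stopifnot(floor >= 0)
  n <- max(label)
  ids <- seq_len(n)
  hi <- !is.na(image) & image > floor & label > 0
  cnt <- tabulate(label[hi], n)
  data.frame(cell = ids, areaUm2 = cnt * pixelSizeUm^2)
}
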