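#' Rolling background subtraction
#'
#' Removes slowly varying background by grayscale morphological opening with
#' a disc structuring element (the rolling-ball estimate of the background)
#' and subtracting it. Because the opening never exceeds the image, the
#' result is non-negative without clipping. The default radius follows the
#' convention of 1.5 times the largest expected nuclear diameter (~50 um for
#' A7r5 cells), i.e. 75 um.
#'
#' The background is estimated on a presmoothed copy of the image (Gaussian,
#' \code{presmoothSigma} px): a min-filter ridden directly over pixel noise
#' sits on the noise's lower envelope and would leave a positive pedestal
#' after subtraction, whereas the opening of the smoothed image tracks the
#' true background level. The estimate is capped at the image so the result
#' stays non-negative. For radii above \code{shrinkAbovePx} pixels the
#' opening runs on a block-minimum shrunken copy (then enlarged
#' bilinearly) - the usual large-radius rolling-ball acceleration; smaller
#' radii use the exact opening.
#'
#' @param image numeric matrix (a.u.)
#' @param radiusUm rolling radius in micrometres (> 0)
#' @param pixelSizeUm micrometres per pixel
#' @param presmoothSigma Gaussian sigma (px) for the background estimate;
#'   0 uses the raw image
#' @param shrinkAbovePx radius (px) above which the shrink acceleration is
#'   used
#' @return background-subtracted matrix, same dimensions
#' @export
subtractBackground <- function(image, radiusUm = 75, pixelSizeUm = 1.24,
                               presmoothSigma = 2, shrinkAbovePx = 100) {
  stopifnot(is.matrix(image), radiusUm > 0, pixelSizeUm > 0)
  rPx <- radiusUm / pixelSizeUm
  if (rPx < 2)
    stop("rolling radius of ", signif(rPx, 3), " px is degenerate (< 2 px)")
  m <- min(image); M <- max(image)
  if (M <= m) return(image - image)
  est <- if (presmoothSigma > 0) EBImage::gblur(image, presmoothSigma)
         else image
  openDisc <- function(img, r) {
    size <- 2L * as.integer(floor(r)) + 1L
    brush <- EBImage::makeBrush(size, shape = "disc")
    # opening commutes with affine rescaling; map into [0, 1] first because
    # EBImage grayscale morphology assumes normalized intensities
    EBImage::opening((img - m) / (M - m), brush) * (M - m) + m
  }
  if (rPx <= shrinkAbovePx) {
    bg <- openDisc(est, rPx)
  } else {
    s <- as.integer(ceiling(rPx / 50))
    nr <- nrow(image); nc <- ncol(image)
    nrs <- ceiling(nr / s); ncs <- ceiling(nc / s)
    pad <- matrix(Inf, nrs * s, ncs * s)
    pad[seq_len(nr), seq_len(nc)] <- est
    small <- matrix(Inf, nrs, ncs)
    for (dy in seq_len(s)) for (dx in seq_len(s))
      small <- pmin(small, pad[seq(dy, by = s, length.out = nrs),
                               seq(dx, by = s, length.out = ncs)])
    bgSmall <- openDisc(small, rPx / s)
    bg <- EBImage::resize(bgSmall, w = nrs * s, h = ncs * s)[seq_len(nr),
                                                            seq_len(nc)]
  }
  bg <- pmin(bg, image)
  image - bg
}

#' Suggest a nuclear threshold (Otsu)
#'
#' Convenience helper: Otsu's threshold on the image histogram, as a starting
#' point for the single-intensity threshold applied to a staining batch. It
#' is only a suggestion and is never applied implicitly; segmentation always
#' takes an explicit threshold.
#'
#' @param image numeric matrix (a.u.)
#' @return suggested threshold (a.u.)
#' @export
suggestThreshold <- function(image) {
  rng <- range(image, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  scaled <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + th * diff(rng)
}

#' Threshold-based nuclear segmentation
#'
#' Labels 8-connected components above a single intensity threshold and
#' filters them by area. Labels are renumbered to consecutive positive
#' integers in raster order. An empty result is allowed (with a warning).
#'
#' @param image numeric matrix, typically background-subtracted nuclear stain
#' @param threshold intensity threshold (a.u., > 0); pixels strictly above it
#'   are foreground
#' @param minAreaUm2,maxAreaUm2 component area filter in square micrometres
#' @param pixelSizeUm micrometres per pixel
#' @return integer label matrix with attributes \code{pixelSize} and
#'   \code{provenance} (threshold, area filter, connectivity)
#' @export
thresholdNuclei <- function(image, threshold, minAreaUm2 = 30,
                            maxAreaUm2 = Inf, pixelSizeUm = 1.24) {
  stopifnot(is.matrix(image), threshold > 0)
  lab <- .label8(image > threshold)
  if (max(lab) > 0) {
    areas <- tabulate(lab) * pixelSizeUm^2
    keep <- which(areas >= minAreaUm2 & areas <= maxAreaUm2)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  if (max(lab) == 0) warning("no nuclei passed the threshold and area filter")
  attr(lab, "pixelSize") <- pixelSizeUm
  attr(lab, "provenance") <- list(threshold = threshold,
                                  minAreaUm2 = minAreaUm2,
                                  maxAreaUm2 = maxAreaUm2,
                                  connectivity = 8L)
  lab
}

#' Voronoi expansion of nuclear ROIs into cell and cytosolic territories
#'
#' Every pixel is assigned to the nucleus whose mask it is nearest to
#' (Euclidean distance to the nuclear mask, not the centroid), provided that
#' distance does not exceed the expansion cap - i.e. cell territories extend
#' to the lesser of \code{maxExpansionUm} or the equidistant (Voronoi)
#' borders between nuclear edges. Distance ties go to the lower label id.
#' The cytosolic map additionally excludes pixels within \code{dilationPx}
#' of any nuclear mask, reproducing the convention of dilating nuclear ROIs
#' by 4 pixels before measuring cytosolic signal.
#'
#' The cap is applied as \code{floor(maxExpansionUm / pixelSizeUm)} pixels,
#' so a lone nucleus grows to its mask dilated by a disc of that radius
#' (107 px for the default 133 um at 1.24 um/px).
#'
#' @param nuclei integer nuclear label matrix (e.g. from
#'   \code{\link{thresholdNuclei}})
#' @param dilationPx nuclear dilation excluded from the cytosol, pixels
#' @param maxExpansionUm expansion cap, micrometres
#' @param pixelSizeUm micrometres per pixel (defaults to the matrix
#'   attribute when present)
#' @return a \code{\linkS4class{CellROIMap}}
#' @export
voronoiCellRois <- function(nuclei, dilationPx = 4, maxExpansionUm = 133,
                            pixelSizeUm = attr(nuclei, "pixelSize")) {
  if (is.null(pixelSizeUm)) pixelSizeUm <- 1.24
  if (max(nuclei) < 1) stop("at least one nucleus is required")
  capPx <- floor(maxExpansionUm / pixelSizeUm)
  va <- .voronoiAssign(matrix(as.integer(nuclei), nrow(nuclei)), capPx)
  cells <- va$label
  cyto <- cells
  cyto[va$dist <= dilationPx] <- 0L
  new("CellROIMap", nuclei = matrix(as.integer(nuclei), nrow(nuclei)),
      cells = cells, cytosol = cyto, dist = va$dist,
      pixelSize = pixelSizeUm, dilationPx = dilationPx,
      maxExpansionUm = maxExpansionUm,
      provenance = c(as.list(attr(nuclei, "provenance")),
                     list(capPx = capPx)))
}

#' Summary table of labelled ROIs
#'
#' @param label integer label matrix
#' @param pixelSizeUm micrometres per pixel
#' @return data.frame (id, x, y centroid in 0-based px, areaPx, areaUm2)
#' @export
roiTable <- function(label, pixelSizeUm = attr(label, "pixelSize")) {
  if (is.null(pixelSizeUm)) pixelSizeUm <- 1.24
  n <- max(label)
  if (n == 0)
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      areaPx = integer(0), areaUm2 = numeric(0)))
  idx <- which(label > 0)
  l <- label[idx]
  ys <- (idx - 1) %% nrow(label)
  xs <- (idx - 1) %/% nrow(label)
  areaPx <- tabulate(l, n)
  data.frame(id = seq_len(n),
             x = as.numeric(tapply(xs, l, mean)),
             y = as.numeric(tapply(ys, l, mean)),
             areaPx = areaPx,
             areaUm2 = areaPx * pixelSizeUm^2)
}
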