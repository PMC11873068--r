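#' FieldImage: one multi-channel field of view
#'
#' Container for one field of view: named channel rasters (matrices indexed
#' \code{[row, col] = [y + 1, x + 1]}, arbitrary units), the pixel size in
#' micrometres per pixel, the nominal camera bit depth, and, for synthetic
#' fields, the generator ground truth (see \code{\link{makeField}}).
#'
#' @slot channels named list of numeric matrices, all with identical dimensions
#' @slot pixelSize micrometres per pixel
#' @slot bitDepth nominal bit depth of the source camera (16 by default)
#' @slot truth list with elements \code{cells} and \code{puncta}
#'   (data frames) for synthetic fields, otherwise empty
#' @slot metadata free-form list (plate, well, fov, condition, media, ...)
#' @exportClass FieldImage
setClass("FieldImage",
  representation(channels = "list", pixelSize = "numeric",
                 bitDepth = "numeric", truth = "list", metadata = "list"),
  prototype(channels = list(), pixelSize = 1.24, bitDepth = 16,
            truth = list(), metadata = list()))

setValidity("FieldImage", function(object) {
  ch <- object@channels
  if (length(ch)) {
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
      return("channels must be a named list")
    if (!all(vapply(ch, is.matrix, logical(1))))
      return("each channel must be a matrix")
    d <- vapply(ch, dim, integer(2))
    if (any(d != d[, 1])) return("all channels must share dimensions")
  }
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' CellROIMap: nuclear, cell and cytosolic label maps
#'
#' The three label rasters produced by \code{\link{voronoiCellRois}}: the
#' nuclear label map, the capped Voronoi cell territories (same label ids),
#' and the cytosolic map (cell territory minus the dilated nucleus). The
#' distance raster holds, for every assigned pixel, the Euclidean distance in
#' pixels to its owning nuclear mask.
#'
#' @slot nuclei,cells,cytosol integer label matrices (0 = background)
#' @slot dist numeric matrix of distances to the owning nuclear mask (px)
#' @slot pixelSize micrometres per pixel
#' @slot dilationPx nuclear dilation excluded from the cytosol, in pixels
#' @slot maxExpansionUm expansion cap in micrometres
#' @slot provenance list (threshold, background radius, connectivity, ...)
#' @exportClass CellROIMap
setClass("CellROIMap",
  representation(nuclei = "matrix", cells = "matrix", cytosol = "matrix",
                 dist = "matrix", pixelSize = "numeric", dilationPx = "numeric",
                 maxExpansionUm = "numeric", provenance = "list"))

setValidity("CellROIMap", function(object) {
  if (!identical(dim(object@nuclei), dim(object@cells)) ||
      !identical(dim(object@nuclei), dim(object@cytosol)))
    return("label maps must share dimensions")
  if (any(object@cytosol > 0 & object@nuclei > 0))
    return("cytosolic and nuclear ROIs must be disjoint")
  TRUE
})

#' QuantalFit: quantal nucleoid intensity estimate
#'
#' Result of \code{\link{fitQuantalMixture}}: the quantal (single mtDNA copy)
#' integrated punctum intensity \code{q}, mixture weights over copy numbers
#' \code{1..K}, the unit noise scale sigma (component k has sd sigma*sqrt(k)),
#' and fit diagnostics. \code{valid} is FALSE when the fit did not converge or
#' the single-copy component is not the most abundant one.
#'
#' @slot q quantal intensity (a.u.)
#' @slot weights numeric vector of component weights (sum 1)
#' @slot sigma unit noise sd (a.u.)
#' @slot gof weighted residual norm on the fitted histogram
#' @slot nPuncta number of puncta used
#' @slot method "wls" (histogram least squares) or "em"
#' @slot valid logical
#' @exportClass QuantalFit
setClass("QuantalFit",
  representation(q = "numeric", weights = "numeric", sigma = "numeric",
                 gof = "numeric", nPuncta = "numeric", method = "character",
                 valid = "logical"))

setValidity("QuantalFit", function(object) {
  if (length(object@q) != 1 || object@q <= 0) return("q must be positive")
  if (any(object@weights < -1e-9)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  TRUE
})

#' GfpMixtureFit: triple-Gaussian transfection gate
#'
#' Three-component Gaussian mixture fit of nuclear GFP intensities with the
#' transfection threshold mu1 + 3*sigma1 (mean plus three standard deviations
#' of the lowest, background component) and the fraction of cells above it.
#'
#' @slot mu,sigma,weight numeric length-3 vectors sorted by mu
#' @slot threshold mu1 + 3*sigma1
#' @slot fractionAbove fraction of the fitted sample above the threshold
#' @slot logLik fit log-likelihood
#' @slot valid logical (FALSE for degenerate fits)
#' @exportClass GfpMixtureFit
setClass("GfpMixtureFit",
  representation(mu = "numeric", sigma = "numeric", weight = "numeric",
                 threshold = "numeric", fractionAbove = "numeric",
                 logLik = "numeric", valid = "logical"))

setValidity("GfpMixtureFit", function(object) {
  if (length(object@mu) != 3) return("three components required")
  if (is.unsorted(object@mu)) return("components must be sorted by mean")
  if (abs(sum(object@weight) - 1) > 1e-6) return("weights must sum to 1")
  TRUE
})

#' PloidyGateSet: 2-D gates on (integrated stain intensity, nuclear area)
#'
#' Axis-aligned boxes classifying nuclei into ploidy classes 2, 2S, 4, 4S and
#' 8 (diploid G0/G1, diploid S-phase, tetraploid/diploid G2-M, tetraploid
#' S-phase, octoploid/tetraploid G2-M); anything outside every box is
#' "ungated". Intensity intervals are half-open [lo, hi) so gates are
#' pairwise disjoint by construction.
#'
#' @slot gates data.frame with columns class, intMin, intMax, areaMin, areaMax
#' @slot g1Mode modal integrated intensity of the diploid G0/G1 peak (a.u.)
#' @exportClass PloidyGateSet
setClass("PloidyGateSet",
  representation(gates = "data.frame", g1Mode = "numeric"))

setValidity("PloidyGateSet", function(object) {
  need <- c("class", "intMin", "intMax", "areaMin", "areaMax")
  if (!all(need %in% names(object@gates))) return("missing gate columns")
  g <- object@gates[order(object@gates$intMin), ]
  if (nrow(g) > 1 && any(g$intMax[-nrow(g)] > g$intMin[-1] + 1e-9))
    return("intensity gates must not overlap")
  TRUE
})

#' ConcentrationEstimate: Poisson-corrected ddPCR quantification
#'
#' Mean copies per droplet for the mitochondrial (ND1) and nuclear reference
#' (ACTB) targets, the resulting mtDNA copies per cell, and binomial
#' confidence bounds propagated from the negative-droplet fractions.
#'
#' @slot lambdaNd1,lambdaActb mean copies per droplet
#' @slot nDroplets droplets used
#' @slot lociPerCell nuclear reference loci per cell
#' @slot copiesPerCell mtDNA copies per cell
#' @slot ci numeric matrix (2 rows lo/hi, columns nd1/actb/copiesPerCell)
#' @slot saturated logical per target (no negative droplets: lower bound only)
#' @exportClass ConcentrationEstimate
setClass("ConcentrationEstimate",
  representation(lambdaNd1 = "numeric", lambdaActb = "numeric",
                 nDroplets = "numeric", lociPerCell = "numeric",
                 copiesPerCell = "numeric", ci = "matrix",
                 saturated = "logical"))

#' GrowthFit: exponential growth-model fit
#'
#' Least-squares fit of \code{count = c + a * exp(k * t)} (offset model) or
#' \code{count = a * exp(k * t)} (pure model) with the doubling time
#' \code{ln(2)/k}. The doubling time is \code{NA} when \code{k <= 0}.
#'
#' @slot a amplitude (cells)
#' @slot k rate constant (1/h)
#' @slot c additive offset (cells; 0 for the pure model)
#' @slot doublingTime ln(2)/k in hours, NA if k <= 0
#' @slot model "offset_exponential" or "pure_exponential"
#' @slot residualNorm residual sum of squares
#' @slot r2 coefficient of determination
#' @slot converged logical
#' @slot window fitted time range (h)
#' @exportClass GrowthFit
setClass("GrowthFit",
  representation(a = "numeric", k = "numeric", c = "numeric",
                 doublingTime = "numeric", model = "character",
                 residualNorm = "numeric", r2 = "numeric",
                 converged = "logical", window = "numeric"))

## ---- accessors ----

#' @describeIn FieldImage-class channel names
#' @param x,object a \code{FieldImage}
#' @export
setMethod("names", "FieldImage", function(x) names(x@channels))

#' Extract a channel raster from a FieldImage
#' @param x a \code{FieldImage}
#' @param name channel name
#' @export
setMethod("$", "FieldImage", function(x, name) x@channels[[name]])

#' Pixel size accessor
#' @param object a \code{FieldImage} or \code{CellROIMap}
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
setMethod("pixelSize", "FieldImage", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "CellROIMap", function(object) object@pixelSize)

#' Generator ground truth of a synthetic field
#' @param object a \code{FieldImage}
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname groundTruth
setMethod("groundTruth", "FieldImage", function(object) object@truth)

#' Quantal unit intensity accessor
#' @param object a \code{QuantalFit}
#' @export
setGeneric("quantalIntensity", function(object) standardGeneric("quantalIntensity"))

#' @rdname quantalIntensity
setMethod("quantalIntensity", "QuantalFit", function(object) object@q)

#' Doubling time accessor
#' @param object a \code{GrowthFit}
#' @export
setGeneric("doublingTimeOf", function(object) standardGeneric("doublingTimeOf"))

#' @rdname doublingTimeOf
setMethod("doublingTimeOf", "GrowthFit", function(object) object@doublingTime)

#' Copies per cell accessor
#' @param object a \code{ConcentrationEstimate}
#' @export
setGeneric("copiesPerCellOf", function(object) standardGeneric("copiesPerCellOf"))

#' @rdname copiesPerCellOf
setMethod("copiesPerCellOf", "ConcentrationEstimate",
          function(object) object@copiesPerCell)

## ---- show methods ----

setMethod("show", "FieldImage", function(object) {
  d <- if (length(object@channels)) dim(object@channels[[1]]) else c(0L, 0L)
  cat("FieldImage ", d[2], "x", d[1], " px (", object@pixelSize, " um/px), ",
      length(object@channels), " channel(s): ",
      paste(names(object@channels), collapse = ", "), "\n", sep = "")
  if (length(object@truth))
    cat("  synthetic; ground truth: ", nrow(object@truth$cells), " cells, ",
        if (!is.null(object@truth$puncta)) nrow(object@truth$puncta) else 0,
        " puncta\n", sep = "")
})

setMethod("show", "CellROIMap", function(object) {
  n <- max(object@nuclei)
  cat("CellROIMap with", n, "cells; dilation", object@dilationPx,
      "px; expansion cap", object@maxExpansionUm, "um\n")
})

setMethod("show", "QuantalFit", function(object) {
  cat("QuantalFit (", object@method, "): q = ", signif(object@q, 5),
      " a.u., sigma = ", signif(object@sigma, 4),
      ", n = ", object@nPuncta,
      if (!object@valid) " [INVALID]" else "", "\n", sep = "")
  cat("  weights:", paste(signif(object@weights, 3), collapse = " "), "\n")
})

setMethod("show", "GfpMixtureFit", function(object) {
  cat("GfpMixtureFit: mu = (", paste(signif(object@mu, 4), collapse = ", "),
      "), threshold mu1+3*sd1 = ", signif(object@threshold, 5),
      ", ", signif(100 * object@fractionAbove, 3), "% above",
      if (!object@valid) " [INVALID]" else "", "\n", sep = "")
})

setMethod("show", "PloidyGateSet", function(object) {
  cat("PloidyGateSet (G1 mode ", signif(object@g1Mode, 4), " a.u.):\n", sep = "")
  print(object@gates, row.names = FALSE)
})

setMethod("show", "ConcentrationEstimate", function(object) {
  cat("ConcentrationEstimate: lambda ND1 = ", signif(object@lambdaNd1, 5),
      ", lambda ACTB = ", signif(object@lambdaActb, 5),
      " copies/droplet (n = ", object@nDroplets, ")\n", sep = "")
  cat("  copies per cell = ", signif(object@copiesPerCell, 5),
      " (", object@lociPerCell, " reference loci per cell)\n", sep = "")
})

setMethod("show", "GrowthFit", function(object) {
  cat("GrowthFit (", object@model, "): k = ", signif(object@k, 5),
      " 1/h, a = ", signif(object@a, 5), ", c = ", signif(object@c, 5),
      ", Td = ", if (is.na(object@doublingTime)) "undefined"
                 else paste0(signif(object@doublingTime, 4), " h"),
      if (!object@converged) " [not converged]" else "", "\n", sep = "")
})
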