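#' Normalize TMRM intensities to the FCCP/oligomycin window
#'
#' Each cell's TMRM intensity is expressed relative to the dynamic range of
#' the plate: its intensity less the mean of FCCP-treated (depolarized)
#' wells, divided by the difference between the means of oligomycin-
#' (hyperpolarized) and FCCP-treated wells. Values may fall outside [0, 1].
#' The index is exactly invariant to adding a constant to all intensities
#' (cells and both anchor wells).
#'
#' @param cellValues numeric vector of per-cell TMRM intensities (a.u.)
#' @param fccpMean mean intensity of FCCP-treated wells (a.u.)
#' @param oligoMean mean intensity of oligomycin-treated wells (a.u.;
#'   must exceed \code{fccpMean})
#' @return per-cell normalized membrane-potential index
#' @export
normalizeTmrm <- function(cellValues, fccpMean, oligoMean) {
  if (!is.finite(fccpMean) || !is.finite(oligoMean) || oligoMean <= fccpMean)
    stop("oligomycin mean must exceed FCCP mean for TMRM normalization")
  (cellValues - fccpMean) / (oligoMean - fccpMean)
}

#' Normalize MitoSOX intensities to a reference mean
#'
#' Divides per-cell MitoSOX intensities by the reference-population mean
#' (conventionally the per-plate mean of wild-type-transfected,
#' control-treated diploid cells). Jointly rescaling values and reference
#' leaves the index unchanged.
#'
#' @param cellValues numeric vector of per-cell intensities (a.u.)
#' @param referenceMean reference mean (> 0)
#' @return fold-of-reference index per cell
#' @export
normalizeMitosox <- function(cellValues, referenceMean) {
  if (!is.finite(referenceMean) || referenceMean <= 0)
    stop("reference mean must be positive")
  cellValues / referenceMean
}

#' Mitochondrial mass proxy: supra-floor area per cell
#'
#' Thresholded area per cytosolic ROI of a mitochondrial channel, in square
#' micrometres: sub-floor pixels never count toward the per-cell
#' mitochondrial area, so the measure is monotone non-increasing in the
#' floor.
#'
#' @param image numeric matrix (mitochondrial dye channel)
#' @param cellRois a \code{\linkS4class{CellROIMap}} (its cytosol map is
#'   used) or an integer label matrix
#' @param floor intensity floor (>= 0)
#' @return data.frame (cell, areaUm2)
#' @export
mitoMassArea <- function(image, cellRois, floor) {
  if (is(cellRois, "CellROIMap")) {
    lab <- cellRois@cytosol
    px <- cellRois@pixelSize
  } else {
    lab <- cellRois
    px <- attr(cellRois, "pixelSize") %||% 1.24
  }
  thresholdedAreaPerCell(image, lab, floor, pixelSizeUm = px)
}
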