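#' Mito-Stress-Test respiration metrics from an OCR trace
#'
#' Extracts the standard respiration metrics from a four-phase oxygen
#' consumption trace (basal, oligomycin, FCCP, rotenone/antimycin-A), using
#' the instrument vendor's point-selection convention: non-mitochondrial
#' respiration is the mean of the post-rotenone/antimycin phase; basal is
#' the last pre-oligomycin measurement minus non-mitochondrial; ATP-linked
#' is the last pre-oligomycin minus the minimum post-oligomycin; proton leak
#' is the minimum post-oligomycin minus non-mitochondrial; maximal is the
#' maximum post-FCCP minus non-mitochondrial. By construction
#' \code{basal = atpLinked + protonLeak} exactly. A maximal (FCCP) response
#' below basal is still reported, flagged \code{subBasalMaximal} - a known
#' behaviour of some smooth muscle lines at 1 uM FCCP.
#'
#' @param trace data.frame with columns time_min, ocr and phase (factor with
#'   levels basal, oligo, fccp, rotaa; \code{\link{makeOcrTrace}} produces
#'   this layout), at least 3 measurements per phase
#' @return one-row data.frame: nonMito, basal, atpLinked, protonLeak,
#'   maximal, subBasalMaximal
#' @export
ocrMetrics <- function(trace) {
  stopifnot(all(c("time_min", "ocr", "phase") %in% names(trace)))
  ph <- as.character(trace$phase)
  need <- c("basal", "oligo", "fccp", "rotaa")
  cnt <- table(factor(ph, levels = need))
  if (any(cnt < 3)) stop("need at least 3 measurements per phase")
  o <- order(trace$time_min)
  ocr <- trace$ocr[o]; ph <- ph[o]
  nonMito <- mean(ocr[ph == "rotaa"])
  lastBasal <- tail(ocr[ph == "basal"], 1)
  minOligo <- min(ocr[ph == "oligo"])
  maxFccp <- max(ocr[ph == "fccp"])
  atp <- lastBasal - minOligo
  leak <- minOligo - nonMito
  basal <- atp + leak        # = lastBasal - nonMito, identity exact
  maximal <- maxFccp - nonMito
  data.frame(nonMito = nonMito, basal = basal, atpLinked = atp,
             protonLeak = leak, maximal = maximal,
             subBasalMaximal = maxFccp < lastBasal)
}

#' Normalize OCR metrics per cell
#'
#' Divides every respiration metric by the well's cell count (obtained by
#' imaging the well after the assay). The additivity identity
#' \code{basal = atpLinked + protonLeak} is preserved.
#'
#' @param metrics one-row data.frame from \code{\link{ocrMetrics}}
#' @param nCells cells in the well (> 0)
#' @return the metrics divided by \code{nCells} (flag columns untouched)
#' @export
normalizePerCell <- function(metrics, nCells) {
  if (!is.finite(nCells) || nCells <= 0) stop("nCells must be positive")
  num <- c("nonMito", "basal", "atpLinked", "protonLeak", "maximal")
  metrics[num] <- metrics[num] / nCells
  metrics
}
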