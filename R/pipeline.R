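#' Per-cell measurements over a segmented field
#'
#' Builds one row per cell: nuclear centroid and area, integrated
#' nuclear-stain intensity (over the full nuclear mask), and mean nuclear
#' intensity of any further channels (GFP reporter, dyes) measured over the
#' nuclear mask eroded by \code{erodePx} pixels to avoid partial edge
#' pixels. Channel images should already be background-subtracted; NA
#' pixels are excluded, and an all-NA nucleus reports NA.
#'
#' @param roiMap a \code{\linkS4class{CellROIMap}}
#' @param stain background-subtracted nuclear-stain matrix
#' @param nuclearChannels named list of further matrices to measure as
#'   nuclear means (e.g. list(gfp = ..., dye = ...))
#' @param erodePx nuclear mask erosion for the mean measurements, pixels
#' @return data.frame (cell, x, y, areaUm2, stainTotalMeasured, then one
#'   \code{<name>Mean} column per extra channel)
#' @export
measureCells <- function(roiMap, stain, nuclearChannels = list(),
                         erodePx = 2) {
  stopifnot(is(roiMap, "CellROIMap"))
  nuc <- roiMap@nuclei
  tab <- roiTable(nuc, roiMap@pixelSize)
  if (nrow(tab) == 0) return(tab)
  idx <- which(nuc > 0)
  l <- nuc[idx]
  tot <- tapply(stain[idx], l, sum, na.rm = TRUE)
  tab$stainTotalMeasured <- as.numeric(tot)[match(tab$id, as.integer(names(tot)))]
  if (length(nuclearChannels)) {
    mask <- nuc > 0
    if (erodePx > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(erodePx) + 1L,
                                  shape = "disc")
      er <- EBImage::erode(mask * 1, brush) > 0.5
    } else er <- mask
    eidx <- which(er & mask)
    el <- nuc[eidx]
    for (nm in names(nuclearChannels)) {
      v <- nuclearChannels[[nm]][eidx]
      mns <- tapply(v, el, function(z)
        if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
      tab[[paste0(nm, "Mean")]] <-
        as.numeric(mns)[match(tab$id, as.integer(names(mns)))]
    }
  }
  names(tab)[names(tab) == "id"] <- "cell"
  tab
}

#' Run the imaging pipeline over one or more fields
#'
#' Chains, for every field: rolling background subtraction, threshold
#' nuclear segmentation, Voronoi expansion into cell and cytosolic ROIs,
#' per-cell measurements, punctum detection in the cytosol and per-cell
#' punctum sums. Punctum intensities are then pooled per batch (plate by
#' default) for the quantal mixture fit, per-cell mCN is estimated, ploidy
#' is gated automatically from the G1 peak (when enough cells), the GFP
#' transfection gate is fitted (when a \code{gfp} channel is present), and
#' mCN is normalized per (plate, media) to the mean of the reference
#' condition. The pipeline itself is deterministic: identical inputs and
#' parameters reproduce identical outputs.
#'
#' Fields must carry \code{metadata} entries \code{plate}, \code{well},
#' \code{fov}, \code{condition} and \code{media} (filled with defaults when
#' absent). Missing reference wells skip the normalization with a warning;
#' raw values are still returned.
#'
#' @param fields a \code{\linkS4class{FieldImage}} or list of them
#' @param params list overriding defaults: \code{nucThreshold} (required;
#'   a.u.), \code{minAreaUm2}, \code{maxAreaUm2}, \code{backgroundRadiusUm}
#'   (75), \code{dilationPx} (4), \code{maxExpansionUm} (133),
#'   \code{peakMin} (required; a.u.), \code{minSeparationPx} (2),
#'   \code{patchR} (2), \code{nComponents} (10), \code{minPuncta} (200),
#'   \code{referenceCondition} ("WT"), \code{batchKey} ("plate"),
#'   \code{gateMinCells} (500), \code{gfpMinCells} (1000)
#' @return list with elements \code{cells} (per-cell table), \code{fov}
#'   (per-field summary), \code{plate} (per plate x media x condition
#'   summary), \code{quantalFits} (per batch), \code{gfpFits},
#'   \code{ploidyGates}
#' @export
runImagingPipeline <- function(fields, params = list()) {
  if (is(fields, "FieldImage")) fields <- list(field1 = fields)
  p <- modifyList(list(minAreaUm2 = 30, maxAreaUm2 = Inf,
                       backgroundRadiusUm = 75, dilationPx = 4,
                       maxExpansionUm = 133, minSeparationPx = 2,
                       patchR = 2, nComponents = 10, minPuncta = 200,
                       referenceCondition = "WT", batchKey = "plate",
                       gateMinCells = 500, gfpMinCells = 1000), params)
  if (is.null(p$nucThreshold))
    stop("params$nucThreshold is required (see suggestThreshold())")
  if (is.null(p$peakMin)) stop("params$peakMin is required")

  allCells <- list(); allPuncta <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    stopifnot(is(f, "FieldImage"))
    md <- f@metadata
    meta <- list(plate = md$plate %||% "plate1",
                 well = md$well %||% paste0("W", i),
                 fov = md$fov %||% 1L,
                 condition = md$condition %||% "WT",
                 media = md$media %||% "GM")
    px <- f@pixelSize
    stain <- subtractBackground(f@channels$stain, p$backgroundRadiusUm, px)
    nuclei <- thresholdNuclei(stain, p$nucThreshold, p$minAreaUm2,
                              p$maxAreaUm2, px)
    if (max(nuclei) == 0) next
    roi <- voronoiCellRois(nuclei, p$dilationPx, p$maxExpansionUm, px)
    extra <- list()
    for (nm in setdiff(names(f@channels), c("stain", "dsdna")))
      extra[[nm]] <- subtractBackground(f@channels[[nm]],
                                        p$backgroundRadiusUm, px)
    cells <- measureCells(roi, stain, extra)
    if (!is.null(f@channels$dsdna)) {
      dsd <- subtractBackground(f@channels$dsdna, p$backgroundRadiusUm, px)
      pk <- detectPuncta(dsd, roi@cytosol, p$peakMin, p$minSeparationPx,
                         p$patchR)
      sums <- sumPunctaPerCell(pk, cellIds = cells$cell)
      cells <- merge(cells, sums, by = "cell", sort = TRUE)
      if (nrow(pk)) {
        pk$fieldId <- i
        for (nm in names(meta)) pk[[nm]] <- meta[[nm]]
        allPuncta[[length(allPuncta) + 1L]] <- pk
      }
    }
    cells$fieldId <- i
    for (nm in names(meta)) cells[[nm]] <- meta[[nm]]
    allCells[[length(allCells) + 1L]] <- cells
  }
  if (!length(allCells)) stop("no cells segmented in any field")
  cells <- do.call(rbind, allCells)
  puncta <- if (length(allPuncta)) do.call(rbind, allPuncta) else NULL

  # quantal fit per batch, mCN per cell
  quantalFits <- list()
  if (!is.null(puncta) && "punctaSum" %in% names(cells)) {
    cells$mcn <- NA_real_
    for (b in unique(puncta[[p$batchKey]])) {
      ints <- puncta$intensity[puncta[[p$batchKey]] == b]
      fit <- try(fitQuantalMixture(ints, p$nComponents,
                                   minPuncta = p$minPuncta), silent = TRUE)
      if (inherits(fit, "try-error")) {
        warning("quantal fit failed for batch ", b)
        next
      }
      quantalFits[[as.character(b)]] <- fit
      sel <- cells[[p$batchKey]] == b
      if (fit@valid) cells$mcn[sel] <- cells$punctaSum[sel] / fit@q
    }
  }

  # ploidy gates per batch
  ploidyGates <- list()
  cells$ploidyClass <- NA_character_
  for (b in unique(cells[[p$batchKey]])) {
    sel <- cells[[p$batchKey]] == b
    if (sum(sel) >= p$gateMinCells) {
      g <- try(autoGatesFromG1Peak(cells[sel, ], p$gateMinCells),
               silent = TRUE)
      if (!inherits(g, "try-error")) {
        ploidyGates[[as.character(b)]] <- g
        cells$ploidyClass[sel] <- gatePloidy(cells[sel, ], g)$ploidyClass
      }
    }
  }

  # transfection gate per batch
  gfpFits <- list()
  if ("gfpMean" %in% names(cells)) {
    cells$transfectedCall <- NA
    for (b in unique(cells[[p$batchKey]])) {
      sel <- cells[[p$batchKey]] == b
      if (sum(sel) >= p$gfpMinCells) {
        gf <- try(fitGfpMixture(cells$gfpMean[sel], p$gfpMinCells),
                  silent = TRUE)
        if (!inherits(gf, "try-error") && gf@valid) {
          gfpFits[[as.character(b)]] <- gf
          cells$transfectedCall[sel] <- cells$gfpMean[sel] > gf@threshold
        }
      }
    }
  }

  # reference normalization per (plate, media)
  if ("mcn" %in% names(cells)) {
    cells$mcnNorm <- NA_real_
    for (key in unique(paste(cells$plate, cells$media))) {
      sel <- paste(cells$plate, cells$media) == key
      ref <- sel & cells$condition == p$referenceCondition
      if (!any(ref)) {
        warning("no ", p$referenceCondition, " reference cells for ", key,
                "; normalization skipped")
        next
      }
      refMean <- mean(cells$mcn[ref], na.rm = TRUE)
      if (is.finite(refMean) && refMean > 0)
        cells$mcnNorm[sel] <- normalizeToReference(cells$mcn[sel], refMean)
    }
  }

  fov <- summarizeByFov(cells)
  plate <- summarizeByPlate(cells)
  list(cells = cells, puncta = puncta, fov = fov, plate = plate,
       quantalFits = quantalFits, gfpFits = gfpFits,
       ploidyGates = ploidyGates, params = p)
}

#' Summarize per-cell records by field of view
#'
#' Per-FOV cell counts, mean mCN (raw and normalized when present), and
#' ploidy class fractions (summing to 1 per FOV, "ungated" included).
#'
#' @param cells per-cell data.frame with plate/well/fov columns
#' @return per-FOV data.frame
#' @export
summarizeByFov <- function(cells) {
  key <- interaction(cells$plate, cells$well, cells$fov, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- cells[key == k, ]
    out <- data.frame(plate = d$plate[1], well = d$well[1], fov = d$fov[1],
                      condition = d$condition[1], media = d$media[1],
                      nCells = nrow(d))
    for (col in intersect(c("mcn", "mcnNorm", "punctaSum"), names(d)))
      out[[paste0("mean_", col)]] <- mean(d[[col]], na.rm = TRUE)
    if ("ploidyClass" %in% names(d) && any(!is.na(d$ploidyClass))) {
      cl <- d$ploidyClass
      for (g in c("2", "2S", "4", "4S", "8", "ungated"))
        out[[paste0("frac_", g)]] <- mean(cl == g, na.rm = TRUE)
    }
    out
  })
  do.call(rbind, rows)
}

summarizeByPlate <- function(cells) {
  key <- interaction(cells$plate, cells$media, cells$condition, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- cells[key == k, ]
    out <- data.frame(plate = d$plate[1], media = d$media[1],
                      condition = d$condition[1], nCells = nrow(d),
                      nFov = length(unique(paste(d$well, d$fov))))
    for (col in intersect(c("mcn", "mcnNorm"), names(d)))
      out[[paste0("mean_", col)]] <- mean(d[[col]], na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}
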