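#' Configuration for a synthetic field of view
#'
#' Builds and validates the parameter set for \code{\link{makeField}}. The
#' defaults describe sparsely plated A7r5-like smooth muscle cells imaged at
#' 1.24 um/px: a mixed-ploidy population whose integrated nuclear-stain
#' intensity is proportional to genome copies (8\% CV), cytosolic anti-dsDNA
#' puncta whose integrated intensities are integer multiples of the quantal
#' single-copy intensity \code{q} plus Gaussian noise, an optional nuclear
#' GFP transfection reporter drawn from a three-component mixture, and an
#' optional nuclear dye channel with per-ploidy mean levels.
#'
#' Per-cell total mtDNA copies are negative-binomial with mean
#' \code{copiesPerCellMean} and coefficient of variation \code{copiesCv};
#' each cell's copies are partitioned into puncta by drawing per-punctum copy
#' numbers from \code{punctaCopyWeights} (geometric-like, mode at one copy)
#' until the total is reached exactly, so ground-truth copies are conserved.
#' Cells sit on a jittered grid with centre spacing \code{cellSpacingUm};
#' puncta are placed uniformly in a cytosolic annulus between the nuclear
#' radius plus \code{punctaGapUm} and \code{punctaOuterUm}, never inside
#' nuclei.
#'
#' @param fieldSizePx integer pair (width, height) or NULL to size the field
#'   from \code{nCells} and \code{cellSpacingUm}
#' @param pixelSizeUm micrometres per pixel
#' @param nCells number of cells
#' @param ploidyWeights proportions over classes 2N, 2S, 4N, 4S, 8N (sum 1)
#' @param nuclearRadiusUm nuclear radius per ploidy class, micrometres
#' @param nuclearIntensityPerGenome integrated stain intensity per genome
#'   copy (a.u.)
#' @param nuclearCv cell-to-cell CV of integrated nuclear intensity
#' @param quantalIntensity single-copy punctum integrated intensity q (a.u.)
#' @param copiesPerCellMean,copiesCv mean and CV of true copies per cell
#' @param punctaCopyWeights proportions over per-punctum copy numbers 1..K
#' @param punctaSigma unit intensity noise sd; a k-copy punctum gets
#'   sd \code{punctaSigma * sqrt(k)} (a.u.)
#' @param psfSigmaPx point-spread sigma of rendered puncta, pixels
#' @param transfectedFraction proportion of transfected cells
#' @param gfpComponents 3x3 matrix, rows (mean, sd, weight); row 1 is the
#'   untransfected background component
#' @param dyeMeans named per-ploidy nuclear dye mean levels (a.u.), or NULL
#'   to skip the dye channel
#' @param dyeCv cell-to-cell CV of the dye level
#' @param cellSpacingUm centre-to-centre cell spacing, micrometres
#' @param punctaGapUm,punctaOuterUm cytosolic annulus bounds (micrometres;
#'   inner bound is nuclear radius + gap)
#' @param backgroundLevel,noiseSd additive background and Gaussian read
#'   noise sd per pixel (a.u.)
#' @param channels channels to render, subset of
#'   c("stain", "dsdna", "gfp", "dye")
#' @param seed master seed; all generator substreams derive from it
#' @return a validated list of class "SynthFieldConfig"
#' @export
synthFieldConfig <- function(fieldSizePx = NULL,
                             pixelSizeUm = 1.24,
                             nCells = 100,
                             ploidyWeights = c("2" = 0.60, "2S" = 0.08,
                                               "4" = 0.20, "4S" = 0.04,
                                               "8" = 0.08),
                             nuclearRadiusUm = c("2" = 8, "2S" = 9.5,
                                                 "4" = 11.3, "4S" = 13.5,
                                                 "8" = 16),
                             nuclearIntensityPerGenome = 5000,
                             nuclearCv = 0.08,
                             quantalIntensity = 100,
                             copiesPerCellMean = 400,
                             copiesCv = 0.2,
                             punctaCopyWeights = 0.4^(0:9) * 0.6 / (1 - 0.4^10),
                             punctaSigma = 8,
                             psfSigmaPx = 1.5,
                             transfectedFraction = 0.25,
                             gfpComponents = rbind(c(100, 20, 0.75),
                                                   c(500, 80, 0.15),
                                                   c(2000, 300, 0.10)),
                             dyeMeans = NULL,
                             dyeCv = 0.10,
                             cellSpacingUm = 180,
                             punctaGapUm = 2.5,
                             punctaOuterUm = 80,
                             backgroundLevel = 20,
                             noiseSd = 1.4,
                             channels = c("stain", "dsdna"),
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "SynthFieldConfig"
  validateSynthConfig(cfg)
  cfg
}

validateSynthConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SynthFieldConfig"))
  if (abs(sum(cfg$ploidyWeights) - 1) > 1e-9)
    stop("ploidyWeights must sum to 1")
  if (abs(sum(cfg$punctaCopyWeights) - 1) > 1e-9)
    stop("punctaCopyWeights must sum to 1")
  if (any(cfg$punctaCopyWeights < 0) || any(cfg$ploidyWeights < 0))
    stop("proportions must be non-negative")
  if (cfg$nCells < 0 || cfg$pixelSizeUm <= 0 || cfg$quantalIntensity <= 0 ||
      cfg$copiesPerCellMean < 0 || any(cfg$nuclearRadiusUm <= 0) ||
      cfg$cellSpacingUm <= 0 || cfg$psfSigmaPx <= 0)
    stop("intensities, radii, counts and spacings must be positive")
  if (!all(names(cfg$ploidyWeights) %in% names(cfg$nuclearRadiusUm)))
    stop("nuclearRadiusUm must cover every ploidy class")
  if (cfg$transfectedFraction < 0 || cfg$transfectedFraction > 1)
    stop("transfectedFraction must be a proportion")
  gm <- cfg$gfpComponents
  if (!is.matrix(gm) || nrow(gm) != 3 || ncol(gm) != 3)
    stop("gfpComponents must be a 3x3 matrix (mean, sd, weight rows)")
  if (abs(sum(gm[, 3]) - 1) > 1e-9) stop("gfp component weights must sum to 1")
  invisible(TRUE)
}

# genome copy content per ploidy class; S-phase classes span their interval
ploidyGenomes <- function(classes, u) {
  g <- numeric(length(classes))
  g[classes == "2"] <- 2
  g[classes == "4"] <- 4
  g[classes == "8"] <- 8
  s2 <- classes == "2S"
  g[s2] <- 2 + 2 * u[s2]
  s4 <- classes == "4S"
  g[s4] <- 4 + 4 * u[s4]
  g
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Renders the channels requested in the configuration and records the full
#' generator ground truth. Nuclei are anti-aliased disks whose integrated
#' stain intensity is proportional to genome copies; puncta are isotropic
#' Gaussian spots of integrated intensity \code{copies * q + noise} placed in
#' cytosolic annuli (never inside nuclei); GFP and dye levels fill the
#' nuclear disk. Given the same configuration (including its seed) the
#' output is bit-identical.
#'
#' @param config a \code{\link{synthFieldConfig}}
#' @return a \code{\linkS4class{FieldImage}}; \code{groundTruth(x)$cells} has
#'   one row per cell (position, ploidy class, genome copies, true mtDNA
#'   copies, transfection flag, channel levels) and
#'   \code{groundTruth(x)$puncta} one row per punctum (owner cell, position,
#'   copy number, integrated intensity). Coordinates are 0-based pixel
#'   centres.
#' @export
makeField <- function(config) {
  validateSynthConfig(config)
  cfg <- config
  px <- cfg$pixelSizeUm
  spacing <- cfg$cellSpacingUm / px
  outerPx <- cfg$punctaOuterUm / px
  margin <- ceiling(outerPx + 3)

  n <- cfg$nCells
  if (n > 0) {
    ncol0 <- ceiling(sqrt(n))
    nrow0 <- ceiling(n / ncol0)
  } else ncol0 <- nrow0 <- 0

  if (is.null(cfg$fieldSizePx)) {
    W <- ceiling(ncol0 * spacing + 2 * margin)
    H <- ceiling(nrow0 * spacing + 2 * margin)
    if (n == 0) W <- H <- 256
  } else {
    W <- cfg$fieldSizePx[1]; H <- cfg$fieldSizePx[2]
    capCols <- floor((W - 2 * margin) / spacing)
    capRows <- floor((H - 2 * margin) / spacing)
    if (n > 0 && (capCols < 1 || capRows < 1 || capCols * capRows < n))
      stop("overcrowded field: ", n, " cells cannot be placed at spacing ",
           cfg$cellSpacingUm, " um in a ", W, "x", H, " px field")
    ncol0 <- min(max(ncol0, ceiling(n / capRows)), capCols)
    nrow0 <- ceiling(n / ncol0)
  }

  blank <- function() matrix(0, nrow = H, ncol = W)
  channels <- stats::setNames(lapply(cfg$channels, function(i) blank()),
                              cfg$channels)

  cells <- data.frame()
  puncta <- data.frame()

  if (n > 0) {
    # -- layout (jittered grid keeps nuclei non-overlapping by construction)
    idx <- seq_len(n) - 1L
    gx <- idx %% ncol0
    gy <- idx %/% ncol0
    maxR <- max(cfg$nuclearRadiusUm) / px
    jit <- max(0, (spacing / 2 - maxR - 2) * 0.5)
    lay <- withSeed(childSeed(cfg$seed, 1), {
      list(jx = runif(n, -jit, jit), jy = runif(n, -jit, jit))
    })
    cx <- margin + (gx + 0.5) * spacing + lay$jx
    cy <- margin + (gy + 0.5) * spacing + lay$jy

    # -- ploidy, genome content, nuclear intensity
    pl <- withSeed(childSeed(cfg$seed, 2), {
      cls <- sample(names(cfg$ploidyWeights), n, replace = TRUE,
                    prob = cfg$ploidyWeights)
      list(cls = cls, us = runif(n), z = rnorm(n))
    })
    genomes <- ploidyGenomes(pl$cls, pl$us)
    rPx <- cfg$nuclearRadiusUm[pl$cls] / px
    stainTotal <- genomes * cfg$nuclearIntensityPerGenome *
      pmax(0.1, 1 + cfg$nuclearCv * pl$z)

    # -- true copies per cell (inverse-CDF so that paired configurations
    #    generated from one master seed share their uniform draws)
    copies <- withSeed(childSeed(cfg$seed, 3), {
      u <- runif(n)
      mu <- cfg$copiesPerCellMean
      if (mu <= 0) rep(0L, n)
      else if (cfg$copiesCv^2 * mu <= 1) qpois(u, mu)
      else qnbinom(u, size = mu / (cfg$copiesCv^2 * mu - 1), mu = mu)
    })

    # -- transfection flags and channel levels
    gfpLevel <- transfected <- dyeLevel <- NULL
    aux <- withSeed(childSeed(cfg$seed, 4), {
      transfected <- runif(n) < cfg$transfectedFraction
      gm <- cfg$gfpComponents
      wFg <- gm[2:3, 3] / sum(gm[2:3, 3])
      comp <- ifelse(transfected,
                     sample(2:3, n, replace = TRUE, prob = wFg), 1L)
      gfpLevel <- rnorm(n, gm[comp, 1], gm[comp, 2])
      dyeLevel <- if (!is.null(cfg$dyeMeans)) {
        base <- cfg$dyeMeans[pl$cls]
        if (anyNA(base)) stop("dyeMeans must name every ploidy class")
        pmax(0, base * (1 + cfg$dyeCv * rnorm(n)))
      } else rep(NA_real_, n)
      list(transfected = transfected, gfpLevel = pmax(0, gfpLevel),
           dyeLevel = dyeLevel)
    })

    cells <- data.frame(cell = seq_len(n), x = cx, y = cy,
                        ploidy = pl$cls, genomes = genomes,
                        radiusPx = as.numeric(rPx),
                        stainTotal = stainTotal,
                        copies = as.integer(copies),
                        transfected = aux$transfected,
                        gfpLevel = aux$gfpLevel,
                        dyeLevel = aux$dyeLevel,
                        stringsAsFactors = FALSE)

    # -- puncta: partition each cell's copies exactly, place in the annulus
    puncta <- withSeed(childSeed(cfg$seed, 5), {
      K <- length(cfg$punctaCopyWeights)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        tot <- copies[i]
        if (tot <= 0) next
        ks <- integer(0)
        while (sum(ks) < tot) {
          draw <- sample.int(K, size = max(16, ceiling(tot / 1.5)),
                             replace = TRUE, prob = cfg$punctaCopyWeights)
          ks <- c(ks, draw)
          cum <- cumsum(ks)
          if (any(cum >= tot)) {
            stop_at <- which(cum >= tot)[1]
            ks <- ks[seq_len(stop_at)]
            ks[stop_at] <- ks[stop_at] - (cum[stop_at] - tot)
            break
          }
        }
        m <- length(ks)
        rIn <- rPx[i] + cfg$punctaGapUm / px
        rOut <- max(outerPx, rIn + 2)   # annulus never degenerate
        rr <- sqrt(runif(m, rIn^2, rOut^2))
        th <- runif(m, 0, 2 * pi)
        intens <- pmax(0.05 * cfg$quantalIntensity,
                       ks * cfg$quantalIntensity +
                         rnorm(m, 0, cfg$punctaSigma * sqrt(ks)))
        out[[i]] <- data.frame(cell = i,
                               x = cx[i] + rr * cos(th),
                               y = cy[i] + rr * sin(th),
                               copies = ks, intensity = intens)
      }
      do.call(rbind, c(out, list(make.row.names = FALSE)))
    })
    if (is.null(puncta)) puncta <- data.frame(cell = integer(0), x = numeric(0),
                                              y = numeric(0), copies = integer(0),
                                              intensity = numeric(0))

    # -- render
    if ("stain" %in% cfg$channels) {
      lev <- stainTotal / (pi * rPx^2)
      channels$stain <- .renderDisks(channels$stain, cx, cy,
                                     as.numeric(rPx), as.numeric(lev))
    }
    if ("dsdna" %in% cfg$channels && nrow(puncta) > 0) {
      channels$dsdna <- .renderSpots(channels$dsdna, puncta$x, puncta$y,
                                     puncta$intensity, cfg$psfSigmaPx)
    }
    if ("gfp" %in% cfg$channels) {
      channels$gfp <- .renderDisks(channels$gfp, cx, cy,
                                   as.numeric(rPx), aux$gfpLevel)
    }
    if ("dye" %in% cfg$channels) {
      if (is.null(cfg$dyeMeans)) stop("dye channel requested without dyeMeans")
      channels$dye <- .renderDisks(channels$dye, cx, cy,
                                   as.numeric(rPx), aux$dyeLevel)
    }
  }

  channels <- withSeed(childSeed(cfg$seed, 6), {
    lapply(channels, function(ch)
      ch + cfg$backgroundLevel + matrix(rnorm(H * W, 0, cfg$noiseSd), H, W))
  })

  new("FieldImage", channels = channels, pixelSize = px, bitDepth = 16,
      truth = list(cells = cells, puncta = puncta, config = cfg),
      metadata = list())
}

#' Generate a synthetic duplex ddPCR droplet table
#'
#' Per-droplet target occupancies are independent Poisson draws (via inverse
#' CDF, so two conditions generated from the same seed are common-random-
#' number paired); two-channel fluorescence amplitudes place occupied and
#' empty droplets in well-separated clusters, giving the four populations of
#' a duplex EvaGreen assay (empty, ND1-only, ACTB-only, double-positive).
#'
#' @param lambdaNd1,lambdaActb mean copies per droplet for the mitochondrial
#'   and nuclear reference targets (>= 0)
#' @param nDroplets number of droplets (>= 1)
#' @param intensityModel list with elements \code{negMean}, \code{negSd},
#'   \code{posShift}, \code{posSd}, each length 2 (channel 1 = ND1,
#'   channel 2 = ACTB)
#' @param seed master seed
#' @return data.frame with columns ch1, ch2 (a.u.) and ground truth
#'   occNd1, occActb (true copies per droplet)
#' @export
makeDroplets <- function(lambdaNd1, lambdaActb, nDroplets,
                         intensityModel = list(negMean = c(1000, 1000),
                                               negSd = c(100, 100),
                                               posShift = c(4000, 4000),
                                               posSd = c(200, 200)),
                         seed = 1L) {
  stopifnot(lambdaNd1 >= 0, lambdaActb >= 0, nDroplets >= 1)
  occ1 <- withSeed(childSeed(seed, 11), qpois(runif(nDroplets), lambdaNd1))
  occ2 <- withSeed(childSeed(seed, 12), qpois(runif(nDroplets), lambdaActb))
  im <- intensityModel
  amp <- withSeed(childSeed(seed, 13), {
    p1 <- occ1 > 0; p2 <- occ2 > 0
    ch1 <- rnorm(nDroplets, im$negMean[1] + im$posShift[1] * p1,
                 ifelse(p1, im$posSd[1], im$negSd[1]))
    ch2 <- rnorm(nDroplets, im$negMean[2] + im$posShift[2] * p2,
                 ifelse(p2, im$posSd[2], im$negSd[2]))
    list(ch1 = ch1, ch2 = ch2)
  })
  data.frame(ch1 = amp$ch1, ch2 = amp$ch2,
             occNd1 = occ1, occActb = occ2)
}

#' Generate a synthetic exponential growth-count series
#'
#' Counts follow \code{offset + n0 * exp(k * t)} sampled every \code{dt}
#' hours, with optional Poisson noise on the expected count. Expected counts
#' above \code{maxCount} (confluence) are truncated and flagged.
#'
#' @param n0 initial cell count (amplitude)
#' @param k growth rate constant, 1/h
#' @param offset additive count offset
#' @param tEnd,dt series end and sampling interval, hours (dt > 0)
#' @param noise "poisson" or "none"
#' @param maxCount confluence ceiling
#' @param seed master seed
#' @return data.frame (time_h, count) with attribute "truncated"
#' @export
makeGrowthCounts <- function(n0, k, offset = 0, tEnd = 72, dt = 1 / 3,
                             noise = c("poisson", "none"),
                             maxCount = 1e6, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(dt > 0, tEnd >= dt)
  t <- seq(0, tEnd, by = dt)
  mu <- offset + n0 * exp(k * t)
  truncated <- any(mu > maxCount)
  mu <- pmin(mu, maxCount)
  count <- if (noise == "poisson")
    withSeed(childSeed(seed, 21), qpois(runif(length(mu)), mu)) else mu
  out <- data.frame(time_h = t, count = count)
  attr(out, "truncated") <- truncated
  out
}

#' Generate a synthetic Mito-Stress-Test OCR trace
#'
#' A stepwise oxygen-consumption trace over the four phases basal,
#' oligomycin, FCCP and rotenone/antimycin-A, with measurements at 3-minute
#' increments and Gaussian noise. Injection times fall between phases.
#'
#' @param levels length-4 phase mean OCR (pmol O2/min/well), ordered basal,
#'   oligomycin, FCCP, rotenone/antimycin-A
#' @param nPerPhase measurements per phase (>= 3)
#' @param noiseSd Gaussian noise sd
#' @param dtMin measurement interval, minutes
#' @param nCells cells per well recorded alongside the trace
#' @param seed master seed
#' @return data.frame (time_min, ocr, phase) with attributes "injections"
#'   (named times of oligo, fccp, rotaa) and "nCells"
#' @export
makeOcrTrace <- function(levels, nPerPhase = 3, noiseSd = 0, dtMin = 3,
                         nCells = NA_real_, seed = 1L) {
  stopifnot(length(levels) == 4, nPerPhase >= 3)
  phases <- c("basal", "oligo", "fccp", "rotaa")
  ph <- rep(phases, each = nPerPhase)
  t <- seq_along(ph) * dtMin
  mu <- rep(levels, each = nPerPhase)
  ocr <- if (noiseSd > 0)
    withSeed(childSeed(seed, 31), mu + rnorm(length(mu), 0, noiseSd)) else mu
  out <- data.frame(time_min = t, ocr = ocr,
                    phase = factor(ph, levels = phases))
  inj <- c(oligo = t[nPerPhase] + dtMin / 2,
           fccp = t[2 * nPerPhase] + dtMin / 2,
           rotaa = t[3 * nPerPhase] + dtMin / 2)
  attr(out, "injections") <- inj
  attr(out, "nCells") <- nCells
  out
}
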