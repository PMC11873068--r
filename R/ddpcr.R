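#' Classify duplex droplets into the four populations
#'
#' Quadrant gating of two-channel droplet amplitudes: droplets above the
#' channel-1 threshold carry the mitochondrial target (ND1), droplets above
#' the channel-2 threshold carry the nuclear reference (ACTB), giving the
#' classes negative, nd1, actb and double. Thresholds may be supplied
#' manually or derived per channel ("auto") by splitting the bimodal
#' amplitude distribution at the midpoint between the two cluster centres
#' (2-means with deterministic quantile initialization). Auto gating flags
#' a channel whose clusters are not separated (centre gap below twice the
#' pooled within-cluster spread). Gating is idempotent: reapplying the same
#' thresholds reproduces the labels.
#'
#' @param droplets data.frame with columns ch1, ch2 (a.u.)
#' @param gates "auto", or numeric length-2 (channel-1, channel-2 thresholds)
#' @param minDroplets minimum droplets for auto mode (default 1000)
#' @return \code{droplets} with a \code{class} factor column (levels
#'   negative, nd1, actb, double) and attribute "thresholds"; auto mode also
#'   sets attribute "separationFlag" per channel
#' @export
classifyDroplets <- function(droplets, gates = "auto", minDroplets = 1000) {
  stopifnot(all(c("ch1", "ch2") %in% names(droplets)))
  sepFlag <- c(ch1 = FALSE, ch2 = FALSE)
  if (identical(gates, "auto")) {
    if (nrow(droplets) < minDroplets)
      stop("auto gating needs at least ", minDroplets, " droplets")
    split1 <- valleyThreshold(droplets$ch1)
    split2 <- valleyThreshold(droplets$ch2)
    thr <- c(split1$threshold, split2$threshold)
    sepFlag <- c(ch1 = !split1$separated, ch2 = !split2$separated)
  } else {
    stopifnot(is.numeric(gates), length(gates) == 2)
    thr <- gates
  }
  p1 <- droplets$ch1 > thr[1]
  p2 <- droplets$ch2 > thr[2]
  cls <- ifelse(p1 & p2, "double",
                ifelse(p1, "nd1", ifelse(p2, "actb", "negative")))
  droplets$class <- factor(cls, levels = c("negative", "nd1", "actb",
                                           "double"))
  attr(droplets, "thresholds") <- thr
  attr(droplets, "separationFlag") <- sepFlag
  droplets
}

valleyThreshold <- function(v) {
  cen0 <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
  if (diff(cen0) < 1e-9) {             # effectively unimodal
    return(list(threshold = max(v) + 1, separated = FALSE))
  }
  km <- stats::kmeans(v, centers = matrix(cen0, 2, 1))
  cen <- sort(km$centers[, 1])
  within <- sqrt(km$tot.withinss / length(v))
  # splitting a unimodal distribution yields centres ~1.6 within-sds apart;
  # genuinely bimodal amplitude clusters sit many sds apart
  list(threshold = mean(cen), separated = diff(cen) > 4 * within)
}

#' Poisson correction of a negative-droplet fraction
#'
#' Mean copies per droplet from the fraction of droplets negative for a
#' target: \code{lambda = -ln(nNegative / nTotal)}. Saturated wells (no
#' negative droplets) return the lower bound \code{ln(nTotal)} with a
#' warning rather than an estimate.
#'
#' @param nNegative droplets negative for the target (0..nTotal)
#' @param nTotal total droplets (> 0)
#' @return lambda, copies per droplet; attribute "saturated" marks bounds
#' @export
poissonConcentration <- function(nNegative, nTotal) {
  stopifnot(nTotal > 0, nNegative >= 0, nNegative <= nTotal)
  if (nNegative == 0) {
    warning("no negative droplets: returning a lower bound on lambda")
    lam <- log(nTotal)
    attr(lam, "saturated") <- TRUE
    return(lam)
  }
  lam <- -log(nNegative / nTotal)
  attr(lam, "saturated") <- FALSE
  lam
}

#' Absolute mtDNA copies per cell from duplex occupancies
#'
#' The mitochondrial concentration divided by the per-cell-equivalent
#' nuclear reference concentration:
#' \code{mCN = lambdaNd1 / (lambdaActb / lociPerCell)}. The default of six
#' reference loci per cell corresponds to three amplified loci per haploid
#' genome in a diploid cell, and scales the result directly.
#'
#' @param lambdaNd1 mitochondrial target, copies per droplet
#' @param lambdaActb nuclear reference, copies per droplet (> 0)
#' @param lociPerCell reference loci per cell (>= 1, default 6)
#' @return mtDNA copies per cell
#' @export
copiesPerCell <- function(lambdaNd1, lambdaActb, lociPerCell = 6) {
  stopifnot(lociPerCell >= 1)
  if (!is.finite(lambdaActb) || lambdaActb <= 0)
    stop("nuclear reference concentration must be positive")
  as.numeric(lambdaNd1) / (as.numeric(lambdaActb) / lociPerCell)
}

#' Full ddPCR quantification of a classified droplet table
#'
#' Chains classification (if needed), per-target Poisson correction and the
#' copies-per-cell ratio, with binomial confidence bounds on each lambda
#' propagated from the negative fractions.
#'
#' @param droplets data.frame with ch1/ch2 (and optionally a class column
#'   from \code{\link{classifyDroplets}})
#' @param gates passed to \code{\link{classifyDroplets}} when unclassified
#' @param lociPerCell reference loci per cell
#' @param conf confidence level for the binomial bounds
#' @return a \code{\linkS4class{ConcentrationEstimate}}
#' @export
estimateConcentration <- function(droplets, gates = "auto", lociPerCell = 6,
                                  conf = 0.95) {
  if (is.null(droplets$class)) droplets <- classifyDroplets(droplets, gates)
  n <- nrow(droplets)
  neg1 <- sum(droplets$class %in% c("negative", "actb"))
  neg2 <- sum(droplets$class %in% c("negative", "nd1"))
  l1 <- poissonConcentration(neg1, n)
  l2 <- poissonConcentration(neg2, n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lamCi <- function(nneg) {
    p <- max(nneg, 1) / n
    se <- sqrt(p * (1 - p) / n)
    rev(-log(pmin(pmax(p + c(-1, 1) * z * se, 1 / n), 1)))
  }
  ci1 <- lamCi(neg1); ci2 <- lamCi(neg2)
  cpc <- copiesPerCell(l1, l2, lociPerCell)
  ciC <- c(copiesPerCell(ci1[1], ci2[2], lociPerCell),
           copiesPerCell(ci1[2], max(ci2[1], 1e-12), lociPerCell))
  ci <- cbind(nd1 = ci1, actb = ci2, copiesPerCell = ciC)
  rownames(ci) <- c("lo", "hi")
  new("ConcentrationEstimate", lambdaNd1 = as.numeric(l1),
      lambdaActb = as.numeric(l2), nDroplets = n,
      lociPerCell = lociPerCell, copiesPerCell = cpc, ci = ci,
      saturated = c(nd1 = isTRUE(attr(l1, "saturated")),
                    actb = isTRUE(attr(l2, "saturated"))))
}
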