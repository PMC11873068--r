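# Unconstrained univariate Gaussian-mixture EM with k-means++ init and
# multiple seeded restarts. Deterministic given the seed; identifiable by
# sorting components by mean.
gaussianMixtureEM <- function(x, G, nstart = 10, tol = 1e-8, maxit = 500,
                              seed = 1L) {
  n <- length(x)
  kppCenters <- function() {
    cen <- x[sample.int(n, 1)]
    d2 <- (x - cen)^2
    for (g in seq_len(G - 1)) {
      p <- d2 / sum(d2)
      nc <- x[sample.int(n, 1, prob = p)]
      cen <- c(cen, nc)
      d2 <- pmin(d2, (x - nc)^2)
    }
    cen
  }
  best <- NULL
  withSeed(seed, {
    for (s in seq_len(nstart)) {
      mu <- sort(kppCenters())
      sg <- rep(max(stats::sd(x) / G, 1e-8), G)
      w <- rep(1 / G, G)
      ll0 <- -Inf
      for (it in seq_len(maxit)) {
        dens <- vapply(seq_len(G),
                       function(g) w[g] * stats::dnorm(x, mu[g], sg[g]),
                       numeric(n))
        tot <- rowSums(dens)
        tot[tot <= 0] <- .Machine$double.xmin
        ll <- sum(log(tot))
        r <- dens / tot
        nk <- colSums(r)
        if (any(nk < 1e-8)) break       # emptied component: abandon start
        w <- nk / n
        mu <- colSums(r * x) / nk
        sg <- pmax(sqrt(colSums(r * (outer(x, mu, "-"))^2) / nk), 1e-8)
        if (it > 5 && abs(ll - ll0) < tol * abs(ll)) break
        ll0 <- ll
      }
      if (is.null(best) || ll > best$ll)
        best <- list(mu = mu, sigma = sg, weight = w, ll = ll)
    }
  })
  o <- order(best$mu)
  list(mu = best$mu[o], sigma = best$sigma[o], weight = best$weight[o],
       logLik = best$ll)
}

#' Triple-Gaussian transfection gate on nuclear GFP intensity
#'
#' Fits a three-component Gaussian mixture to nuclear GFP mean intensities
#' (EM, k-means++ initialization, 10 seeded restarts) and defines cells
#' above \code{mu1 + 3 * sigma1} - the mean plus three standard deviations
#' of the lowest (untransfected background) component - as transfected.
#'
#' @param nuclearGfp numeric vector of nuclear GFP mean intensities
#' @param minCells minimum sample size (default 1000)
#' @param nstart EM restarts
#' @param seed seed for the restarts
#' @return a \code{\linkS4class{GfpMixtureFit}}; invalid when the background
#'   component is degenerate (sigma1 ~ 0) or carries weight below 0.2
#' @export
fitGfpMixture <- function(nuclearGfp, minCells = 1000, nstart = 10,
                          seed = 1L) {
  x <- nuclearGfp[is.finite(nuclearGfp)]
  if (length(x) < minCells)
    stop("need at least ", minCells, " cells (got ", length(x), ")")
  f <- gaussianMixtureEM(x, G = 3, nstart = nstart, seed = seed)
  thr <- f$mu[1] + 3 * f$sigma[1]
  valid <- f$sigma[1] > 1e-6 * max(1, abs(f$mu[1])) && f$weight[1] >= 0.2
  new("GfpMixtureFit", mu = f$mu, sigma = f$sigma,
      weight = f$weight / sum(f$weight), threshold = thr,
      fractionAbove = mean(x > thr), logLik = f$logLik, valid = valid)
}

#' Derive ploidy gates from the diploid G0/G1 intensity peak
#'
#' A reproducible stand-in for manual gating: locates the diploid G0/G1
#' modal integrated nuclear-stain intensity \code{m} (lowest substantial
#' mode of the kernel density estimate) and builds intensity boxes
#' \code{[0.75, 1.25) m} for 2N, \code{[1.5, 2.5) m} for 4N and
#' \code{[3, 5) m} for 8N; S-phase gates fill the gaps between consecutive
#' boxes. All gates share an upper nuclear-area bound of six times the
#' median area. Gate boundaries scale linearly with any global intensity
#' rescale, since \code{m} does.
#'
#' @param cells data.frame with columns \code{stainTotalMeasured} (or
#'   \code{intensity}) and \code{areaUm2} (or \code{area})
#' @param minCells minimum population size (default 500)
#' @param modeProminence a mode must reach this fraction of the tallest
#'   density peak to count (default 0.25)
#' @return a \code{\linkS4class{PloidyGateSet}}
#' @export
autoGatesFromG1Peak <- function(cells, minCells = 500,
                                modeProminence = 0.25) {
  int <- cells[["stainTotalMeasured"]] %||% cells[["intensity"]]
  area <- cells[["areaUm2"]] %||% cells[["area"]]
  if (is.null(int) || is.null(area)) stop("need intensity and area columns")
  int <- int[is.finite(int)]
  if (length(int) < minCells)
    stop("need at least ", minCells, " cells (got ", length(int), ")")
  d <- stats::density(int, n = 1024)
  isMax <- which(diff(sign(diff(d$y))) == -2) + 1
  if (!length(isMax)) isMax <- which.max(d$y)
  strong <- isMax[d$y[isMax] >= modeProminence * max(d$y)]
  if (!length(strong)) stop("no detectable G1 intensity mode")
  m <- d$x[min(strong)]
  if (m <= 0) stop("no detectable G1 intensity mode")
  amax <- 6 * stats::median(area, na.rm = TRUE)
  gates <- data.frame(
    class = c("2", "2S", "4", "4S", "8"),
    intMin = m * c(0.75, 1.25, 1.50, 2.50, 3.00),
    intMax = m * c(1.25, 1.50, 2.50, 3.00, 5.00),
    areaMin = 0,
    areaMax = amax,
    stringsAsFactors = FALSE)
  new("PloidyGateSet", gates = gates, g1Mode = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify cells by ploidy gates
#'
#' Assigns each cell the class of the (single, by construction) gate whose
#' intensity interval \code{[intMin, intMax)} and area interval contain it,
#' or "ungated".
#'
#' @param cells data.frame with intensity and area columns (as in
#'   \code{\link{autoGatesFromG1Peak}})
#' @param gates a \code{\linkS4class{PloidyGateSet}}
#' @return \code{cells} with a \code{ploidyClass} column appended
#' @export
gatePloidy <- function(cells, gates) {
  stopifnot(is(gates, "PloidyGateSet"))
  int <- cells[["stainTotalMeasured"]] %||% cells[["intensity"]]
  area <- cells[["areaUm2"]] %||% cells[["area"]]
  g <- gates@gates
  cls <- rep("ungated", length(int))
  for (i in seq_len(nrow(g))) {
    inGate <- !is.na(int) & int >= g$intMin[i] & int < g$intMax[i] &
      !is.na(area) & area >= g$areaMin[i] & area <= g$areaMax[i]
    cls[inGate] <- g$class[i]
  }
  cells$ploidyClass <- cls
  cells
}

#' Fraction of cells above a floor
#'
#' Share of values strictly above \code{floor} - e.g. the fraction of cells
#' gated "high" for a ROS dye relative to background intensity.
#'
#' @param values numeric vector (non-empty)
#' @param floor threshold (>= 0)
#' @return proportion in [0, 1]
#' @export
fractionHigh <- function(values, floor) {
  stopifnot(floor >= 0)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values")
  mean(v > floor)
}
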