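#' Fit the quantal Gaussian mixture to punctum intensities
#'
#' Models the integrated punctum intensity distribution as a mixture of
#' \code{nComponents} Gaussians whose means are constrained to integer
#' multiples \code{k * q} of a single quantal intensity \code{q} (one mtDNA
#' copy per nucleoid for the most abundant, single-copy component), with
#' component sd \code{sigma * sqrt(k)} (noise variance additive over
#' quanta).
#'
#' The default method ("wls") bins the intensities (Freedman-Diaconis) and
#' minimizes the Poisson-weighted squared residual between observed and
#' model counts over \code{(q, sigma)}, solving the non-negative component
#' weights exactly at each step; 20 log-spaced starts for \code{q} between
#' the 5th percentile and the histogram mode avoid the k-aliasing local
#' optimum at q/2. Method "em" runs a constrained-mean EM on the raw sample
#' and is provided as an equivalent alternative.
#'
#' The fit is flagged invalid when it does not converge or when the
#' single-copy component is not the most abundant; invalid fits block
#' downstream copy-number estimation.
#'
#' @param intensities numeric vector of integrated punctum intensities (a.u.)
#' @param nComponents number of quantal components (default 10)
#' @param method "wls" (histogram weighted least squares) or "em"
#' @param minPuncta minimum sample size (default 200)
#' @return a \code{\linkS4class{QuantalFit}}
#' @export
fitQuantalMixture <- function(intensities, nComponents = 10,
                              method = c("wls", "em"), minPuncta = 200) {
  method <- match.arg(method)
  x <- intensities[is.finite(intensities) & intensities > 0]
  if (length(x) < minPuncta)
    stop("need at least ", minPuncta, " puncta (got ", length(x), ")")
  K <- as.integer(nComponents)

  # degenerate sample: all intensities (numerically) identical
  if (stats::sd(x) < 1e-9 * mean(x)) {
    w <- c(1, rep(0, K - 1))
    return(new("QuantalFit", q = mean(x), weights = w, sigma = 0,
               gof = 0, nPuncta = length(x), method = method, valid = TRUE))
  }

  if (method == "wls") fitQuantalWls(x, K) else fitQuantalEm(x, K)
}

quantalHistogram <- function(x) {
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)   # Freedman-Diaconis
  if (bw <= 0) bw <- diff(range(x)) / 50
  nb <- min(400, max(25, ceiling(diff(range(x)) / bw)))
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = nb + 1),
                      plot = FALSE)
  list(mids = h$mids, counts = h$counts, breaks = h$breaks,
       width = diff(h$breaks[1:2]))
}

# expected counts per bin: exact bin integrals of each component (midpoint
# evaluation is badly biased once the bin width approaches sigma)
quantalDesign <- function(breaks, q, sigma, K, n) {
  ks <- seq_len(K)
  nb <- length(breaks) - 1
  vapply(ks, function(k) {
    s <- pmax(sigma * sqrt(k), 1e-9)
    p <- stats::pnorm(breaks, k * q, s)
    n * (p[-1] - p[-length(p)])
  }, numeric(nb))
}

fitQuantalWls <- function(x, K) {
  h <- quantalHistogram(x)
  n <- length(x)
  wts <- 1 / pmax(h$counts, 1)            # Poisson histogram weights
  sw <- sqrt(wts)

  objective <- function(par) {
    q <- exp(par[1]); sigma <- exp(par[2])
    A0 <- quantalDesign(h$breaks, q, sigma, K, n)
    A <- A0 * sw
    b <- h$counts * sw
    sol <- try(pracma::lsqnonneg(A, b), silent = TRUE)
    if (inherits(sol, "try-error")) return(list(ssr = Inf))
    # component weight = its share of the predicted count mass; an
    # amplitude on a component lying outside the histogram support has a
    # near-zero design column and correctly gets (near-)zero weight
    mass <- sol$x * colSums(A0)
    list(ssr = sum((A %*% sol$x - b)^2), w = mass)
  }

  # multi-start grid for q: 5th percentile to the histogram mode
  qmode <- h$mids[which.max(h$counts)]
  q5 <- stats::quantile(x, 0.05, names = FALSE)
  lo <- max(min(q5, 0.7 * qmode), 1e-6)
  hi <- max(qmode * 1.1, lo * 1.2)
  starts <- exp(seq(log(lo), log(hi), length.out = 20))

  # among multi-start solutions prefer the best one in which the
  # single-copy component dominates (the acceptance rule); a k-aliased
  # optimum at q/m fits the histogram equally well but puts its mass on
  # components m, 2m, ... and is rejected here
  bestAny <- NULL; bestValid <- NULL
  for (q0 in starts) {
    opt <- try(stats::optim(c(log(q0), log(0.1 * q0)),
                            function(p) objective(p)$ssr,
                            method = "L-BFGS-B",
                            lower = c(log(lo * 0.5), log(1e-4 * q0)),
                            upper = c(log(hi * 1.5), log(q0))),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) next
    ow <- objective(opt$par)$w
    if (is.null(ow) || sum(ow) <= 0) next
    cand <- list(value = opt$value, q = exp(opt$par[1]),
                 sigma = exp(opt$par[2]), w = ow / sum(ow))
    if (is.null(bestAny) || cand$value < bestAny$value) bestAny <- cand
    if (which.max(cand$w) == 1L &&
        (is.null(bestValid) || cand$value < bestValid$value))
      bestValid <- cand
  }
  if (is.null(bestAny))
    return(new("QuantalFit", q = 1, weights = c(1, rep(0, K - 1)), sigma = 1,
               gof = Inf, nPuncta = length(x), method = "wls", valid = FALSE))
  sel <- bestValid %||% bestAny
  new("QuantalFit", q = sel$q, weights = as.numeric(sel$w),
      sigma = sel$sigma, gof = sqrt(sel$value), nPuncta = length(x),
      method = "wls", valid = !is.null(bestValid))
}

fitQuantalEm <- function(x, K, maxit = 500, tol = 1e-10) {
  n <- length(x)
  # initialize from the histogram mode (single-copy peak)
  h <- quantalHistogram(x)
  q <- h$mids[which.max(h$counts)]
  sigma <- max(0.05 * q, stats::mad(x[x < 1.5 * q], center = q))
  w <- rep(1 / K, K)
  ks <- seq_len(K)
  ll0 <- -Inf; converged <- FALSE
  for (it in seq_len(maxit)) {
    dens <- vapply(ks, function(k)
      w[k] * stats::dnorm(x, k * q, pmax(sigma * sqrt(k), 1e-9)), numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    # maximizing sum_ik r_ik * -(x_i - k q)^2 / (2 sigma^2 k) gives
    #   q = sum_ik r_ik x_i / sum_ik r_ik k,
    #   sigma^2 = (1/n) sum_ik r_ik (x_i - k q)^2 / k
    q <- sum(r * x) / sum(sweep(r, 2, ks, "*"))
    sigma <- sqrt(sum(r * outer(x, ks * q, "-")^2 /
                        matrix(ks, n, K, byrow = TRUE)) / n)
    if (it > 5 && abs(ll - ll0) < tol * abs(ll)) { converged <- TRUE; break }
    ll0 <- ll
  }
  valid <- converged && which.max(w) == 1L
  new("QuantalFit", q = q, weights = as.numeric(w / sum(w)),
      sigma = sigma, gof = -ll, nPuncta = n, method = "em", valid = valid)
}

#' Estimate per-cell mitochondrial DNA copy number
#'
#' Divides each cell's summed punctum intensity by the quantal single-copy
#' intensity from a valid \code{\linkS4class{QuantalFit}}; copy numbers are
#' real-valued and not rounded.
#'
#' @param cellSums numeric vector of per-cell summed punctum intensities
#'   (a.u.), or the data.frame from \code{\link{sumPunctaPerCell}}
#' @param fit a valid \code{\linkS4class{QuantalFit}}
#' @return numeric vector of mCN estimates (or the input data.frame with an
#'   \code{mcn} column appended)
#' @export
estimateMcn <- function(cellSums, fit) {
  stopifnot(is(fit, "QuantalFit"))
  if (!fit@valid)
    stop("quantal fit is invalid; mCN estimation withheld")
  if (is.data.frame(cellSums)) {
    cellSums$mcn <- cellSums$punctaSum / fit@q
    cellSums
  } else cellSums / fit@q
}

#' Normalize values to a reference mean
#'
#' Plate-wise (or batch-wise) normalization: each value is divided by the
#' mean of the reference group, so the reference normalizes to 1 and a value
#' of 0.73 is a 27\% reduction.
#'
#' @param values numeric vector
#' @param referenceMean mean of the reference group (> 0)
#' @return normalized values
#' @export
normalizeToReference <- function(values, referenceMean) {
  if (!is.finite(referenceMean) || referenceMean <= 0)
    stop("reference mean must be positive and finite")
  values / referenceMean
}
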