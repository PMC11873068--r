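#' Fit an exponential growth model to a count series
#'
#' Least-squares fit of the three-parameter model
#' \code{count = c + a * exp(k * t)} (offset model; the pure model fixes
#' \code{c = 0}), with \code{k} initialized from a log-linear regression of
#' the upper half of the series and the fit performed by
#' Levenberg-Marquardt. The doubling time is \code{ln(2)/k}, undefined
#' (NA, with the sign recorded) when \code{k <= 0}. The rate is invariant
#' to time-origin shifts (the amplitude absorbs them).
#'
#' Because the observations are counts, the default weighting is
#' Poisson-motivated (1/count): residuals are scaled by the expected
#' counting noise so early, low-count frames are not drowned out by the
#' high-count tail.
#'
#' With \code{model = "auto"} both models are fitted and the one with the
#' lower BIC (Gaussian approximation on the weighted residuals) is
#' returned: when the series spans too few doublings to identify an
#' additive offset, the criterion falls back to the pure exponential
#' rather than reporting an offset-inflated rate.
#'
#' @param curve data.frame with columns \code{time_h} (strictly increasing)
#'   and \code{count} (>= 0); at least 8 points, not all equal
#' @param model "offset_exponential", "pure_exponential" or "auto"
#' @param weighting "poisson" (1/count weights) or "none"
#' @return a \code{\linkS4class{GrowthFit}}
#' @export
fitGrowth <- function(curve, model = c("offset_exponential",
                                       "pure_exponential", "auto"),
                      weighting = c("poisson", "none")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  if (model == "auto") {
    fo <- fitGrowth(curve, "offset_exponential", weighting)
    fp <- fitGrowth(curve, "pure_exponential", weighting)
    npt <- sum(is.finite(curve$time_h) & is.finite(curve$count))
    bic <- function(f, p) npt * log(f@residualNorm / npt) + p * log(npt)
    return(if (bic(fo, 3) < bic(fp, 2) && fo@converged) fo else fp)
  }
  stopifnot(all(c("time_h", "count") %in% names(curve)))
  t <- curve$time_h; y <- curve$count
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 8) stop("need at least 8 time points")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (stats::sd(y) == 0) stop("counts are all equal; no growth to fit")

  # init: log-linear regression on the tail (offset hardly matters there)
  upper <- t >= stats::median(t)
  yl <- pmax(y[upper], 0.5)
  ini <- stats::lm(log(yl) ~ t[upper])
  k0 <- unname(coef(ini)[2])
  if (!is.finite(k0) || k0 == 0) k0 <- 1e-3
  a0 <- max(exp(unname(coef(ini)[1])), 0.5)
  c0 <- if (model == "offset_exponential") min(y) * 0.25 else 0

  fit <- NULL
  converged <- FALSE
  form <- if (model == "offset_exponential")
    count ~ c + a * exp(k * time_h) else count ~ a * exp(k * time_h)
  start <- if (model == "offset_exponential")
    list(a = a0, k = k0, c = c0) else list(a = a0, k = k0)
  wts <- if (weighting == "poisson") 1 / pmax(y, 1) else rep(1, length(y))
  fit <- try(minpack.lm::nlsLM(form, data = data.frame(time_h = t, count = y),
                               start = start, weights = wts,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (!inherits(fit, "try-error")) {
    converged <- fit$convInfo$isConv %||% TRUE
    cf <- coef(fit)
    a <- unname(cf["a"]); k <- unname(cf["k"])
    cc <- if (model == "offset_exponential") unname(cf["c"]) else 0
    rss <- sum(resid(fit)^2)
  } else {
    a <- a0; k <- k0; cc <- c0
    rss <- sum((y - (cc + a * exp(k * t)))^2)
  }
  tss <- sum((y - mean(y))^2)
  new("GrowthFit", a = a, k = k, c = cc,
      doublingTime = if (k > 0) log(2) / k else NA_real_,
      model = model, residualNorm = rss,
      r2 = 1 - rss / tss,
      converged = converged && !inherits(fit, "try-error"),
      window = range(t))
}

#' Doubling time from a growth rate constant
#'
#' \code{ln(2)/k} in hours; undefined (NA with a warning) for \code{k <= 0}.
#'
#' @param k growth rate constant, 1/h
#' @return doubling time in hours
#' @export
doublingTime <- function(k) {
  out <- ifelse(k > 0, log(2) / k, NA_real_)
  if (any(!is.na(k) & k <= 0))
    warning("doubling time undefined for non-positive growth rate")
  out
}

#' Relative growth of a count series
#'
#' Final count divided by the first-frame count; scale-invariant.
#'
#' @param curve data.frame with columns time_h and count
#' @return final / first ratio
#' @export
relativeGrowth <- function(curve) {
  y <- curve$count[order(curve$time_h)]
  if (y[1] <= 0) stop("first-frame count must be positive")
  y[length(y)] / y[1]
}

#' Rebase a growth curve at a reference time
#'
#' Divides all counts by the (linearly interpolated) count at \code{t0},
#' e.g. the time at which conditioned media was added, so the curve passes
#' through 1 there. An exponential curve rebased anywhere keeps its rate.
#'
#' @param curve data.frame with columns time_h and count
#' @param t0 reference time within the observed range
#' @return the curve with counts normalized to the value at t0
#' @export
rebaseAtTime <- function(curve, t0) {
  t <- curve$time_h
  if (t0 < min(t) || t0 > max(t)) stop("t0 outside the observed time range")
  ref <- stats::approx(t, curve$count, xout = t0)$y
  if (!is.finite(ref) || ref <= 0) stop("count at t0 must be positive")
  curve$count <- curve$count / ref
  curve
}
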