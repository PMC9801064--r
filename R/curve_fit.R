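#' @include AllClasses.R
NULL

# 4PL forward evaluation on raw parameters; f(0) = eMin analytically.
ll4 <- function(x, eMin, eMax, ic50, slope) {
  y <- rep(eMin, length(x))
  pos <- x > 0
  if (any(pos)) {
    lu <- slope * (log(x[pos]) - log(ic50))
    # guard exp overflow: u/(1+u) -> 1 for large u
    frac <- ifelse(lu > 500, 1, ifelse(lu < -500, 0, {
      u <- exp(pmin(lu, 500)); u / (1 + u)
    }))
    y[pos] <- eMin + (eMax - eMin) * frac
  }
  y
}

#' Evaluate a fitted log-logistic curve
#'
#' @param curve a \linkS4class{LogLogisticCurve}.
#' @param x dose(s), >= 0; \code{llForward(curve, 0)} returns \code{eMin}.
#' @return predicted response fraction(s).
#' @seealso \code{\link{fitLogLogistic}}, \code{\link{llInverse}}
#' @export
llForward <- function(curve, x) {
  stopifnot(is(curve, "LogLogisticCurve"))
  if (any(x < 0)) stop("doses must be non-negative")
  if (curve@degenerate) return(rep(curve@eMin, length(x)))
  ll4(x, curve@eMin, curve@eMax, curve@ic50, curve@slope)
}

#' Invert a fitted log-logistic curve
#'
#' Returns the dose at which the curve reaches response \code{y}:
#' \eqn{m (t/(1-t))^{1/\lambda}} with \eqn{t = (y - E_{min})/(E_{max}-E_{min})}
#' for \eqn{y} strictly inside \eqn{(E_{min}, E_{max})}; 0 for
#' \eqn{y \le E_{min}} and \code{Inf} for \eqn{y \ge E_{max}} (one-sided
#' limits).
#'
#' @param curve a non-degenerate increasing \linkS4class{LogLogisticCurve}.
#' @param y response fraction(s).
#' @return dose(s).
#' @export
llInverse <- function(curve, y) {
  stopifnot(is(curve, "LogLogisticCurve"))
  if (curve@degenerate || curve@eMax <= curve@eMin)
    stop("inverse undefined for a degenerate (flat or non-increasing) curve")
  t <- (y - curve@eMin) / (curve@eMax - curve@eMin)
  out <- numeric(length(y))
  out[t <= 0] <- 0
  out[t >= 1] <- Inf
  mid <- t > 0 & t < 1
  out[mid] <- curve@ic50 * (t[mid] / (1 - t[mid]))^(1 / curve@slope)
  out
}

flatCurve <- function(value, ic50 = 1, slopeLo = 1e-3, n = 0L,
                      converged = TRUE) {
  new("LogLogisticCurve", eMin = value, eMax = value, ic50 = ic50,
      slope = slopeLo, rss = 0, nPoints = as.integer(n),
      converged = converged, degenerate = TRUE)
}

#' Fit the four-parameter log-logistic dose-response model
#'
#' Least-squares fit of
#' \eqn{f(x) = E_{min} + (E_{max}-E_{min})(x/m)^\lambda / (1+(x/m)^\lambda)}
#' by box-constrained Levenberg-Marquardt (via \pkg{minpack.lm}), with
#' \code{ic50} optimized on the log scale. Dose 0 enters through the limit
#' \eqn{f(0)=E_{min}}. Three slope starts (0.5, 1, 3) are tried and the best
#' residual sum of squares kept; \code{eMin}/\code{eMax} start at the data
#' extremes and \code{ic50} at the dose nearest the half response. Any subset
#' of parameters can be pinned via \code{fixed} (the ZIP conditional fits pin
#' \code{eMin}).
#'
#' Constant responses yield a degenerate flat curve (value = that response,
#' slope at its lower bound). A free fit that lands at \code{eMax < eMin}
#' (data decreasing in dose) is likewise collapsed to a flagged flat curve
#' at the mean response; when \code{eMin} is fixed the inverted fit is
#' returned as-is so conditional antagonism is representable.
#'
#' @param doses numeric vector of doses >= 0, at least 2 distinct values.
#' @param responses numeric vector of response fractions, same length.
#' @param fixed named list pinning any of \code{eMin}, \code{eMax},
#'   \code{ic50}, \code{slope}.
#' @param eBounds length-2 bounds for both asymptotes (default c(0, 1),
#'   inhibition fractions).
#' @param slopeBounds length-2 bounds for the slope (default c(1e-3, 10)).
#' @return a \linkS4class{LogLogisticCurve}.
#' @examples
#' d <- c(0.01, 0.1, 1, 10, 100)
#' y <- d / (1 + d)  # eMin=0, eMax=1, ic50=1, slope=1
#' fitLogLogistic(d, y)
#' @export
fitLogLogistic <- function(doses, responses, fixed = list(),
                           eBounds = c(0, 1), slopeBounds = c(1e-3, 10)) {
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  keep <- is.finite(doses) & is.finite(responses)
  doses <- doses[keep]; responses <- responses[keep]
  if (any(doses < 0)) stop("doses must be non-negative")
  if (length(unique(doses)) < 2L)
    stop("at least 2 distinct doses are required to fit a curve")
  posDoses <- doses[doses > 0]
  mRef <- if (length(posDoses)) exp(mean(log(range(posDoses)))) else 1

  if (diff(range(responses)) < 1e-12) {
    crv <- flatCurve(responses[1], ic50 = mRef, slopeLo = slopeBounds[1],
                     n = length(doses))
    return(crv)
  }

  parNames <- c("eMin", "eMax", "logm", "slope")
  fixedFull <- c(
    eMin = if (!is.null(fixed$eMin)) fixed$eMin else NA_real_,
    eMax = if (!is.null(fixed$eMax)) fixed$eMax else NA_real_,
    logm = if (!is.null(fixed$ic50)) log(fixed$ic50) else NA_real_,
    slope = if (!is.null(fixed$slope)) fixed$slope else NA_real_
  )
  free <- parNames[is.na(fixedFull)]
  lo <- c(eMin = eBounds[1], eMax = eBounds[1],
          logm = log(mRef) - 20, slope = slopeBounds[1])
  hi <- c(eMin = eBounds[2], eMax = eBounds[2],
          logm = log(mRef) + 20, slope = slopeBounds[2])

  resid <- function(p) {
    full <- fixedFull
    full[free] <- p
    responses - ll4(doses, full["eMin"], full["eMax"], exp(full["logm"]),
                    full["slope"])
  }

  clamp <- function(v, a, b) pmin(pmax(v, a), b)
  halfResp <- (min(responses) + max(responses)) / 2
  mInit <- doses[which.min(abs(responses - halfResp))]
  if (mInit <= 0) mInit <- if (length(posDoses)) min(posDoses) else 1
  init0 <- c(eMin = clamp(min(responses), eBounds[1], eBounds[2]),
             eMax = clamp(max(responses), eBounds[1], eBounds[2]),
             logm = clamp(log(mInit), lo["logm"], hi["logm"]),
             slope = 1)

  best <- NULL
  for (s0 in c(0.5, 1, 3)) {
    init <- init0
    init["slope"] <- clamp(s0, slopeBounds[1], slopeBounds[2])
    p0 <- init[free]
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lo[free], upper = hi[free],
                         fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-10, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = ans$par, rss = rss,
                   converged = ans$info %in% 1:4)
  }
  if (is.null(best)) stop("log-logistic fit failed for all starts")

  full <- fixedFull
  full[free] <- best$par
  eMinHat <- unname(full["eMin"]); eMaxHat <- unname(full["eMax"])
  if (eMaxHat < eMinHat && is.na(fixedFull["eMin"]) &&
      is.na(fixedFull["eMax"])) {
    # free fit wants a decreasing curve: not a valid monotherapy model
    return(flatCurve(mean(responses), ic50 = mRef, slopeLo = slopeBounds[1],
                     n = length(doses), converged = FALSE))
  }
  new("LogLogisticCurve",
      eMin = eMinHat, eMax = eMaxHat, ic50 = exp(unname(full["logm"])),
      slope = unname(full["slope"]), rss = best$rss,
      nPoints = length(doses), converged = best$converged,
      degenerate = abs(eMaxHat - eMinHat) < 1e-12)
}
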