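#' @include AllClasses.R AllGenerics.R curve_fit.R data_model.R
NULL

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Reference-model expected responses at one condition
#'
#' \code{expectedHsa} is the highest single agent expectation, the maximum
#' of the constituent monotherapy responses; \code{expectedBliss} is the
#' Bliss independence expectation \eqn{1 - \prod_i (1 - y_i)}, with the
#' monotherapy responses clamped to [0, 1] inside the product (products of
#' out-of-range values corrupt the probabilistic expectation).
#'
#' @param monoResponses numeric vector, the monotherapy response fraction of
#'   each constituent drug at the condition's dose.
#' @return expected response fraction.
#' @export
expectedHsa <- function(monoResponses) {
  if (length(monoResponses) == 0L)
    stop("at least one monotherapy response is required")
  max(monoResponses)
}

#' @rdname expectedHsa
#' @export
expectedBliss <- function(monoResponses) {
  if (length(monoResponses) == 0L)
    stop("at least one monotherapy response is required")
  1 - prod(1 - clamp01(monoResponses))
}

#' Loewe additivity expectation at one dose combination
#'
#' Solves the dose-equivalence (isobole) equation
#' \eqn{\sum_i x_i / f_i^{-1}(y) = 1} for \eqn{y} by bisection over the
#' bracket \eqn{(\max_i E_{min,i}, \min_i E_{max,i})}. Drugs at dose 0 drop
#' out of the sum; a single active drug reduces the equation to
#' \eqn{y = f(x)}; all doses 0 gives \eqn{y = 0}. When the equation has no
#' root inside the bracket the expectation saturates at the nearest bracket
#' edge (\eqn{\min_i E_{max,i}} beyond the upper asymptotes).
#'
#' @param curves list of fitted monotherapy \linkS4class{LogLogisticCurve}s.
#' @param doses numeric vector of doses (same order), >= 0.
#' @param tol bisection tolerance on y.
#' @param maxit maximum bisection iterations.
#' @return expected response fraction, or NA if any active constituent curve
#'   is degenerate.
#' @export
loeweExpectation <- function(curves, doses, tol = 1e-10, maxit = 200L) {
  stopifnot(length(curves) == length(doses))
  act <- doses > 0
  if (!any(act)) return(0)
  cs <- curves[act]; xs <- doses[act]
  if (any(vapply(cs, function(c) c@degenerate || c@eMax <= c@eMin,
                 logical(1))))
    return(NA_real_)
  if (length(cs) == 1L) return(llForward(cs[[1]], xs))
  eMins <- vapply(cs, slot, numeric(1), "eMin")
  eMaxs <- vapply(cs, slot, numeric(1), "eMax")
  lo <- max(eMins) + 1e-9
  hi <- min(eMaxs) - 1e-12
  if (lo >= hi) return(min(eMaxs))
  g <- function(y)
    sum(xs / vapply(cs, llInverse, numeric(1), y = y)) - 1
  if (g(hi) > 0) return(min(eMaxs))   # doses beyond all asymptotes
  if (g(lo) < 0) return(max(eMins))   # floor forced by heterogeneous eMin
  a <- lo; b <- hi
  for (it in seq_len(maxit)) {
    mid <- (a + b) / 2
    if (g(mid) > 0) a <- mid else b <- mid
    if ((b - a) < tol) break
  }
  (a + b) / 2
}

# fit one 4PL per drug from the block's monotherapy rows (incl. the
# untreated control at dose 0)
fitMonotherapyCurves <- function(block, means = conditionMeans(block),
                                 eBounds = c(0, 1)) {
  n <- nDrugs(block)
  keys <- apply(block@grid, 1L, doseKey)
  zeroIdx <- match(doseKey(numeric(n)), keys)
  mIdx <- monoIndex(block)
  lapply(seq_len(n), function(i) {
    doses <- c(0, block@doseLadders[[i]])
    resp <- c(means[zeroIdx], means[mIdx[[i]]])
    ok <- is.finite(resp)
    fitLogLogistic(doses[ok], resp[ok], eBounds = eBounds)
  })
}

# --- ZIP fitted surface, recursive over combination order ---

# index matrix to read/write a line along `axis` with the other axes fixed
lineIdx <- function(k, axis, along, at) {
  idx <- matrix(0L, length(along), k)
  idx[, axis] <- along
  if (k > 1L)
    idx[, -axis] <- matrix(at, nrow = length(along), ncol = k - 1L,
                           byrow = TRUE)
  idx
}

# arr: mean-response array over (ladder+1) dims (index 1 = dose 0);
# returns the ZIP fitted mean response over the all-nonzero sub-grid.
# Conditional 1-D fits along each drug pin eMin at the fitted response of
# the remaining drugs (partner monotherapy fit for 2 drugs; the (k-1)-drug
# ZIP fitted response, recursively, for more).
zipFittedArray <- function(arr, ladders, curves, eBounds = c(0, 1)) {
  k <- length(ladders)
  if (k == 1L)
    return(list(fit = llForward(curves[[1]], ladders[[1]]), fallback = 0L))
  dims <- lengths(ladders)
  acc <- array(0, dim = dims)
  nacc <- array(0L, dim = dims)
  fallback <- 0L
  subFit <- vector("list", k)
  for (i in seq_len(k)) {
    if (k > 2L && is.null(subFit[[i]])) {
      # sub-block with drug i absent (axis i at dose 0)
      idx <- as.matrix(expand.grid(lapply(dim(arr)[-i], seq_len)))
      full <- matrix(1L, nrow(idx), k)
      full[, -i] <- idx
      subArr <- array(arr[full], dim = dim(arr)[-i])
      sf <- zipFittedArray(subArr, ladders[-i], curves[-i], eBounds)
      subFit[[i]] <- sf$fit
      fallback <- fallback + sf$fallback
    }
    partner <- as.matrix(expand.grid(lapply(dims[-i], seq_len)))
    if (nrow(partner) == 0L) next
    for (r in seq_len(nrow(partner))) {
      pidx <- partner[r, ]
      pin <- if (k == 2L) {
        j <- setdiff(seq_len(k), i)
        llForward(curves[[j]], ladders[[j]][pidx])
      } else {
        subFit[[i]][matrix(pidx, 1L)]
      }
      readIdx <- lineIdx(k, i, seq_len(dims[i]) + 1L, pidx + 1L)
      resp <- arr[readIdx]
      writeIdx <- lineIdx(k, i, seq_len(dims[i]), pidx)
      ok <- is.finite(resp)
      vals <- resp  # fallback: observed condition means
      if (is.finite(pin) && sum(ok) >= 2L) {
        crv <- tryCatch(
          fitLogLogistic(ladders[[i]][ok], resp[ok],
                         fixed = list(eMin = pin), eBounds = eBounds),
          error = function(e) NULL)
        if (!is.null(crv)) vals <- llForward(crv, ladders[[i]])
        else fallback <- fallback + 1L
      } else fallback <- fallback + 1L
      hasVal <- is.finite(vals)
      acc[writeIdx[hasVal, , drop = FALSE]] <-
        acc[writeIdx[hasVal, , drop = FALSE]] + vals[hasVal]
      nacc[writeIdx[hasVal, , drop = FALSE]] <-
        nacc[writeIdx[hasVal, , drop = FALSE]] + 1L
    }
  }
  fit <- acc / k
  fit[nacc < k] <- NA_real_  # a cell missed by any axis is undefined
  list(fit = fit, fallback = fallback)
}

# score all combination (all-nonzero) conditions from a per-condition mean
# response vector; used both for the observed surface and for bootstrap
# resamples ("curve fitting over the whole dose matrix" per resample)
scoreCore <- function(block, means, models, eBounds = c(0, 1),
                      warn = TRUE) {
  n <- nDrugs(block)
  comb <- combinationIdx(block)
  mIdx <- monoIndex(block)
  # ladder position of each combination condition per drug
  rankIdx <- vapply(seq_len(n), function(j)
    match(block@grid[comb, j], block@doseLadders[[j]]), integer(length(comb)))
  rankIdx <- matrix(rankIdx, ncol = n)
  monoMat <- vapply(seq_len(n), function(j)
    means[mIdx[[j]]][rankIdx[, j]], numeric(length(comb)))
  monoMat <- matrix(monoMat, ncol = n)
  if (anyNA(monoMat)) {
    bad <- which(is.na(monoMat), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "monotherapy condition missing for drug '%s' at dose %g",
      block@drugNames[bad[2]],
      block@doseLadders[[bad[2]]][rankIdx[bad[1], bad[2]]]))
  }
  obs <- means[comb]
  d <- as.data.frame(block@grid[comb, , drop = FALSE])
  colnames(d) <- block@drugNames
  d$observed <- obs

  needCurves <- any(c("loewe", "zip") %in% models)
  curves <- if (needCurves) fitMonotherapyCurves(block, means, eBounds)
            else list()
  zipFallback <- 0L

  if ("hsa" %in% models) {
    d$yHsa <- apply(monoMat, 1L, max)
    d$sHsa <- (obs - d$yHsa) * 100
  }
  if ("bliss" %in% models) {
    d$yBliss <- 1 - apply(1 - clamp01(monoMat), 1L, prod)
    d$sBliss <- (obs - d$yBliss) * 100
  }
  if ("loewe" %in% models) {
    anyDegen <- any(vapply(curves, function(c)
      c@degenerate || c@eMax <= c@eMin, logical(1)))
    if (anyDegen) {
      if (warn)
        warning(sprintf(
          "block '%s': a monotherapy curve is degenerate; LOEWE undefined",
          block@blockId))
      d$yLoewe <- NA_real_
    } else {
      d$yLoewe <- vapply(seq_along(comb), function(r)
        loeweExpectation(curves, block@grid[comb[r], ]), numeric(1))
    }
    d$sLoewe <- (obs - d$yLoewe) * 100
  }
  if ("zip" %in% models) {
    arr <- meanArray(block, means)
    zf <- zipFittedArray(arr, block@doseLadders, curves, eBounds)
    zipFallback <- zf$fallback
    fitted <- zf$fit[rankIdx]
    d$fitted <- fitted
    fmono <- vapply(seq_len(n), function(j)
      llForward(curves[[j]], block@doseLadders[[j]])[rankIdx[, j]],
      numeric(length(comb)))
    fmono <- matrix(fmono, ncol = n)
    d$yZip <- 1 - apply(1 - clamp01(fmono), 1L, prod)
    d$sZip <- (fitted - d$yZip) * 100
  }
  list(data = d, curves = curves, zipFallback = zipFallback)
}

#' Score a combination block against the four synergy reference models
#'
#' Computes, at every all-nonzero dose condition, the expected response of
#' the selected reference models and the synergy score
#' \eqn{S = (y - y_{model}) \times 100} in percentage points, where \eqn{y}
#' is the observed condition mean (HSA, BLISS, LOEWE) or the ZIP-fitted mean
#' response \eqn{\hat y_c = \frac1n \sum_i f'_i(x_i)} (ZIP). Monotherapy
#' responses enter HSA/BLISS as observed condition means; LOEWE and ZIP use
#' 4PL monotherapy fits (\code{\link{fitLogLogistic}}). Block-average scores
#' are unweighted means over all combination conditions; conditions missing
#' from ragged grids propagate NA and are excluded from the averages.
#'
#' @param block a \linkS4class{CombinationBlock} (viability blocks are
#'   normalized to inhibition first).
#' @param models subset of \code{c("hsa", "bliss", "loewe", "zip")}.
#' @param eBounds asymptote bounds passed to the curve fits.
#' @return a \linkS4class{SynergySurface}.
#' @examples
#' spec <- generatorSpec(nDrugs = 2, interaction = "none_bliss")
#' blk <- generateBlock(spec)$block
#' surf <- scoreSurface(blk, models = c("hsa", "bliss"))
#' blockSummary(surf)
#' @export
scoreSurface <- function(block, models = c("hsa", "bliss", "loewe", "zip"),
                         eBounds = c(0, 1)) {
  stopifnot(is(block, "CombinationBlock"))
  models <- match.arg(tolower(models), c("hsa", "bliss", "loewe", "zip"),
                      several.ok = TRUE)
  if (block@responseScale != "inhibition") block <- normalizeResponse(block)
  core <- scoreCore(block, conditionMeans(block), models, eBounds)
  scoreCols <- paste0("s", toupper(substring(models, 1, 1)),
                      substring(models, 2))
  avg <- vapply(scoreCols, function(cn) mean(core$data[[cn]], na.rm = TRUE),
                numeric(1))
  names(avg) <- models
  new("SynergySurface", blockId = block@blockId,
      drugNames = block@drugNames, data = core$data, summary = avg,
      curves = core$curves, models = models)
}

#' Synergy barometer at one dose condition
#'
#' Places the observed combination response and the expected responses of
#' all computed models on the common percent-inhibition scale. The reading
#' is "synergistic" when the observed response exceeds every model
#' expectation, "antagonistic" when it falls below every expectation, and
#' "mixed" otherwise.
#'
#' @param surface a \linkS4class{SynergySurface}.
#' @param doses numeric vector of the condition's doses (one per drug, all
#'   nonzero, on the block's grid).
#' @return a \linkS4class{BarometerReading}.
#' @export
barometer <- function(surface, doses) {
  stopifnot(is(surface, "SynergySurface"))
  n <- length(surface@drugNames)
  if (length(doses) != n)
    stop(sprintf("expected %d doses, got %d", n, length(doses)))
  gridKeys <- apply(as.matrix(surface@data[, seq_len(n), drop = FALSE]),
                    1L, doseKey)
  row <- match(doseKey(as.numeric(doses)), gridKeys)
  if (is.na(row))
    stop(sprintf("condition (%s) is not on the block's combination grid",
                 paste(doses, collapse = ", ")))
  cap <- paste0("y", toupper(substring(surface@models, 1, 1)),
                substring(surface@models, 2))
  expected <- vapply(cap, function(cn) surface@data[[cn]][row] * 100,
                     numeric(1))
  names(expected) <- toupper(surface@models)
  expected <- sort(expected)
  observed <- surface@data$observed[row] * 100
  consensus <- if (all(is.finite(expected)) && observed > max(expected))
    "synergistic"
  else if (all(is.finite(expected)) && observed < min(expected))
    "antagonistic"
  else "mixed"
  new("BarometerReading",
      doses = stats::setNames(as.numeric(doses), surface@drugNames),
      observed = observed, expected = expected, consensus = consensus)
}
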