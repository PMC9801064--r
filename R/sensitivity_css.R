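#' @include AllClasses.R AllGenerics.R curve_fit.R data_model.R synergy_models.R
NULL

# log10-linear interpolation weight of `target` between bracketing nonzero
# ladder doses; returns list(lo, hi, w) with value = (1-w)*lo + w*hi,
# clamped to the ladder ends (flagged by the caller when far outside)
bracketLog10 <- function(ladder, target) {
  if (target <= ladder[1]) return(list(lo = 1L, hi = 1L, w = 0))
  k <- length(ladder)
  if (target >= ladder[k]) return(list(lo = k, hi = k, w = 0))
  hi <- findInterval(target, ladder, rightmost.closed = TRUE) + 1L
  lo <- hi - 1L
  w <- (log10(target) - log10(ladder[lo])) /
       (log10(ladder[hi]) - log10(ladder[lo]))
  list(lo = lo, hi = hi, w = w)
}

# slice the mean-response array along drug i with every partner fixed at
# its IC50 (log-linear interpolation between bracketing tested doses);
# returns responses over c(0, ladder_i)
ic50Slice <- function(arr, ladders, curves, i) {
  k <- length(ladders)
  sl <- arr
  dimsLeft <- seq_len(k)
  for (j in rev(setdiff(seq_len(k), i))) {
    lad <- ladders[[j]]
    br <- bracketLog10(lad, curves[[j]]@ic50)
    ax <- match(j, dimsLeft)
    loArr <- sliceAxis(sl, ax, br$lo + 1L)  # +1: index 1 is dose 0
    hiArr <- sliceAxis(sl, ax, br$hi + 1L)
    sl <- (1 - br$w) * loArr + br$w * hiArr
    dimsLeft <- dimsLeft[-ax]
  }
  as.numeric(sl)
}

# drop `axis` of an array by fixing it at `at`
sliceAxis <- function(arr, axis, at) {
  d <- dim(arr)
  if (is.null(d)) return(arr[at])
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- at
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  newDim <- d[-axis]
  if (length(newDim) == 0L) as.numeric(out)
  else array(out, dim = newDim)
}

#' Combination sensitivity score (CSS)
#'
#' Summarizes the overall efficacy of a combination on the percent-inhibition
#' scale: for each drug \eqn{i}, the partner drugs are fixed at their fitted
#' IC50 doses (interpolating the combination response between the bracketing
#' tested partner doses, linear in log10 dose), a 4PL curve is fitted to the
#' resulting one-dimensional combination response along drug \eqn{i}, and
#' \deqn{CSS_i = 100 \frac{\int f \, d\log_{10}x}{\log_{10}x_{max} -
#'   \log_{10}x_{min}}}
#' integrates that curve over drug \eqn{i}'s nonzero tested range. The block
#' CSS is the mean of the per-drug scores. Defined for two-drug blocks; for
#' higher orders all partners are fixed at their IC50s simultaneously
#' (experimental, flagged in the result).
#'
#' A partner IC50 falling outside its tested range is evaluated at the
#' nearest tested dose; more than one log10 unit outside is flagged
#' \code{extrapolated}.
#'
#' @param block a \linkS4class{CombinationBlock} on the inhibition scale.
#' @param eBounds asymptote bounds for the curve fits.
#' @return list with \code{css} (percent), \code{cssPerDrug} (named),
#'   \code{curves} (monotherapy fits) and \code{flags}.
#' @examples
#' spec <- generatorSpec(nDrugs = 2, interaction = "none_bliss")
#' blk <- generateBlock(spec)$block
#' cssScore(blk)$css
#' @export
cssScore <- function(block, eBounds = c(0, 1)) {
  stopifnot(is(block, "CombinationBlock"))
  if (block@responseScale != "inhibition") block <- normalizeResponse(block)
  n <- nDrugs(block)
  if (n < 2L) stop("CSS requires a combination of at least 2 drugs")
  flags <- character(0)
  if (n > 2L) flags <- c(flags, "experimental_high_order")
  curves <- fitMonotherapyCurves(block, eBounds = eBounds)
  arr <- meanArray(block)
  perDrug <- numeric(n)
  for (i in seq_len(n)) {
    for (j in setdiff(seq_len(n), i)) {
      lad <- block@doseLadders[[j]]
      ic <- curves[[j]]@ic50
      if (ic < lad[1] / 10 || ic > lad[length(lad)] * 10)
        flags <- c(flags, sprintf("extrapolated_%s", block@drugNames[j]))
    }
    resp <- ic50Slice(arr, block@doseLadders, curves, i)
    ladder <- block@doseLadders[[i]]
    doses <- c(0, ladder)
    ok <- is.finite(resp)
    if (sum(ok) < 2L)
      stop(sprintf("too few responses along '%s' to fit the CSS curve",
                   block@drugNames[i]))
    crv <- fitLogLogistic(doses[ok], resp[ok], eBounds = eBounds)
    lo <- log10(ladder[1]); hi <- log10(ladder[length(ladder)])
    auc <- stats::integrate(function(t) llForward(crv, 10^t), lo, hi,
                            rel.tol = 1e-8, abs.tol = 1e-10,
                            subdivisions = 500L)$value
    perDrug[i] <- 100 * auc / (hi - lo)
  }
  names(perDrug) <- block@drugNames
  list(css = mean(perDrug), cssPerDrug = perDrug, curves = curves,
       flags = unique(flags))
}

#' Synergy-sensitivity (SS) plot points
#'
#' One point per block: the combination sensitivity score (x axis,
#' efficacy) against the block-average synergy score of the chosen model
#' (y axis, interaction). Blocks are ranked by \code{css + synergy}
#' descending, so the "top-right corner" - effective and synergistic
#' combinations - ranks first. Blocks whose chosen score is undefined
#' (e.g. LOEWE with a degenerate monotherapy) are omitted with a warning.
#'
#' @param blocks list of \linkS4class{CombinationBlock}.
#' @param model synergy model for the y axis (default "zip").
#' @param surfaces optional pre-computed \linkS4class{SynergySurface} list
#'   (matched by position); computed when absent.
#' @return data.frame with \code{block_id}, \code{drugs}, \code{css},
#'   \code{synergy}, \code{rank}.
#' @export
ssPoints <- function(blocks, model = "zip", surfaces = NULL) {
  model <- match.arg(tolower(model), c("hsa", "bliss", "loewe", "zip"))
  if (length(blocks) == 0L)
    return(data.frame(block_id = character(), drugs = character(),
                      css = numeric(), synergy = numeric(),
                      rank = integer()))
  rows <- list()
  for (k in seq_along(blocks)) {
    blk <- blocks[[k]]
    surf <- if (!is.null(surfaces) && model %in% surfaces[[k]]@models)
      surfaces[[k]]
    else scoreSurface(blk, models = model)
    syn <- blockSummary(surf)[[model]]
    if (!is.finite(syn)) {
      warning(sprintf("block '%s': %s score undefined, point omitted",
                      blockId(blk), toupper(model)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = blockId(blk),
      drugs = paste(drugNames(blk), collapse = "+"),
      css = cssScore(blk)$css, synergy = syn,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(block_id = character(), drugs = character(),
                      css = numeric(), synergy = numeric(),
                      rank = integer()))
  out$rank <- rank(-(out$css + out$synergy), ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}
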