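#' @include AllClasses.R AllGenerics.R curve_fit.R data_model.R
NULL

utils::globalVariables(c("x", "y", "value", "model"))

#' Build a synthetic-block generator specification
#'
#' Defaults emulate a typical two-drug screen: 5-point dose ladders spanning
#' four log10 units around the IC50 (0.01-100, IC50 = 1, unit slope, full
#' efficacy), one replicate, no noise. The triple-combination shape of
#' matrix-portal screens is obtained with \code{nDrugs = 3} and ladders of
#' lengths 10, 10, 12; the replicated two-drug shape with
#' \code{replicates = 4}.
#'
#' @param nDrugs number of drugs (>= 1).
#' @param curves list of per-drug parameter lists
#'   (\code{eMin}, \code{eMax}, \code{ic50}, \code{slope}); a single list is
#'   recycled. Default: eMin 0, eMax 1, ic50 1, slope 1.
#' @param ladders list of per-drug nonzero dose ladders; a single vector is
#'   recycled. Default: \code{10^seq(-2, 2)}.
#' @param interaction interaction model (see \linkS4class{GeneratorSpec}).
#' @param delta interaction magnitude on the response-fraction scale.
#' @param window for \code{dose_window_boost}: list of per-drug integer rank
#'   vectors where the boost applies; default the top two ranks of each
#'   drug.
#' @param noiseSd additive Gaussian noise SD on the inhibition fraction.
#' @param replicates replicates per condition.
#' @param blockId block label.
#' @return a \linkS4class{GeneratorSpec}.
#' @export
generatorSpec <- function(nDrugs = 2L,
                          curves = list(list(eMin = 0, eMax = 1, ic50 = 1,
                                             slope = 1)),
                          ladders = list(10^seq(-2, 2)),
                          interaction = "none_bliss", delta = 0,
                          window = NULL, noiseSd = 0, replicates = 1L,
                          blockId = "sim") {
  nDrugs <- as.integer(nDrugs)
  if (!is.null(names(curves)) || !is.list(curves[[1]]))
    curves <- list(curves)
  if (length(curves) == 1L) curves <- rep(curves, nDrugs)
  if (!is.list(ladders)) ladders <- list(ladders)
  if (length(ladders) == 1L) ladders <- rep(ladders, nDrugs)
  if (is.null(window))
    window <- lapply(ladders, function(l)
      seq_len(length(l))[-seq_len(max(0L, length(l) - 2L))])
  new("GeneratorSpec", nDrugs = nDrugs, curves = curves, ladders = ladders,
      interaction = interaction, delta = delta, window = window,
      noiseSd = noiseSd, replicates = as.integer(replicates),
      blockId = blockId)
}

specCurves <- function(spec) {
  lapply(spec@curves, function(p)
    new("LogLogisticCurve", eMin = p$eMin, eMax = p$eMax, ic50 = p$ic50,
        slope = p$slope, degenerate = abs(p$eMax - p$eMin) < 1e-12))
}

# noiseless surface value and ground-truth scores at one condition
truthAt <- function(spec, doses, curves, shiftedCurves) {
  act <- doses > 0
  mono <- vapply(seq_along(doses), function(i)
    llForward(curves[[i]], doses[i]), numeric(1))
  blissExp <- 1 - prod(1 - clamp01(mono))
  hsaExp <- max(mono)
  interior <- sum(act) == length(doses) && length(doses) > 1L
  base <- switch(spec@interaction,
    none_hsa = hsaExp,
    none_bliss = blissExp,
    none_loewe_sham = llForward(curves[[1]], sum(doses)),
    potency_shift = if (interior) {
      sm <- vapply(seq_along(doses), function(i)
        llForward(shiftedCurves[[i]], doses[i]), numeric(1))
      1 - prod(1 - clamp01(sm))
    } else blissExp,
    dose_window_boost = blissExp
  )
  boost <- 0
  if (spec@interaction == "dose_window_boost" && interior) {
    inWin <- all(vapply(seq_along(doses), function(i) {
      r <- match(doses[i], spec@ladders[[i]])
      r %in% spec@window[[i]]
    }, logical(1)))
    if (inWin) boost <- spec@delta
  }
  y <- base + boost
  # ground-truth score of the generator's own null (percentage points)
  sTruth <- switch(spec@interaction,
    none_hsa = (y - hsaExp) * 100,
    none_bliss = (y - blissExp) * 100,
    dose_window_boost = (y - blissExp) * 100,
    none_loewe_sham = 0,
    potency_shift = NA_real_
  )
  list(y = y, sTruth = if (interior) sTruth else NA_real_)
}

#' Generate a synthetic combination block with known ground truth
#'
#' Builds the full-factorial grid over the spec's ladders (plus dose 0),
#' evaluates the noiseless baseline surface of the chosen interaction model,
#' applies the interaction term, and adds per-replicate Gaussian noise.
#' Monotherapy rows follow the spec curves exactly at zero noise.
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @param seed optional integer seed (uses the current RNG stream when
#'   NULL, so \code{\link{generateStudy}} can drive many blocks from one
#'   stream).
#' @return list with \code{block} (a \linkS4class{CombinationBlock}) and
#'   \code{truth}, a data.frame of per-condition noiseless responses and
#'   ground-truth scores (NA where the generator defines none, e.g. edge
#'   conditions and the potency_shift model).
#' @export
generateBlock <- function(spec, seed = NULL) {
  stopifnot(is(spec, "GeneratorSpec"))
  if (spec@interaction == "none_loewe_sham") {
    p1 <- spec@curves[[1]]
    same <- all(vapply(spec@curves, function(p)
      isTRUE(all.equal(unlist(p[c("eMin", "eMax", "ic50", "slope")]),
                       unlist(p1[c("eMin", "eMax", "ic50", "slope")]))),
      logical(1)))
    if (!same)
      stop("none_loewe_sham requires all drugs to share one curve")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  curves <- specCurves(spec)
  shifted <- lapply(spec@curves, function(p)
    new("LogLogisticCurve", eMin = p$eMin, eMax = p$eMax,
        ic50 = p$ic50 / 2, slope = p$slope))
  grid <- fullGrid(spec@ladders)
  truthY <- numeric(nrow(grid))
  truthS <- numeric(nrow(grid))
  responses <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- truthAt(spec, grid[i, ], curves, shifted)
    truthY[i] <- tr$y
    truthS[i] <- tr$sTruth
    responses[[i]] <- tr$y +
      if (spec@noiseSd > 0) stats::rnorm(spec@replicates, 0, spec@noiseSd)
      else numeric(spec@replicates)
  }
  names(responses) <- apply(grid, 1L, doseKey)
  block <- newBlock(spec@blockId,
                    paste0("drug", seq_len(spec@nDrugs)),
                    spec@ladders, rep("uM", spec@nDrugs), responses)
  truth <- as.data.frame(grid)
  colnames(truth) <- paste0("drug", seq_len(spec@nDrugs))
  truth$response <- truthY
  truth$sTruth <- truthS
  list(block = block, truth = truth)
}

#' Generate a reproducible battery of synthetic blocks
#'
#' Seeds the RNG once and draws \code{count} blocks from one stream, so a
#' fixed seed reproduces the whole battery and different seeds share the
#' design but not the noise. Used for calibration suites (e.g. type-I error
#' checks on null generators).
#'
#' @param count number of blocks (>= 1).
#' @param spec a \linkS4class{GeneratorSpec} applied to every block.
#' @param seed integer seed for the battery.
#' @return list of \code{\link{generateBlock}} results; block ids are
#'   suffixed \code{_1.._count}.
#' @export
generateStudy <- function(count, spec, seed = NULL) {
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(count), function(k) {
    sp <- spec
    sp@blockId <- sprintf("%s_%d", spec@blockId, k)
    generateBlock(sp)
  })
}
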