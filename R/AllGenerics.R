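#' @include AllClasses.R
NULL

#' Accessors for combination blocks and derived objects
#'
#' @param object a \linkS4class{CombinationBlock}, \linkS4class{SynergySurface},
#'   or other package object.
#' @return \code{blockId}: the block label. \code{drugNames}: character vector
#'   of drug names. \code{nDrugs}: number of drugs. \code{doseLadders}: list of
#'   per-drug nonzero dose ladders. \code{conditionGrid}: numeric matrix of
#'   grid conditions (columns named by drug). \code{responseList}: list of
#'   replicate response vectors per condition. \code{conditionMeans}: numeric
#'   vector of per-condition mean responses (fractions).
#' @name accessors
#' @aliases blockId drugNames nDrugs doseLadders conditionGrid responseList
#'   conditionMeans
NULL

#' @rdname accessors
#' @export
setGeneric("blockId", function(object) standardGeneric("blockId"))
#' @rdname accessors
#' @export
setGeneric("drugNames", function(object) standardGeneric("drugNames"))
#' @rdname accessors
#' @export
setGeneric("nDrugs", function(object) standardGeneric("nDrugs"))
#' @rdname accessors
#' @export
setGeneric("doseLadders", function(object) standardGeneric("doseLadders"))
#' @rdname accessors
#' @export
setGeneric("conditionGrid", function(object) standardGeneric("conditionGrid"))
#' @rdname accessors
#' @export
setGeneric("responseList", function(object) standardGeneric("responseList"))
#' @rdname accessors
#' @export
setGeneric("conditionMeans", function(object, ...) standardGeneric("conditionMeans"))

#' Synergy scores and block summaries
#'
#' \code{synergyScores} returns the per-condition score table of a
#' \linkS4class{SynergySurface}; \code{blockSummary} the named vector of
#' block-average scores (percentage points).
#'
#' @param object a \linkS4class{SynergySurface}.
#' @name surface-accessors
#' @aliases synergyScores blockSummary
NULL

#' @rdname surface-accessors
#' @export
setGeneric("synergyScores", function(object) standardGeneric("synergyScores"))
#' @rdname surface-accessors
#' @export
setGeneric("blockSummary", function(object) standardGeneric("blockSummary"))

#' @rdname accessors
setMethod("blockId", "CombinationBlock", function(object) object@blockId)
#' @rdname accessors
setMethod("drugNames", "CombinationBlock", function(object) object@drugNames)
#' @rdname accessors
setMethod("nDrugs", "CombinationBlock",
          function(object) length(object@drugNames))
#' @rdname accessors
setMethod("doseLadders", "CombinationBlock",
          function(object) setNames(object@doseLadders, object@drugNames))
#' @rdname accessors
setMethod("conditionGrid", "CombinationBlock", function(object) {
  g <- object@grid
  colnames(g) <- object@drugNames
  g
})
#' @rdname accessors
setMethod("responseList", "CombinationBlock", function(object) object@responses)

#' @rdname accessors
#' @param percent logical, return percent instead of fraction.
#' @param ... passed to methods.
setMethod("conditionMeans", "CombinationBlock",
  function(object, percent = FALSE, ...) {
    m <- vapply(object@responses,
                function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
    if (percent) m * 100 else m
  })

#' @rdname accessors
setMethod("blockId", "SynergySurface", function(object) object@blockId)
#' @rdname accessors
setMethod("drugNames", "SynergySurface", function(object) object@drugNames)
#' @rdname surface-accessors
setMethod("synergyScores", "SynergySurface", function(object) object@data)
#' @rdname surface-accessors
setMethod("blockSummary", "SynergySurface", function(object) object@summary)

setMethod("show", "LogLogisticCurve", function(object) {
  cat(sprintf(
    "LogLogisticCurve: eMin=%.4g eMax=%.4g ic50=%.4g slope=%.4g%s%s\n",
    object@eMin, object@eMax, object@ic50, object@slope,
    if (object@degenerate) " [degenerate]" else "",
    if (!object@converged) " [not converged]" else ""))
})

setMethod("show", "CombinationBlock", function(object) {
  reps <- lengths(object@responses)
  cat(sprintf("CombinationBlock '%s': %d drug(s) [%s]\n", object@blockId,
              nDrugs(object), paste(object@drugNames, collapse = ", ")))
  cat(sprintf("  grid: %d conditions (%s nonzero ladder doses), scale: %s\n",
              nrow(object@grid),
              paste(lengths(object@doseLadders), collapse = " x "),
              object@responseScale))
  cat(sprintf("  replicates per condition: %s%s\n",
              paste(range(reps[reps > 0]), collapse = "-"),
              if (any(reps == 0L)) sprintf(" (%d conditions missing)",
                                           sum(reps == 0L)) else ""))
})

setMethod("show", "SynergySurface", function(object) {
  cat(sprintf("SynergySurface '%s': %d combination conditions\n",
              object@blockId, nrow(object@data)))
  s <- object@summary
  cat("  block-average scores: ",
      paste(sprintf("%s=%.2f", names(s), s), collapse = "  "), "\n", sep = "")
})

setMethod("show", "BarometerReading", function(object) {
  cat(sprintf("BarometerReading at (%s)\n",
              paste(sprintf("%s=%g", names(object@doses), object@doses),
                    collapse = ", ")))
  cat(sprintf("  observed: %.2f%% inhibition, consensus: %s\n",
              object@observed, object@consensus))
  cat("  expected: ",
      paste(sprintf("%s=%.2f", names(object@expected), object@expected),
            collapse = "  "), "\n", sep = "")
})

setMethod("show", "BootstrapSummary", function(object) {
  cat(sprintf(
    "BootstrapSummary [%s]: B=%d, block score %.3f (SE %.3f), z=%.3f, P=%.4g\n",
    object@model, object@B, object@blockMean, object@blockSE, object@z,
    object@p))
})

setMethod("show", "LandscapeLayout", function(object) {
  cat(sprintf("LandscapeLayout '%s': %d points, paint=%s, stress=%.3g\n",
              object@blockId, nrow(object@data), object@valueKind,
              object@stress))
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf(
    "GeneratorSpec: %d drug(s), grid %s, interaction=%s (delta=%g), noise SD=%g, %d replicate(s)\n",
    object@nDrugs, paste(lengths(object@ladders), collapse = " x "),
    object@interaction, object@delta, object@noiseSd, object@replicates))
})
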