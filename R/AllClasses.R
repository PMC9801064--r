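#' @import methods
NULL

#' Four-parameter log-logistic dose-response curve
#'
#' Container for a fitted 4PL model
#' \deqn{f(x) = E_{min} + (E_{max}-E_{min}) \frac{(x/m)^\lambda}{1+(x/m)^\lambda}}
#' where \eqn{E_{min}} and \eqn{E_{max}} are the lower and upper response
#' asymptotes (inhibition fractions), \eqn{m} the half-maximal dose (IC50)
#' and \eqn{\lambda > 0} the slope. \code{f(0) = E_{min}} by the dose-0 limit.
#'
#' Conditional combination fits (used by the ZIP model) pin \code{eMin} and
#' may legitimately fit \code{eMax < eMin} on antagonistic slices; such
#' curves are decreasing and have no inverse. Monotherapy fits collapse that
#' case to a flagged degenerate flat curve instead.
#'
#' @slot eMin lower asymptote, inhibition fraction.
#' @slot eMax upper asymptote, inhibition fraction.
#' @slot ic50 half-maximal dose \eqn{m > 0}, in the drug's dose unit.
#' @slot slope shape parameter \eqn{\lambda > 0}.
#' @slot rss residual sum of squares of the fit.
#' @slot nPoints number of data points fitted.
#' @slot converged logical, optimizer convergence.
#' @slot degenerate logical, TRUE for flat (constant-response) curves.
#' @exportClass LogLogisticCurve
setClass("LogLogisticCurve",
  representation(
    eMin = "numeric", eMax = "numeric", ic50 = "numeric", slope = "numeric",
    rss = "numeric", nPoints = "integer", converged = "logical",
    degenerate = "logical"
  ),
  prototype(
    rss = NA_real_, nPoints = 0L, converged = TRUE, degenerate = FALSE
  ),
  validity = function(object) {
    msg <- character()
    for (s in c("eMin", "eMax", "ic50", "slope")) {
      if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
        msg <- c(msg, sprintf("'%s' must be a single non-missing number", s))
    }
    if (length(msg)) return(msg)
    if (object@ic50 <= 0) msg <- c(msg, "'ic50' must be > 0")
    if (object@slope <= 0) msg <- c(msg, "'slope' must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' One self-contained drug-combination experiment
#'
#' A full-factorial dose-response block: \eqn{n} drugs, each with a sorted
#' ladder of nonzero test doses, measured at every point of the grid formed
#' by each ladder plus dose 0 (the all-zeros condition is the untreated
#' control). Monotherapy conditions of drug \eqn{i} are the grid rows where
#' every other dose is 0. Responses are stored as inhibition (or viability,
#' before \code{\link{normalizeResponse}}) fractions; all model mathematics
#' operates on the inhibition fraction in [0, 1], percentages appear only at
#' input/output boundaries.
#'
#' @slot blockId opaque block label.
#' @slot drugNames character vector of \eqn{n >= 1} drug names, in first
#'   appearance order.
#' @slot doseLadders list of \eqn{n} strictly increasing positive numeric
#'   vectors (nonzero test doses per drug).
#' @slot doseUnits character vector of \eqn{n} concentration units.
#' @slot grid numeric matrix, one row per grid condition, \eqn{n} dose
#'   columns; rows ordered lexicographically (drug 1 slowest).
#' @slot responses list parallel to \code{grid} rows; each element the
#'   numeric replicate responses (fractions) at that condition. Zero-length
#'   elements mark conditions absent from a ragged input.
#' @slot responseScale "inhibition" or "viability".
#' @slot flags list of named diagnostic flags (e.g. out-of-range responses).
#' @exportClass CombinationBlock
setClass("CombinationBlock",
  representation(
    blockId = "character", drugNames = "character", doseLadders = "list",
    doseUnits = "character", grid = "matrix", responses = "list",
    responseScale = "character", flags = "list"
  ),
  prototype(responseScale = "inhibition", flags = list()),
  validity = function(object) {
    n <- length(object@drugNames)
    msg <- character()
    if (n < 1L) msg <- c(msg, "at least one drug is required")
    if (length(object@doseLadders) != n)
      msg <- c(msg, "one dose ladder per drug is required")
    for (i in seq_len(min(n, length(object@doseLadders)))) {
      lad <- object@doseLadders[[i]]
      if (length(lad) == 0L || any(lad <= 0) || is.unsorted(lad, strictly = TRUE))
        msg <- c(msg, sprintf(
          "dose ladder of '%s' must be strictly increasing and positive",
          object@drugNames[i]))
    }
    if (length(object@doseUnits) != n)
      msg <- c(msg, "one dose unit per drug is required")
    if (ncol(object@grid) != n)
      msg <- c(msg, "grid must have one dose column per drug")
    if (length(object@responses) != nrow(object@grid))
      msg <- c(msg, "one response vector per grid condition is required")
    if (!object@responseScale %in% c("inhibition", "viability"))
      msg <- c(msg, "responseScale must be 'inhibition' or 'viability'")
    if (length(msg)) msg else TRUE
  }
)

#' Per-condition synergy surface of a combination block
#'
#' For every all-nonzero dose condition of a block, the observed mean
#' response, the expected response of each reference model (HSA, BLISS,
#' LOEWE, ZIP) and the corresponding synergy score
#' \eqn{S = (y_{used} - y_{model}) \times 100} in percentage points, where
#' \eqn{y_{used}} is the observed condition mean for HSA/BLISS/LOEWE and
#' the ZIP-fitted mean response \eqn{\hat y_c} for ZIP.
#'
#' @slot blockId block label.
#' @slot drugNames drug names.
#' @slot data data.frame: one row per all-nonzero grid condition with dose
#'   columns (named after the drugs), \code{observed}, \code{fitted}
#'   (\eqn{\hat y_c}), \code{yHsa}/\code{yBliss}/\code{yLoewe}/\code{yZip}
#'   expected fractions, and \code{sHsa}/\code{sBliss}/\code{sLoewe}/
#'   \code{sZip} scores (percentage points).
#' @slot summary named numeric: unweighted block-average score per model.
#' @slot curves list of fitted monotherapy \linkS4class{LogLogisticCurve}s.
#' @slot models character, the models actually computed.
#' @exportClass SynergySurface
setClass("SynergySurface",
  representation(
    blockId = "character", drugNames = "character", data = "data.frame",
    summary = "numeric", curves = "list", models = "character"
  )
)

#' Barometer reading at one dose condition
#'
#' Places the observed combination response and the four model expectations
#' on one percent-inhibition scale. Consensus is "synergistic" when the
#' observed response exceeds every expectation, "antagonistic" when it falls
#' below every expectation, otherwise "mixed".
#'
#' @slot doses named numeric, the condition's doses.
#' @slot observed observed response, percent inhibition.
#' @slot expected named numeric, model expectations in percent inhibition,
#'   sorted ascending.
#' @slot consensus "synergistic", "antagonistic" or "mixed".
#' @exportClass BarometerReading
setClass("BarometerReading",
  representation(
    doses = "numeric", observed = "numeric", expected = "numeric",
    consensus = "character"
  )
)

#' Bootstrap summary of synergy scores for one model
#'
#' Dose-level bootstrap mean, standard error and 95\% confidence interval
#' (\eqn{\bar s \pm 1.96\,SE}) for the synergy score, plus the block-level
#' average score, its bootstrap standard error, \eqn{z = |\bar s'|/SE'} and
#' the empirical \eqn{P = \exp(-0.717 z - 0.416 z^2)}.
#'
#' @slot model model label ("hsa", "bliss", "loewe", "zip").
#' @slot conditionStats data.frame: dose columns, \code{mean}, \code{se},
#'   \code{ciLo}, \code{ciHi} per all-nonzero condition (percentage points).
#' @slot blockMean block-level mean synergy score.
#' @slot blockSE bootstrap standard error of the block average.
#' @slot z standardized block score.
#' @slot p empirical P value.
#' @slot B number of bootstrap samples.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot nDropped resamples dropped due to fit failures (LOEWE/ZIP).
#' @exportClass BootstrapSummary
setClass("BootstrapSummary",
  representation(
    model = "character", conditionStats = "data.frame",
    blockMean = "numeric", blockSE = "numeric", z = "numeric", p = "numeric",
    B = "integer", seed = "integer", nDropped = "integer"
  ),
  prototype(seed = NA_integer_, nDropped = 0L)
)

#' Two-dimensional landscape layout of a dose grid
#'
#' Classical multidimensional scaling of per-drug dose-rank vectors into the
#' plane, so synergy or sensitivity values of combinations of any order can
#' be painted as a landscape. Rank 0 denotes dose 0; rank \eqn{k >= 1} the
#' k-th smallest nonzero tested dose of that drug.
#'
#' @slot blockId block label.
#' @slot drugNames drug names.
#' @slot data data.frame: rank columns (\code{rank.<drug>}), dose columns,
#'   embedded coordinates \code{x}, \code{y}, and \code{value} (the painted
#'   quantity; NA where undefined, e.g. scores at zero-dose edges).
#' @slot stress Kruskal stress-1 of the embedding (0 = distances preserved).
#' @slot valueKind one of "score_hsa", "score_bliss", "score_loewe",
#'   "score_zip", "response".
#' @exportClass LandscapeLayout
setClass("LandscapeLayout",
  representation(
    blockId = "character", drugNames = "character", data = "data.frame",
    stress = "numeric", valueKind = "character"
  )
)

#' Synthetic combination-block generator specification
#'
#' Describes a simulated full-factorial experiment: per-drug 4PL curves and
#' dose ladders, the interaction model, its magnitude, measurement noise and
#' replication. The interaction models are: \code{none_hsa} (surface equals
#' the highest single agent), \code{none_bliss} (Bliss product of the
#' monotherapy curves), \code{none_loewe_sham} (all drugs share one curve
#' and the surface is that curve at the summed dose - the sham experiment),
#' \code{potency_shift} (combination cells follow curves with halved IC50,
#' the ZIP-style potency gain) and \code{dose_window_boost} (Bliss baseline
#' plus an additive response boost \code{delta} inside a rank window).
#'
#' @slot nDrugs number of drugs.
#' @slot curves list of per-drug \linkS4class{LogLogisticCurve} parameters.
#' @slot ladders list of per-drug nonzero dose ladders.
#' @slot interaction interaction model name.
#' @slot delta interaction magnitude, response fraction in [-1, 1].
#' @slot window list of per-drug integer rank vectors delimiting where
#'   \code{delta} applies (dose_window_boost only).
#' @slot noiseSd additive Gaussian noise SD on the inhibition fraction.
#' @slot replicates replicates per condition.
#' @slot blockId label of generated blocks.
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  representation(
    nDrugs = "integer", curves = "list", ladders = "list",
    interaction = "character", delta = "numeric", window = "list",
    noiseSd = "numeric", replicates = "integer", blockId = "character"
  ),
  validity = function(object) {
    msg <- character()
    ok <- c("none_hsa", "none_bliss", "none_loewe_sham", "potency_shift",
            "dose_window_boost")
    if (!object@interaction %in% ok)
      msg <- c(msg, paste0("interaction must be one of: ",
                           paste(ok, collapse = ", ")))
    if (abs(object@delta) > 1) msg <- c(msg, "delta must lie in [-1, 1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
    if (length(object@curves) != object@nDrugs ||
        length(object@ladders) != object@nDrugs)
      msg <- c(msg, "one curve and one ladder per drug are required")
    for (lad in object@ladders)
      if (any(lad <= 0) || is.unsorted(lad, strictly = TRUE))
        msg <- c(msg, "ladders must be strictly increasing and positive")
    if (length(msg)) msg else TRUE
  }
)
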