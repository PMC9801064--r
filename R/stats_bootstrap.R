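#' @include AllClasses.R AllGenerics.R synergy_models.R
NULL

#' Empirical P value for a block-average synergy score
#'
#' Standardizes the mean of the supplied score samples against zero and
#' converts \eqn{z = |\bar s'| / SE'} to
#' \eqn{P = \exp(-0.717 z - 0.416 z^2)}, the closed-form approximation to
#' the two-sided normal tail. With \code{mode = "replicates"} the samples
#' are B bootstrap block-average scores and \eqn{SE'} is their (n-1)
#' standard deviation; with \code{mode = "pooled"} (the no-replicate case)
#' the samples are the per-condition scores of the single observed matrix
#' pooled together and \eqn{SE'} is their standard error of the mean.
#'
#' @param scoreSamples numeric vector of score samples (>= 2).
#' @param mode "replicates" or "pooled".
#' @return list with \code{p}, \code{z}, \code{mean}, \code{se} and
#'   \code{flag} ("zero_spread" when the spread collapses).
#' @examples
#' exp(-0.717 * 1.96 - 0.416 * 1.96^2)  # ~0.0496, the alpha = 0.05 landmark
#' @export
empiricalP <- function(scoreSamples, mode = c("replicates", "pooled")) {
  mode <- match.arg(mode)
  s <- scoreSamples[is.finite(scoreSamples)]
  if (length(s) < 2L) stop("at least 2 score samples are required")
  m <- mean(s)
  se <- stats::sd(s)
  if (mode == "pooled") se <- se / sqrt(length(s))
  flag <- NA_character_
  if (se == 0) {
    if (m == 0) return(list(p = 1, z = 0, mean = m, se = 0,
                            flag = "zero_spread"))
    return(list(p = .Machine$double.eps, z = Inf, mean = m, se = 0,
                flag = "zero_spread"))
  }
  z <- abs(m) / se
  p <- min(1, exp(-0.717 * z - 0.416 * z^2))
  list(p = p, z = z, mean = m, se = se, flag = flag)
}

# per-condition replicate mean and SD; single-replicate conditions get
# sigma = 0 (they contribute no resampling noise)
conditionMoments <- function(block) {
  mu <- vapply(block@responses, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  sigma <- vapply(block@responses, function(v)
    if (length(v) > 1L) stats::sd(v) else 0, numeric(1))
  list(mu = mu, sigma = sigma)
}

#' Bootstrap confidence intervals and P values for synergy scores
#'
#' Draws \code{B} bootstrap dose-response matrices, sampling each
#' condition's response from \eqn{N(\mu, \sigma)} with \eqn{\mu, \sigma}
#' the replicate mean and standard deviation (conditions with a single
#' replicate resample with \eqn{\sigma = 0}; sampled responses are not
#' clamped). HSA and BLISS scores are recomputed directly from each
#' resampled matrix; LOEWE and ZIP are recomputed with full curve refitting
#' over the whole matrix per resample. Per condition, the bootstrap mean
#' \eqn{\bar s}, standard error (the (B-1)-denominator standard deviation of
#' the bootstrap scores) and the 95\% confidence interval
#' \eqn{[\bar s - 1.96 SE, \bar s + 1.96 SE]} are reported; at the block
#' level the bootstrap block-average scores yield \eqn{z} and the empirical
#' P of \code{\link{empiricalP}}.
#'
#' Resamples on which the LOEWE/ZIP refit fails are dropped and counted;
#' more than 10\% of \code{B} dropped aborts the model.
#'
#' @param block a \linkS4class{CombinationBlock} with replicate responses.
#' @param models subset of \code{c("hsa", "bliss", "loewe", "zip")}.
#' @param B number of bootstrap samples (>= 2; default 1000).
#' @param seed integer RNG seed; the draw is reproducible under a fixed
#'   seed and the seed is recorded in the summaries.
#' @param eBounds asymptote bounds for curve refits.
#' @return named list of \linkS4class{BootstrapSummary}, one per model.
#' @export
bootstrapSurface <- function(block, models = c("hsa", "bliss"), B = 1000L,
                             seed = NULL, eBounds = c(0, 1)) {
  stopifnot(is(block, "CombinationBlock"))
  models <- match.arg(tolower(models), c("hsa", "bliss", "loewe", "zip"),
                      several.ok = TRUE)
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  if (block@responseScale != "inhibition") block <- normalizeResponse(block)
  if (!is.null(seed)) set.seed(as.integer(seed))

  mom <- conditionMoments(block)
  nCond <- nrow(block@grid)
  comb <- combinationIdx(block)
  n <- nDrugs(block)
  mIdx <- monoIndex(block)
  rankIdx <- matrix(vapply(seq_len(n), function(j)
    match(block@grid[comb, j], block@doseLadders[[j]]),
    integer(length(comb))), ncol = n)

  # one resampled response per condition per bootstrap draw
  Y <- matrix(stats::rnorm(nCond * B, mean = mom$mu, sd = mom$sigma),
              nrow = nCond, ncol = B)

  directModels <- intersect(models, c("hsa", "bliss"))
  fitModels <- intersect(models, c("loewe", "zip"))
  scores <- list()  # per model: nComb x B (dropped resamples = NA column)
  dropped <- stats::setNames(rep(0L, length(models)), models)

  if (length(directModels)) {
    monoRows <- lapply(seq_len(n), function(j) mIdx[[j]][rankIdx[, j]])
    obsY <- Y[comb, , drop = FALSE]
    if ("hsa" %in% directModels) {
      expHsa <- Reduce(pmax, lapply(monoRows, function(r)
        Y[r, , drop = FALSE]))
      scores$hsa <- (obsY - expHsa) * 100
    }
    if ("bliss" %in% directModels) {
      surv <- Reduce(`*`, lapply(monoRows, function(r)
        1 - clamp01(Y[r, , drop = FALSE])))
      scores$bliss <- (obsY - (1 - surv)) * 100
    }
  }

  if (length(fitModels)) {
    for (m in fitModels) scores[[m]] <- matrix(NA_real_, length(comb), B)
    for (b in seq_len(B)) {
      core <- tryCatch(
        scoreCore(block, Y[, b], fitModels, eBounds, warn = FALSE),
        error = function(e) NULL)
      for (m in fitModels) {
        cn <- paste0("s", toupper(substring(m, 1, 1)), substring(m, 2))
        v <- if (is.null(core)) NULL else core$data[[cn]]
        if (is.null(v) || all(!is.finite(v)))
          dropped[m] <- dropped[m] + 1L
        else scores[[m]][, b] <- v
      }
    }
    for (m in fitModels)
      if (dropped[m] >= 0.1 * B)
        stop(sprintf(
          "model '%s': %d of %d bootstrap refits failed (>= 10%%), aborting",
          m, dropped[m], B))
  }

  doseDf <- as.data.frame(block@grid[comb, , drop = FALSE])
  colnames(doseDf) <- block@drugNames
  out <- lapply(models, function(m) {
    S <- scores[[m]]
    condMean <- rowMeans(S, na.rm = TRUE)
    condSE <- apply(S, 1L, stats::sd, na.rm = TRUE)
    cs <- cbind(doseDf,
                data.frame(mean = condMean, se = condSE,
                           ciLo = condMean - 1.96 * condSE,
                           ciHi = condMean + 1.96 * condSE))
    sPrime <- colMeans(S, na.rm = TRUE)
    sPrime <- sPrime[is.finite(sPrime)]
    ep <- empiricalP(sPrime, mode = "replicates")
    new("BootstrapSummary", model = m, conditionStats = cs,
        blockMean = ep$mean, blockSE = ep$se, z = ep$z, p = ep$p,
        B = B, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        nDropped = unname(dropped[m]))
  })
  stats::setNames(out, models)
}

#' Block-level significance without replicates
#'
#' When a matrix has no replicates, the bootstrap CI is unavailable; the
#' block-level P is still obtained by pooling the per-condition synergy
#' scores of the single matrix and comparing their mean to zero
#' (\code{\link{empiricalP}} with \code{mode = "pooled"}).
#'
#' @param surface a \linkS4class{SynergySurface}.
#' @param model one of the surface's models.
#' @return list as \code{\link{empiricalP}}.
#' @export
pooledP <- function(surface, model = "zip") {
  stopifnot(is(surface, "SynergySurface"))
  model <- match.arg(tolower(model), surface@models)
  cn <- paste0("s", toupper(substring(model, 1, 1)), substring(model, 2))
  empiricalP(surface@data[[cn]], mode = "pooled")
}

#' Flat statistics table for a set of bootstrap summaries
#'
#' One row per model and block with the block-level statistics; when two or
#' more blocks are present a Benjamini-Hochberg adjusted P column is added.
#'
#' @param summaryList list (over blocks) of named lists of
#'   \linkS4class{BootstrapSummary} as returned by
#'   \code{\link{bootstrapSurface}}.
#' @param blockIds optional character vector of block labels.
#' @return data.frame.
#' @export
statsTable <- function(summaryList, blockIds = names(summaryList)) {
  if (is.null(blockIds)) blockIds <- as.character(seq_along(summaryList))
  rows <- list()
  for (k in seq_along(summaryList)) {
    for (bs in summaryList[[k]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = blockIds[k], model = toupper(bs@model),
        score = bs@blockMean, se = bs@blockSE, z = bs@z, p = bs@p,
        B = bs@B, dropped = bs@nDropped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (length(unique(out$block_id)) >= 2L)
    out$p_adj <- stats::ave(out$p, out$model,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  out
}
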