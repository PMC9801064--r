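#' @include AllClasses.R AllGenerics.R data_model.R synergy_models.R
NULL

#' Dose-rank vector of a grid condition
#'
#' Each drug's dose is replaced by its rank within that drug's sorted
#' nonzero tested ladder: rank 0 denotes dose 0, rank 1 the smallest
#' nonzero tested dose. A combination (0.1, 10, 1000) nM where 0.1 is drug
#' 1's minimum dose, 10 drug 2's third smallest and 1000 drug 3's sixth has
#' rank vector (1, 3, 6).
#'
#' @param block a \linkS4class{CombinationBlock}.
#' @param doses numeric vector of doses (one per drug) on the block's grid.
#' @return named integer vector of ranks.
#' @export
rankVector <- function(block, doses) {
  stopifnot(is(block, "CombinationBlock"))
  n <- nDrugs(block)
  if (length(doses) != n)
    stop(sprintf("expected %d doses, got %d", n, length(doses)))
  r <- integer(n)
  for (i in seq_len(n)) {
    if (doses[i] == 0) { r[i] <- 0L; next }
    pos <- match(doseKey(doses[i]),
                 vapply(block@doseLadders[[i]], doseKey, character(1)))
    if (is.na(pos))
      stop(sprintf("dose %g is not on the tested ladder of drug '%s'",
                   doses[i], block@drugNames[i]))
    r[i] <- pos
  }
  stats::setNames(r, block@drugNames)
}

# rank matrix for every grid condition (rows aligned with block@grid)
rankMatrix <- function(block) {
  n <- nDrugs(block)
  R <- matrix(0L, nrow(block@grid), n)
  for (j in seq_len(n)) {
    pos <- block@grid[, j] > 0
    R[pos, j] <- match(block@grid[pos, j], block@doseLadders[[j]])
  }
  colnames(R) <- block@drugNames
  R
}

# Kruskal stress-1 between original and embedded distances
stress1 <- function(D0, D1) {
  num <- sum((D0 - D1)^2)
  den <- sum(D0^2)
  if (den == 0) return(0)
  sqrt(num / den)
}

#' Two-dimensional landscape layout by classical MDS of dose ranks
#'
#' Embeds every grid condition (zero-dose edges included, at rank 0) into
#' the plane by classical (Torgerson) multidimensional scaling of the
#' Euclidean distances between dose-rank vectors, and attaches the value to
#' paint: a synergy score (at combination conditions; NA on the edges) or
#' the observed response. For two-drug blocks the rank vectors are already
#' planar, so the embedding is congruent to the rank lattice itself and the
#' reported stress is numerically zero, preserving consistency with classic
#' two-drug heatmaps.
#'
#' The orientation is canonical and deterministic: the embedding is rotated
#' so drug 1's rank gradient points along the first axis (rank increasing
#' rightward) and reflected so drug 2's ranks increase upward.
#'
#' @param block a \linkS4class{CombinationBlock} with >= 3 conditions.
#' @param valueKind one of "score_hsa", "score_bliss", "score_loewe",
#'   "score_zip", "response".
#' @param surface optional pre-computed \linkS4class{SynergySurface}
#'   (required fields are computed on the fly when absent and a score is
#'   requested).
#' @return a \linkS4class{LandscapeLayout}.
#' @export
mdsLayout <- function(block, valueKind = "score_zip", surface = NULL) {
  stopifnot(is(block, "CombinationBlock"))
  valueKind <- match.arg(tolower(valueKind),
                         c("score_hsa", "score_bliss", "score_loewe",
                           "score_zip", "response"))
  R <- rankMatrix(block)
  if (nrow(R) < 3L) stop("at least 3 grid conditions are required")
  if (nrow(unique(R)) == 1L)
    stop("degenerate layout: all rank vectors are identical")

  D0 <- stats::dist(R)
  mds <- stats::cmdscale(D0, k = 2, eig = TRUE)
  X <- mds$points
  if (ncol(X) < 2L) X <- cbind(X, 0)

  # canonical orientation: rotate drug 1's rank gradient onto +x ...
  g1 <- R[, 1] - mean(R[, 1])
  v <- c(sum(X[, 1] * g1), sum(X[, 2] * g1))
  if (sqrt(sum(v^2)) > 1e-12) {
    th <- atan2(v[2], v[1])
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    X <- X %*% rot
  }
  # ... then fix the reflection so drug 2's ranks increase upward
  if (ncol(R) >= 2L) {
    g2 <- R[, 2] - mean(R[, 2])
    if (sum(X[, 2] * g2) < 0) X[, 2] <- -X[, 2]
  }

  D1 <- stats::dist(X)
  vals <- rep(NA_real_, nrow(R))
  if (valueKind == "response") {
    vals <- conditionMeans(block, percent = TRUE)
  } else {
    model <- sub("^score_", "", valueKind)
    if (is.null(surface) || !(model %in% surface@models))
      surface <- scoreSurface(block, models = model)
    cn <- paste0("s", toupper(substring(model, 1, 1)), substring(model, 2))
    comb <- combinationIdx(block)
    sKeys <- apply(as.matrix(
      surface@data[, seq_len(nDrugs(block)), drop = FALSE]), 1L, doseKey)
    gKeys <- apply(block@grid[comb, , drop = FALSE], 1L, doseKey)
    vals[comb] <- surface@data[[cn]][match(gKeys, sKeys)]
  }

  d <- data.frame(R, check.names = FALSE)
  colnames(d) <- paste0("rank.", block@drugNames)
  gd <- as.data.frame(block@grid)
  colnames(gd) <- block@drugNames
  d <- cbind(d, gd)
  d$x <- X[, 1]; d$y <- X[, 2]; d$value <- vals

  new("LandscapeLayout", blockId = block@blockId,
      drugNames = block@drugNames, data = d,
      stress = stress1(as.matrix(D0), as.matrix(D1)),
      valueKind = valueKind)
}

#' Long table for small-multiple bar charts of a dose grid
#'
#' One row per combination condition, ordered lexicographically by rank
#' vector, with the painted value - the data behind a grid of bar plots
#' that localizes the most synergistic (or sensitive) dose region.
#'
#' @param block a \linkS4class{CombinationBlock}.
#' @param valueKind as in \code{\link{mdsLayout}}.
#' @param surface optional pre-computed \linkS4class{SynergySurface}.
#' @return data.frame with rank columns and \code{value}.
#' @export
gridBarplotData <- function(block, valueKind = "score_zip", surface = NULL) {
  stopifnot(is(block, "CombinationBlock"))
  valueKind <- match.arg(tolower(valueKind),
                         c("score_hsa", "score_bliss", "score_loewe",
                           "score_zip", "response"))
  comb <- combinationIdx(block)
  if (length(comb) == 0L) {
    out <- data.frame(matrix(integer(), 0, nDrugs(block)))
    colnames(out) <- paste0("rank.", block@drugNames)
    out$value <- numeric(0)
    return(out)
  }
  R <- rankMatrix(block)[comb, , drop = FALSE]
  vals <- if (valueKind == "response") {
    conditionMeans(block, percent = TRUE)[comb]
  } else {
    model <- sub("^score_", "", valueKind)
    if (is.null(surface) || !(model %in% surface@models))
      surface <- scoreSurface(block, models = model)
    cn <- paste0("s", toupper(substring(model, 1, 1)), substring(model, 2))
    sKeys <- apply(as.matrix(
      surface@data[, seq_len(nDrugs(block)), drop = FALSE]), 1L, doseKey)
    gKeys <- apply(block@grid[comb, , drop = FALSE], 1L, doseKey)
    surface@data[[cn]][match(gKeys, sKeys)]
  }
  ord <- do.call(order, as.data.frame(R))
  out <- data.frame(R[ord, , drop = FALSE], check.names = FALSE)
  colnames(out) <- paste0("rank.", block@drugNames)
  out$value <- vals[ord]
  rownames(out) <- NULL
  out
}

#' Plot a synergy/sensitivity landscape
#'
#' Scatter of the MDS embedding painted by the layout's value, with an
#' optional Gaussian kernel-smoothed raster underneath (bandwidth in rank
#' units; cosmetic only, never fed back into scores). Requires
#' \pkg{ggplot2}.
#'
#' @param layout a \linkS4class{LandscapeLayout}.
#' @param smooth logical, draw the smoothed background raster.
#' @param bandwidth Gaussian kernel bandwidth in rank units.
#' @return a ggplot object.
#' @export
plotLandscape <- function(layout, smooth = TRUE, bandwidth = 0.8) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotLandscape requires the 'ggplot2' package")
  d <- layout@data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = x, y = y))
  dv <- d[is.finite(d$value), , drop = FALSE]
  if (smooth && nrow(dv) >= 3L) {
    gx <- seq(min(d$x), max(d$x), length.out = 60)
    gy <- seq(min(d$y), max(d$y), length.out = 60)
    gridPts <- expand.grid(x = gx, y = gy)
    w <- exp(-(outer(gridPts$x, dv$x, "-")^2 +
               outer(gridPts$y, dv$y, "-")^2) / (2 * bandwidth^2))
    gridPts$value <- as.numeric(w %*% dv$value) / rowSums(w)
    p <- p + ggplot2::geom_raster(
      data = gridPts, ggplot2::aes(fill = value)) +
      ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                    high = "#B2182B", midpoint = 0)
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = value), size = 2) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey70",
                                    high = "#B2182B", midpoint = 0) +
    ggplot2::labs(title = sprintf("%s - %s", layout@blockId,
                                  layout@valueKind),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synergy barometer
#'
#' The observed response as a pointer on the percent-inhibition scale with
#' the four model expectations as labelled marks. Requires \pkg{ggplot2}.
#'
#' @param reading a \linkS4class{BarometerReading}.
#' @return a ggplot object.
#' @export
plotBarometer <- function(reading) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotBarometer requires the 'ggplot2' package")
  marks <- data.frame(model = names(reading@expected),
                      value = unname(reading@expected))
  ggplot2::ggplot(marks, ggplot2::aes(x = 0, y = value)) +
    ggplot2::geom_hline(yintercept = reading@observed, colour = "#B2182B",
                        linewidth = 1) +
    ggplot2::geom_point(shape = 3, size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = model), hjust = -0.4,
                       size = 3) +
    ggplot2::annotate("text", x = 0, y = reading@observed,
                      label = sprintf("observed %.2f%% (%s)",
                                      reading@observed, reading@consensus),
                      vjust = -1, colour = "#B2182B", size = 3) +
    ggplot2::scale_x_continuous(NULL, breaks = NULL, limits = c(-1, 1)) +
    ggplot2::labs(y = "% inhibition") +
    ggplot2::theme_minimal()
}
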