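# three-drug block whose ladders make (0.1, 10, 1000) nM rank as (1, 3, 6)
rankExampleBlock <- function() {
  ladders <- list(c(0.1, 1, 10),
                  c(0.1, 1, 10, 100),
                  c(1, 10, 100, 300, 700, 1000))
  combinationBlock("nM-example", c("d1", "d2", "d3"), ladders,
                   function(d) 0.5, units = rep("nM", 3))
}

test_that("rank vectors index each drug's ladder with 0 for dose 0", {
  blk <- rankExampleBlock()
  expect_equal(unname(rankVector(blk, c(0.1, 10, 1000))), c(1L, 3L, 6L))
  expect_equal(unname(rankVector(blk, c(0.1, 0.1, 1))), c(1L, 1L, 1L))
  expect_equal(unname(rankVector(blk, c(10, 0, 0))), c(3L, 0L, 0L))
  expect_error(rankVector(blk, c(0.2, 10, 1000)), "not on the tested ladder")
})

test_that("two-drug grids embed exactly as their rank lattice", {
  blk <- generateBlock(generatorSpec(nDrugs = 2, curves = asymCurves))$block
  lay <- mdsLayout(blk, valueKind = "response")
  expect_lt(lay@stress, 1e-8)
  d <- lay@data
  # congruence: embedded distances equal rank distances pairwise
  D0 <- dist(d[, c("rank.drug1", "rank.drug2")])
  D1 <- dist(d[, c("x", "y")])
  expect_equal(as.numeric(D1), as.numeric(D0), tolerance = 1e-8)
  # canonical orientation: x tracks drug 1's ranks, y drug 2's
  expect_gt(cor(d$x, d$rank.drug1), 0.999)
  expect_gt(cor(d$y, d$rank.drug2), 0.999)
})

test_that("the 3-drug embedding achieves the spectral optimum", {
  blk <- generateBlock(generatorSpec(
    nDrugs = 3, ladders = list(c(1, 10), c(1, 10), c(1, 10))))$block
  lay <- mdsLayout(blk, valueKind = "response")
  # independent oracle: top-2 eigenprojection of the double-centered
  # squared-distance (Gram) matrix of the {0,1,2}^3 rank lattice
  R <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  D2 <- as.matrix(dist(R))^2
  J <- diag(27) - matrix(1 / 27, 27, 27)
  Gram <- -0.5 * J %*% D2 %*% J
  ev <- eigen(Gram, symmetric = TRUE)
  Xo <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  key <- function(M) apply(M, 1, paste, collapse = "|")
  ord <- match(key(as.matrix(lay@data[, 1:3])), key(R))
  # the embedding must capture exactly the top-2 eigenvalue mass (the
  # spectral optimum of any rank-2 Gram approximation)
  X <- as.matrix(lay@data[, c("x", "y")])
  Xc <- scale(X, scale = FALSE)
  expect_equal(sum(Xc^2), sum(ev$values[1:2]), tolerance = 1e-8)
  # the cube's top eigenvalues are triply degenerate, so the plane chosen
  # inside the tied eigenspace is basis-dependent; distances must still
  # track the oracle projection closely
  corGot <- cor(as.numeric(dist(X)), as.numeric(dist(R)))
  corOra <- cor(as.numeric(dist(Xo[ord, ])), as.numeric(dist(R)))
  expect_gte(corGot, corOra - 0.02)
})

test_that("layouts are invariant to condition order and values ride along", {
  spec <- generatorSpec(nDrugs = 3,
                        ladders = list(c(1, 10), c(2, 20), c(3, 30)),
                        curves = asymCurves[c(1, 2, 1)])
  blk <- generateBlock(spec)$block
  lay <- mdsLayout(blk, valueKind = "score_bliss")
  # permuted block: same conditions in reversed storage order
  perm <- rev(seq_len(nrow(blk@grid)))
  g <- conditionGrid(blk)
  blk2 <- combinationBlock("perm", drugNames(blk), doseLadders(blk),
                           function(d) {
    i <- which(apply(g, 1, function(r) all(r == d)))
    blk@responses[[i]]
  })
  lay2 <- mdsLayout(blk2, valueKind = "score_bliss")
  key <- function(d) apply(d[, 1:3], 1, paste, collapse = "|")
  m <- match(key(lay@data), key(lay2@data))
  expect_equal(lay@data$x, lay2@data$x[m], tolerance = 1e-8)
  expect_equal(lay@data$y, lay2@data$y[m], tolerance = 1e-8)
  expect_equal(lay@data$value, lay2@data$value[m], tolerance = 1e-8)
  # painted scores sit at their own conditions
  surf <- scoreSurface(blk, models = "bliss")
  sc <- synergyScores(surf)
  one <- lay@data[lay@data$drug1 == 1 & lay@data$drug2 == 2 &
                  lay@data$drug3 == 3, ]
  expect_equal(one$value,
               sc$sBliss[sc$drug1 == 1 & sc$drug2 == 2 & sc$drug3 == 3])
  # zero-dose edges carry no score
  expect_true(all(is.na(lay@data$value[lay@data$drug1 == 0])))
})

test_that("degenerate layouts are rejected", {
  blk <- combinationBlock("tiny", "a", list(c(1, 2)),
                          function(d) 0.1 * d[1])
  expect_s4_class(mdsLayout(blk, "response"), "LandscapeLayout")
  expect_error(mdsLayout(combinationBlock("one", "a", list(1),
                                          function(d) 0.5), "response"),
               "at least 3")
})

test_that("bar-grid data is rank-ordered and joins the surface scores", {
  blk <- generateBlock(generatorSpec(
    nDrugs = 2, ladders = list(c(1, 10, 100)), curves = asymCurves))$block
  surf <- scoreSurface(blk, models = "bliss")
  tab <- gridBarplotData(blk, "score_bliss", surf)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab[1, 1:2], data.frame(rank.drug1 = 1L, rank.drug2 = 1L),
               ignore_attr = TRUE)
  expect_equal(tab[9, 1:2], data.frame(rank.drug1 = 3L, rank.drug2 = 3L),
               ignore_attr = TRUE)
  sc <- synergyScores(surf)
  expect_equal(tab$value[tab$rank.drug1 == 2 & tab$rank.drug2 == 3],
               sc$sBliss[sc$drug1 == 10 & sc$drug2 == 100])
  # single-drug block: its nonzero doses are the plotted conditions
  mono <- combinationBlock("m", "a", list(c(1, 10)), function(d) 0.3)
  monoTab <- gridBarplotData(mono, "response")
  expect_equal(monoTab$rank.a, c(1L, 2L))
  expect_equal(monoTab$value, c(30, 30))
})
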