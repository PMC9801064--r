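test_that("HSA and Bliss expectations follow their formulas", {
  expect_equal(expectedHsa(c(0.2, 0.5, 0.3)), 0.5)
  expect_equal(expectedHsa(0.4), 0.4)
  expect_equal(expectedHsa(c(0, 0)), 0)
  expect_error(expectedHsa(numeric(0)), "at least one")
  expect_equal(expectedBliss(c(0.5, 0.5)), 0.75)
  expect_equal(expectedBliss(c(0.5, 0.5, 0.5)), 0.875)
  expect_equal(expectedBliss(c(0, 0, 0)), 0)
  # out-of-range monotherapies are clamped inside the product only
  expect_equal(expectedBliss(c(1.2, 0.5)), 1)
})

test_that("per-condition HSA/Bliss scores match hand results", {
  # three-drug toy block with constant monotherapy plateaus
  plateau <- c(0.2, 0.5, 0.3)
  blk <- combinationBlock("toy", c("a", "b", "c"),
                          list(1, 1, 1), function(d) {
    act <- d > 0
    if (!any(act)) return(0)
    if (sum(act) == 1L) return(plateau[which(act)])
    0.6
  })
  surf <- scoreSurface(blk, models = c("hsa", "bliss"))
  sc <- synergyScores(surf)
  triple <- sc[sc$a > 0 & sc$b > 0 & sc$c > 0, ]
  expect_equal(triple$sHsa, 10)              # 0.6 - 0.5
  expect_equal(triple$sBliss, (0.6 - 0.72) * 100)
})

test_that("the Loewe expectation solves the isobole equation", {
  crv <- new("LogLogisticCurve", eMin = 0, eMax = 1, ic50 = 1, slope = 1)
  # two identical drugs f(x) = x/(x+1): f^-1(0.5) = 1 and 0.5 + 0.5 = 1
  expect_equal(loeweExpectation(list(crv, crv), c(0.5, 0.5)), 0.5,
               tolerance = 1e-9)
  # single active drug: the equation degenerates to y = f(x)
  expect_equal(loeweExpectation(list(crv, crv), c(3, 0)), llForward(crv, 3),
               tolerance = 1e-9)
  expect_equal(loeweExpectation(list(crv, crv), c(0, 0)), 0)
  # residual of the solved equation is ~0 for an asymmetric pair
  crv2 <- new("LogLogisticCurve", eMin = 0, eMax = 0.8, ic50 = 5,
              slope = 1.7)
  y <- loeweExpectation(list(crv, crv2), c(2, 7))
  res <- 2 / llInverse(crv, y) + 7 / llInverse(crv2, y) - 1
  expect_lt(abs(res), 1e-7)
  # beyond all asymptotes the expectation saturates at min(eMax)
  expect_equal(loeweExpectation(list(crv, crv2), c(1e9, 1e9)), 0.8)
  flat <- fitLogLogistic(c(0, 1, 10), rep(0.2, 3))
  expect_true(is.na(loeweExpectation(list(crv, flat), c(1, 1))))
})

test_that("null surfaces score zero under their own model", {
  # HSA null
  gbH <- generateBlock(generatorSpec(nDrugs = 2, curves = asymCurves,
                                     interaction = "none_hsa"))
  sH <- scoreSurface(gbH$block, models = "hsa")
  expect_equal(max(abs(synergyScores(sH)$sHsa)), 0)
  # Bliss null
  gbB <- generateBlock(generatorSpec(nDrugs = 2, curves = asymCurves,
                                     interaction = "none_bliss"))
  sB <- scoreSurface(gbB$block, models = "bliss")
  expect_equal(max(abs(synergyScores(sB)$sBliss)), 0)
  # Loewe sham: one curve split across two "drugs"
  gbL <- generateBlock(generatorSpec(nDrugs = 2,
                                     interaction = "none_loewe_sham"))
  sL <- scoreSurface(gbL$block, models = "loewe")
  expect_lt(max(abs(synergyScores(sL)$sLoewe)), 1e-6)
  # ZIP on a Bliss surface of its own monotherapies
  sZ <- scoreSurface(gbB$block, models = "zip")
  expect_lt(max(abs(synergyScores(sZ)$sZip)), 0.5)
})

test_that("three-drug nulls also score zero (high-order consistency)", {
  spec3 <- generatorSpec(nDrugs = 3, curves = asymCurves[c(1, 2, 1)],
                         ladders = list(c(0.1, 1, 10), c(0.5, 5, 50),
                                        c(0.2, 2, 20)),
                         interaction = "none_bliss")
  gb <- generateBlock(spec3)
  surf <- scoreSurface(gb$block)
  sc <- synergyScores(surf)
  expect_equal(max(abs(sc$sBliss)), 0)
  expect_lt(max(abs(sc$sZip)), 0.5)
  expect_true(all(sc$sHsa >= sc$sBliss - 1e-12))
})

test_that("two-drug scores match the independent brute-force oracle", {
  # non-trivial HSA/BLISS/LOEWE scores: Bliss-null data from two different
  # curves (HSA and LOEWE are then nonzero)
  gb <- generateBlock(generatorSpec(nDrugs = 2, curves = asymCurves,
                                    interaction = "none_bliss"))
  surf <- scoreSurface(gb$block)
  got <- synergyScores(surf)
  ora <- oracleScores2(gb$block)
  key <- function(d) paste(d[[1]], d[[2]])
  m <- match(key(got[, 1:2]), key(ora[, c("x1", "x2")]))
  expect_equal(got$sHsa, ora$sHsa[m], tolerance = 1e-8)
  expect_equal(got$sBliss, ora$sBliss[m], tolerance = 1e-8)
  expect_equal(got$sLoewe, ora$sLoewe[m], tolerance = 1e-4)
  expect_equal(got$sZip, ora$sZip[m], tolerance = 1e-4)
})

test_that("ZIP detects a potency shift as positive synergy", {
  gb <- generateBlock(generatorSpec(nDrugs = 2, interaction = "potency_shift"))
  surf <- scoreSurface(gb$block, models = "zip")
  sc <- synergyScores(surf)
  expect_gt(mean(sc$sZip), 0)
  interior <- sc[sc$drug1 %in% c(0.1, 1) & sc$drug2 %in% c(0.1, 1), ]
  expect_true(all(interior$sZip > 0))
  # and the oracle agrees on the sign and magnitude
  ora <- oracleScores2(gb$block)
  key <- function(a, b) paste(a, b)
  m <- match(key(sc[, 1], sc[, 2]), key(ora$x1, ora$x2))
  expect_equal(sc$sZip, ora$sZip[m], tolerance = 1e-4)
})

test_that("raising one combination response raises its scores strictly", {
  spec <- generatorSpec(nDrugs = 2, curves = asymCurves)
  blk <- generateBlock(spec)$block
  i <- which(blk@grid[, 1] == 1 & blk@grid[, 2] == 1)
  blk2 <- blk
  blk2@responses[[i]] <- blk@responses[[i]] + 0.05
  s1 <- synergyScores(scoreSurface(blk, models = c("hsa", "bliss", "loewe")))
  s2 <- synergyScores(scoreSurface(blk2, models = c("hsa", "bliss", "loewe")))
  r <- which(s1$drug1 == 1 & s1$drug2 == 1)
  expect_gt(s2$sHsa[r], s1$sHsa[r])
  expect_gt(s2$sBliss[r], s1$sBliss[r])
  expect_gt(s2$sLoewe[r], s1$sLoewe[r])
})

test_that("single-drug blocks reduce every model to zero score", {
  blk <- combinationBlock("mono", "a", list(10^(-1:2)),
                          function(d) unname(d[1] / (d[1] + 1)))
  surf <- scoreSurface(blk)
  sc <- synergyScores(surf)
  expect_equal(max(abs(sc$sHsa)), 0)
  expect_equal(max(abs(sc$sBliss)), 0)
  expect_lt(max(abs(sc$sLoewe)), 1e-6)
  expect_lt(max(abs(sc$sZip)), 1e-6)
})

test_that("the barometer reports consensus correctly", {
  gb <- generateBlock(generatorSpec(nDrugs = 2, curves = asymCurves,
                                    interaction = "dose_window_boost",
                                    delta = 0.3))
  surf <- scoreSurface(gb$block)
  lad <- doseLadders(gb$block)
  top <- c(lad$drug1[5], lad$drug2[5])       # inside the boost window
  b <- barometer(surf, top)
  expect_s4_class(b, "BarometerReading")
  expect_equal(b@consensus, "synergistic")
  expect_true(all(diff(b@expected) >= 0))
  expect_true(b@observed > max(b@expected))
  # an antagonistic window
  gb2 <- generateBlock(generatorSpec(nDrugs = 2, curves = asymCurves,
                                     interaction = "dose_window_boost",
                                     delta = -0.3))
  b2 <- barometer(scoreSurface(gb2$block), top)
  expect_equal(b2@consensus, "antagonistic")
  # observed tied with one expectation: mixed
  gbN <- generateBlock(generatorSpec(nDrugs = 2, interaction = "none_hsa"))
  b3 <- barometer(scoreSurface(gbN$block, models = c("hsa", "bliss")),
                  c(1, 1))
  expect_equal(b3@consensus, "mixed")
  expect_error(barometer(surf, c(123, 456)), "not on the block")
})
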