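test_that("a replicated two-drug table parses into one full-factorial block", {
  rows <- twoDrugRows(ladders = list(c(1, 10, 100), c(2, 20, 200)),
                      respFun = function(d) 50, k = 2)
  blocks <- parseCombinationTable(tableText(rows))
  expect_length(blocks, 1L)
  blk <- blocks[["b1"]]
  expect_equal(nrow(conditionGrid(blk)), 16L)           # (3+1)^2
  expect_equal(sum(lengths(responseList(blk))), 32L)    # x2 replicates
  expect_equal(drugNames(blk), c("A", "B"))
  expect_equal(doseLadders(blk)$A, c(1, 10, 100))
  # condition count of a full factorial is prod(ladder + 1)
  rows3 <- twoDrugRows(ladders = list(c(1, 5, 10), 10^(1:4)))
  blk3 <- parseCombinationTable(tableText(rows3))[[1]]
  expect_equal(nrow(conditionGrid(blk3)), prod(c(3, 4) + 1))
})

test_that("empty input and schema problems are reported as such", {
  expect_length(parseCombinationTable("block_id,drug_1,conc_1,response\n"), 0L)
  rows <- twoDrugRows()
  rows$response <- NULL
  expect_error(parseCombinationTable(tableText(rows)), "response")
  noDrug <- data.frame(block_id = "b", conc_9 = 1, response = 5)
  expect_error(parseCombinationTable(tableText(noDrug)), "drug")
})

test_that("duplicate replicate keys and ragged grids are validation errors", {
  rows <- twoDrugRows(k = 2)
  rows$replicate[2] <- 1L  # same condition, same replicate index
  expect_error(parseCombinationTable(tableText(rows)), "duplicate")
  rows2 <- twoDrugRows()
  dropped <- rows2[!(rows2$conc_1 == 10 & rows2$conc_2 == 10), ]
  expect_error(parseCombinationTable(tableText(dropped)),
               "missing condition")
  blk <- parseCombinationTable(tableText(dropped), allowRagged = TRUE)[[1]]
  expect_equal(sum(lengths(responseList(blk)) == 0L), 1L)
  expect_length(blk@flags$missingConditions, 1L)
})

test_that("replicate indices are assigned in row order when absent", {
  rows <- twoDrugRows(k = 3, withReplicateCol = FALSE)
  blk <- parseCombinationTable(tableText(rows))[[1]]
  expect_true(all(lengths(responseList(blk)) == 3L))
})

test_that("SI-prefix dose units are harmonized before condition matching", {
  rows <- twoDrugRows(ladders = list(c(1, 10), c(1, 10)))
  # re-express one measurement of drug A in nM: 10 uM == 10000 nM
  i <- which(rows$conc_1 == 10 & rows$conc_2 == 0)
  rows$conc_1[i] <- 10000; rows$conc_unit_1 <- as.character(rows$conc_unit_1)
  rows$conc_unit_1[i] <- "nM"
  blk <- parseCombinationTable(tableText(rows))[[1]]
  expect_equal(doseLadders(blk)$A, c(1, 10))
  rows$conc_unit_1[i] <- "furlongs"
  expect_error(parseCombinationTable(tableText(rows)), "unit")
})

test_that("the legacy two-drug layout is accepted", {
  rows <- twoDrugRows(ladders = list(c(1, 10), c(1, 10)))
  names(rows)[match(c("drug_1", "drug_2", "conc_1", "conc_2"), names(rows))] <-
    c("drug_row", "drug_col", "conc_r", "conc_c")
  names(rows)[match(c("conc_unit_1", "conc_unit_2"), names(rows))] <-
    c("conc_r_unit", "conc_c_unit")
  blk <- parseCombinationTable(tableText(rows))[[1]]
  expect_equal(nrow(conditionGrid(blk)), 9L)
  expect_equal(drugNames(blk), c("A", "B"))
})

test_that("viability converts to inhibition; out-of-range values are flagged, not clamped", {
  rows <- twoDrugRows(ladders = list(c(1, 10), c(1, 10)),
                      respFun = function(d) if (all(d == 0)) -5 else 40,
                      responseType = "viability")
  blk <- normalizeResponse(parseCombinationTable(tableText(rows))[[1]])
  m <- conditionMeans(blk, percent = TRUE)
  g <- conditionGrid(blk)
  expect_equal(unname(m[g[, 1] == 1 & g[, 2] == 1]), 60)   # 100 - 40
  origin <- which(g[, 1] == 0 & g[, 2] == 0)
  expect_equal(unname(m[origin]), 105)                     # 100 - (-5), kept
  expect_true(origin %in% blk@flags$outOfRange)
  # involution up to scale: converting twice round-trips
  expect_equal(conditionMeans(normalizeResponse(blk)), conditionMeans(blk))
  # mixed response types in one block are rejected
  rows$response_type[3] <- "inhibition"
  expect_error(parseCombinationTable(tableText(rows)), "mixed")
})

test_that("blocks round-trip through write and parse", {
  spec <- generatorSpec(nDrugs = 2, curves = asymCurves,
                        noiseSd = 0.03, replicates = 2)
  blk <- generateBlock(spec, seed = 7)$block
  path <- withr::local_tempfile(fileext = ".csv")
  writeBlockTable(blk, path)
  back <- parseCombinationTable(path)[[1]]
  expect_equal(drugNames(back), drugNames(blk))
  expect_equal(conditionGrid(back), conditionGrid(blk))
  expect_equal(conditionMeans(back), conditionMeans(blk), tolerance = 1e-9)
})

test_that("surface tables write, read back and rewrite byte-identically", {
  spec <- generatorSpec(nDrugs = 2, curves = asymCurves)
  blk <- generateBlock(spec)$block
  surf <- scoreSurface(blk, models = c("hsa", "bliss"))
  expect_equal(nrow(surfaceToTable(surf)), 25L * 2L)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeSurface(surf, p1)
  tab <- readSurfaceTable(p1)
  expect_equal(tab$score[tab$model == "BLISS"],
               synergyScores(surf)$sBliss, tolerance = 1e-9)
  writeSurface(surf, p2)
  expect_identical(readLines(p1), readLines(p2))
})
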