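#' @include AllClasses.R AllGenerics.R
NULL

# canonical exact-match key for a dose tuple (after unit harmonization);
# decimal-string equality, never float tolerance
doseKey <- function(doses) paste(sprintf("%.10g", doses), collapse = "|")

# SI prefix factors relative to nM; dose units within a drug are harmonized
# to the first-seen unit
.unitFactor <- c(pM = 1e-3, nM = 1, uM = 1e3, `µM` = 1e3, mM = 1e6)

unitScale <- function(from, to) {
  if (from == to) return(1)
  if (!(from %in% names(.unitFactor)) || !(to %in% names(.unitFactor)))
    stop(sprintf(
      "cannot convert dose unit '%s' to '%s': only SI prefixes %s are supported",
      from, to, paste(setdiff(names(.unitFactor), "µM"), collapse = "/")))
  unname(.unitFactor[from] / .unitFactor[to])
}

# canonical lexicographic full-factorial grid: drug 1 varies slowest
fullGrid <- function(ladders) {
  levs <- lapply(ladders, function(l) c(0, l))
  g <- as.matrix(rev(expand.grid(rev(levs), KEEP.OUT.ATTRS = FALSE)))
  dimnames(g) <- NULL
  g
}

# assemble a CombinationBlock from a keyed response map
newBlock <- function(blockId, drugNames, ladders, units, responsesByKey,
                     responseScale = "inhibition", allowRagged = FALSE,
                     flags = list()) {
  grid <- fullGrid(ladders)
  keys <- apply(grid, 1L, doseKey)
  responses <- lapply(keys, function(k) {
    v <- responsesByKey[[k]]
    if (is.null(v)) numeric(0) else as.numeric(v)
  })
  missing <- keys[lengths(responses) == 0L]
  if (length(missing) && !allowRagged)
    stop(sprintf(
      "block '%s' is not a full factorial grid: %d missing condition(s): %s",
      blockId, length(missing),
      paste(utils::head(gsub("\\|", " / ", missing), 10), collapse = "; ")))
  extra <- setdiff(names(responsesByKey), keys)
  if (length(extra))
    stop(sprintf("block '%s': conditions off the factorial grid: %s",
                 blockId, paste(utils::head(extra, 10), collapse = "; ")))
  if (length(missing)) flags$missingConditions <- missing
  new("CombinationBlock", blockId = blockId, drugNames = drugNames,
      doseLadders = ladders, doseUnits = units, grid = grid,
      responses = responses, responseScale = responseScale, flags = flags)
}

#' Build a combination block from per-condition responses
#'
#' Constructs a full-factorial \linkS4class{CombinationBlock} from dose
#' ladders and a function (or keyed list) giving replicate responses at each
#' condition. Mostly useful programmatically; delimited files go through
#' \code{\link{parseCombinationTable}}.
#'
#' @param blockId block label.
#' @param drugNames character vector of drug names.
#' @param ladders list of strictly increasing positive dose ladders.
#' @param responseFun function(doses) returning the numeric replicate
#'   response fraction(s) at that condition (doses include zeros).
#' @param units dose unit per drug.
#' @param responseScale "inhibition" (default) or "viability".
#' @return a \linkS4class{CombinationBlock}.
#' @export
combinationBlock <- function(blockId, drugNames, ladders, responseFun,
                             units = rep("uM", length(drugNames)),
                             responseScale = "inhibition") {
  grid <- fullGrid(ladders)
  rs <- lapply(seq_len(nrow(grid)), function(i) responseFun(grid[i, ]))
  names(rs) <- apply(grid, 1L, doseKey)
  newBlock(blockId, drugNames, ladders, units, rs,
           responseScale = responseScale)
}

resolveSchema <- function(columns, schema) {
  # legacy two-drug layout: drug_row/drug_col + conc_r/conc_c
  lookup <- function(canon) {
    if (!is.null(schema[[canon]])) schema[[canon]] else canon
  }
  map <- list()
  if (lookup("drug_row") %in% columns && lookup("drug_col") %in% columns) {
    map$drug <- c(lookup("drug_row"), lookup("drug_col"))
    map$conc <- c(lookup("conc_r"), lookup("conc_c"))
    unitCols <- c(lookup("conc_r_unit"), lookup("conc_c_unit"))
    map$unit <- ifelse(unitCols %in% columns, unitCols, NA_character_)
  } else {
    drugCols <- character(); concCols <- character(); unitCols <- character()
    i <- 1L
    repeat {
      dc <- if (!is.null(schema[[paste0("drug_", i)]]))
        schema[[paste0("drug_", i)]] else paste0("drug_", i)
      if (!dc %in% columns) break
      drugCols <- c(drugCols, dc)
      cc <- if (!is.null(schema[[paste0("conc_", i)]]))
        schema[[paste0("conc_", i)]] else paste0("conc_", i)
      concCols <- c(concCols, cc)
      uc <- if (!is.null(schema[[paste0("conc_unit_", i)]]))
        schema[[paste0("conc_unit_", i)]] else paste0("conc_unit_", i)
      unitCols <- c(unitCols, if (uc %in% columns) uc else NA_character_)
      i <- i + 1L
    }
    map$drug <- drugCols; map$conc <- concCols; map$unit <- unitCols
  }
  map$block_id <- lookup("block_id")
  map$response <- lookup("response")
  map$response_type <- lookup("response_type")
  map$replicate <- lookup("replicate")
  map
}

#' Parse a long-format dose-response table into combination blocks
#'
#' Reads a delimited (CSV/TSV) plate-style table with one row per
#' measurement and returns one full-factorial \linkS4class{CombinationBlock}
#' per block identifier. The expected columns are \code{block_id},
#' \code{drug_1..drug_n}, \code{conc_1..conc_n}, optional
#' \code{conc_unit_1..n}, \code{response} (percent), optional
#' \code{response_type} ("viability"/"inhibition") and optional
#' \code{replicate}; the legacy two-drug layout
#' (\code{drug_row}/\code{drug_col}, \code{conc_r}/\code{conc_c}) is also
#' accepted. Column names can be remapped via \code{schema}.
#'
#' Within a block, drugs are ordered by first appearance, responses are
#' grouped by exact dose tuple (decimal-string equality after harmonizing SI
#' prefix units per drug), and replicate indices are assigned 1..k in row
#' order when the column is absent. A grid condition observed more than once
#' with the same replicate index, or a grid with missing conditions (unless
#' \code{allowRagged = TRUE}), is a validation error.
#'
#' @param file path to a delimited file, or a literal string containing the
#'   table (if it contains a newline).
#' @param sep field separator; default guesses "," vs tab from the header.
#' @param schema named list remapping canonical column names to the file's.
#' @param responseType fallback response type when the column is absent.
#' @param allowRagged keep blocks with missing grid conditions (flagged).
#' @return list of \linkS4class{CombinationBlock} (responses stored as
#'   fractions on the input scale; run \code{\link{normalizeResponse}} to get
#'   the canonical inhibition scale).
#' @export
parseCombinationTable <- function(file, sep = NULL, schema = list(),
                                  responseType = "inhibition",
                                  allowRagged = FALSE) {
  txt <- if (length(file) == 1L && grepl("\n", file)) file else {
    if (!file.exists(file)) stop(sprintf("input file '%s' not found", file))
    paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) <= 1L) return(list())
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) return(list())

  map <- resolveSchema(colnames(df), schema)
  need <- c(map$block_id, map$drug, map$conc, map$response)
  if (length(map$drug) == 0L)
    stop("schema error: no drug/concentration columns found (expected 'drug_1'/'conc_1' ... or 'drug_row'/'drug_col')")
  for (col in need)
    if (!col %in% colnames(df))
      stop(sprintf("schema error: required column '%s' is missing", col))
  for (col in c(map$conc, map$response))
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col))

  hasType <- map$response_type %in% colnames(df)
  hasRep <- map$replicate %in% colnames(df)

  blocks <- list()
  for (bid in unique(as.character(df[[map$block_id]]))) {
    sub <- df[as.character(df[[map$block_id]]) == bid, , drop = FALSE]
    nd <- length(map$drug)
    # drug identity per slot must be constant within a block
    dn <- vapply(map$drug, function(c) as.character(sub[[c]][1]), character(1))
    for (j in seq_len(nd))
      if (length(unique(as.character(sub[[map$drug[j]]]))) > 1L)
        stop(sprintf("block '%s': column '%s' names more than one drug",
                     bid, map$drug[j]))
    rtype <- if (hasType) {
      tys <- tolower(unique(as.character(sub[[map$response_type]])))
      if (length(tys) > 1L)
        stop(sprintf("block '%s': mixed response_type values (%s)",
                     bid, paste(tys, collapse = ", ")))
      match.arg(tys, c("viability", "inhibition"))
    } else responseType

    conc <- as.matrix(sub[, map$conc, drop = FALSE])
    if (any(conc < 0)) stop(sprintf("block '%s': negative doses", bid))
    units <- character(nd)
    for (j in seq_len(nd)) {
      if (!is.na(map$unit[j]) && map$unit[j] %in% colnames(sub)) {
        us <- as.character(sub[[map$unit[j]]])
        units[j] <- us[1]
        f <- vapply(us, unitScale, numeric(1), to = units[j])
        conc[, j] <- conc[, j] * f
      } else units[j] <- "uM"
    }

    ladders <- lapply(seq_len(nd), function(j)
      sort(unique(conc[conc[, j] > 0, j])))
    keys <- apply(conc, 1L, doseKey)
    reps <- if (hasRep) as.integer(sub[[map$replicate]]) else {
      stats::ave(seq_along(keys), keys, FUN = seq_along)
    }
    if (anyDuplicated(paste(keys, reps)))
      stop(sprintf(
        "block '%s': duplicate (condition, replicate) key(s), e.g. %s rep %d",
        bid, gsub("\\|", " / ", keys[duplicated(paste(keys, reps))][1]),
        reps[duplicated(paste(keys, reps))][1]))

    ord <- order(match(keys, unique(keys)), reps)
    respByKey <- split(as.numeric(sub[[map$response]][ord]) / 100, keys[ord])
    blocks[[bid]] <- newBlock(bid, unname(dn), ladders, units, respByKey,
                              responseScale = rtype,
                              allowRagged = allowRagged)
  }
  blocks
}

#' Normalize a block to the canonical inhibition scale
#'
#' Converts viability to inhibition (\code{inhibition\% = 100 - viability\%},
#' i.e. fraction \code{1 - v}) and flags responses outside [0, 100]\%
#' inhibition without clamping them (assays over- and under-shoot; values
#' are clamped only inside the Bliss/ZIP product terms during scoring).
#' Already-inhibition blocks are returned with flags refreshed.
#'
#' @param block a \linkS4class{CombinationBlock}.
#' @return the block on the inhibition scale, with
#'   \code{block@flags$outOfRange} listing offending condition indices.
#' @export
normalizeResponse <- function(block) {
  stopifnot(is(block, "CombinationBlock"))
  rs <- block@responses
  if (block@responseScale == "viability")
    rs <- lapply(rs, function(v) 1 - v)
  oor <- which(vapply(rs, function(v)
    length(v) > 0 && any(v < 0 | v > 1), logical(1)))
  block@responses <- rs
  block@responseScale <- "inhibition"
  block@flags$outOfRange <- oor
  block
}

#' Serialize a combination block to a long-format table
#'
#' Inverse of \code{\link{parseCombinationTable}} up to canonical ordering:
#' one row per (condition, replicate) with responses in percent.
#'
#' @param block a \linkS4class{CombinationBlock}.
#' @return a data.frame in the canonical long layout.
#' @export
blockToTable <- function(block) {
  stopifnot(is(block, "CombinationBlock"))
  n <- nDrugs(block)
  rows <- list()
  for (i in seq_len(nrow(block@grid))) {
    v <- block@responses[[i]]
    if (!length(v)) next
    rows[[length(rows) + 1L]] <- data.frame(
      block_id = block@blockId,
      matrix(rep(block@drugNames, each = length(v)), nrow = length(v),
             dimnames = list(NULL, paste0("drug_", seq_len(n)))),
      matrix(rep(block@grid[i, ], each = length(v)), nrow = length(v),
             dimnames = list(NULL, paste0("conc_", seq_len(n)))),
      matrix(rep(block@doseUnits, each = length(v)), nrow = length(v),
             dimnames = list(NULL, paste0("conc_unit_", seq_len(n)))),
      response = v * 100,
      response_type = block@responseScale,
      replicate = seq_along(v),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

outputHeader <- function(seed = NA, input = NA) {
  c(sprintf("# synergyscore %s",
            as.character(utils::packageVersion("synergyscore"))),
    sprintf("# seed=%s", ifelse(is.na(seed), "NA", seed)),
    sprintf("# input=%s", ifelse(is.na(input), "NA", input)))
}

writeTableWithHeader <- function(df, path, seed = NA, input = NA,
                                 digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  fmt <- sprintf("%%.%dg", digits)
  for (j in which(num)) out[[j]] <- sprintf(fmt, df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(seed, input), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a combination block as CSV
#'
#' @param block a \linkS4class{CombinationBlock}.
#' @param path output path.
#' @param seed,input optional metadata recorded in the comment header.
#' @return the path, invisibly.
#' @export
writeBlockTable <- function(block, path, seed = NA, input = NA) {
  writeTableWithHeader(blockToTable(block), path, seed = seed, input = input,
                       digits = 15)
}

#' Long-format surface table
#'
#' One row per combination condition per model, with observed and expected
#' responses in percent inhibition and the synergy score in percentage
#' points. If a \linkS4class{BootstrapSummary} list is supplied, the
#' matching per-condition confidence bounds are joined on.
#'
#' @param surface a \linkS4class{SynergySurface}.
#' @param stats optional list of \linkS4class{BootstrapSummary} (one per
#'   model) whose CIs are added as \code{ci_lo}/\code{ci_hi}.
#' @return a data.frame.
#' @export
surfaceToTable <- function(surface, stats = NULL) {
  stopifnot(is(surface, "SynergySurface"))
  d <- surface@data
  n <- length(surface@drugNames)
  doseCols <- seq_len(n)
  out <- list()
  for (m in surface@models) {
    M <- toupper(m)
    cap <- paste0(toupper(substring(m, 1, 1)), substring(m, 2))
    tab <- data.frame(
      block_id = surface@blockId, d[, doseCols, drop = FALSE],
      model = M,
      observed = d$observed * 100,
      expected = d[[paste0("y", cap)]] * 100,
      score = d[[paste0("s", cap)]],
      check.names = FALSE, stringsAsFactors = FALSE
    )
    if (!is.null(stats)) {
      bs <- Filter(function(s) identical(s@model, m), stats)
      if (length(bs)) {
        cs <- bs[[1]]@conditionStats
        tab$ci_lo <- cs$ciLo
        tab$ci_hi <- cs$ciHi
      } else {
        tab$ci_lo <- NA_real_; tab$ci_hi <- NA_real_
      }
    }
    out[[m]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synergy surface as CSV
#'
#' Writes the long-format table of \code{\link{surfaceToTable}} at 10
#' significant digits under a deterministic comment header; the file
#' round-trips through \code{\link{readSurfaceTable}} without loss and
#' rewriting the result is byte-identical.
#'
#' @inheritParams surfaceToTable
#' @param path output path.
#' @param seed,input optional metadata recorded in the comment header.
#' @return the path, invisibly.
#' @export
writeSurface <- function(surface, path, stats = NULL, seed = NA, input = NA) {
  writeTableWithHeader(surfaceToTable(surface, stats), path,
                       seed = seed, input = input, digits = 10)
}

#' Read back a surface CSV
#'
#' @param path a file written by \code{\link{writeSurface}}.
#' @return the surface data.frame.
#' @export
readSurfaceTable <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' JSON summary of a block (and optionally its scores)
#'
#' @param block a \linkS4class{CombinationBlock}.
#' @param surface optional \linkS4class{SynergySurface} whose block-average
#'   scores and monotherapy curve parameters are included.
#' @param path optional path; when given the JSON is written there.
#' @return JSON string, invisibly when \code{path} is given.
#' @export
blockSummaryJSON <- function(block, surface = NULL, path = NULL) {
  reps <- lengths(block@responses)
  x <- list(
    block_id = block@blockId,
    drugs = block@drugNames,
    dose_units = block@doseUnits,
    dose_ladders = block@doseLadders,
    n_conditions = nrow(block@grid),
    n_combination_conditions = sum(rowSums(block@grid > 0) == nDrugs(block)),
    replicates = list(min = min(reps[reps > 0]), max = max(reps)),
    response_scale = block@responseScale
  )
  if (!is.null(surface)) {
    x$average_scores <- as.list(surface@summary)
    x$monotherapy_curves <- lapply(surface@curves, function(crv) list(
      e_min = crv@eMin, e_max = crv@eMax, ic50 = crv@ic50,
      slope = crv@slope, degenerate = crv@degenerate))
    names(x$monotherapy_curves) <- surface@drugNames
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# --- internal grid helpers used across modules ---

# indices of conditions where every drug is at nonzero dose
combinationIdx <- function(block) which(rowSums(block@grid > 0) == nDrugs(block))

# monotherapy condition index per drug per nonzero dose:
# list over drugs of integer vectors along that drug's ladder
monoIndex <- function(block) {
  n <- nDrugs(block)
  keys <- apply(block@grid, 1L, doseKey)
  lapply(seq_len(n), function(i) {
    vapply(block@doseLadders[[i]], function(d) {
      doses <- numeric(n); doses[i] <- d
      match(doseKey(doses), keys)
    }, integer(1))
  })
}

# mean-response lookup as an n-dim array with dim sizes (ladder+1),
# index 1 = dose 0, index k+1 = k-th nonzero dose
meanArray <- function(block, means = conditionMeans(block)) {
  dims <- lengths(block@doseLadders) + 1L
  arr <- array(NA_real_, dim = dims)
  idx <- matrix(1L, nrow(block@grid), nDrugs(block))
  for (j in seq_len(nDrugs(block))) {
    pos <- block@grid[, j] > 0
    idx[pos, j] <- match(block@grid[pos, j], block@doseLadders[[j]]) + 1L
  }
  arr[idx] <- means
  arr
}
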