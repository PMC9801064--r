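# shared fixture builders (everything generated in code; no stored data)

# canonical long-format CSV text for a set of measurement rows
tableText <- function(rows) {
  paste(c(paste(colnames(rows), collapse = ","),
          apply(rows, 1L, paste, collapse = ",")), collapse = "\n")
}

# rows of a full-factorial 2-drug block from a response function (percent),
# k replicates per condition
twoDrugRows <- function(blockId = "b1", drugs = c("A", "B"),
                        ladders = list(c(1, 10, 100), c(1, 10, 100)),
                        respFun = function(d) 50, k = 1,
                        units = c("uM", "uM"), responseType = "inhibition",
                        withReplicateCol = TRUE) {
  levs <- lapply(ladders, function(l) c(0, l))
  g <- expand.grid(levs[[1]], levs[[2]])
  rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    do.call(rbind, lapply(seq_len(k), function(r)
      data.frame(block_id = blockId, drug_1 = drugs[1], drug_2 = drugs[2],
                 conc_1 = g[i, 1], conc_2 = g[i, 2],
                 conc_unit_1 = units[1], conc_unit_2 = units[2],
                 response = respFun(as.numeric(g[i, ])), replicate = r,
                 response_type = responseType,
                 stringsAsFactors = FALSE)))
  }))
  if (!withReplicateCol) rows$replicate <- NULL
  rows
}

# a small asymmetric pair of monotherapy curves used across tests
asymCurves <- list(list(eMin = 0, eMax = 0.9, ic50 = 1, slope = 1.2),
                   list(eMin = 0, eMax = 0.7, ic50 = 5, slope = 0.8))
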