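# independent brute-force two-drug oracle: direct formula evaluation per
# condition, with its own 4PL fitting (stats::optim) and root solving
# (stats::uniroot) - shares no scoring code with the package

ora4pl <- function(x, emin, emax, m, lam) {
  ifelse(x <= 0, emin, emin + (emax - emin) / (1 + (m / x)^lam))
}

oraInv <- function(p, y) {
  t <- (y - p["emin"]) / (p["emax"] - p["emin"])
  if (t <= 0) return(0)
  if (t >= 1) return(Inf)
  unname(p["m"] * (t / (1 - t))^(1 / p["lam"]))
}

# box-constrained least squares with multi-start L-BFGS-B; same parameter
# box as the model convention (asymptotes in [0,1], slope in [1e-3, 10])
oraFit <- function(doses, resp, eminFix = NULL) {
  if (diff(range(resp)) < 1e-12)
    return(c(emin = resp[1], emax = resp[1], m = 1, lam = 1e-3))
  pos <- doses[doses > 0]
  mRef <- exp(mean(log(range(pos))))
  pred <- function(th) {
    emin <- if (is.null(eminFix)) th[["emin"]] else eminFix
    ora4pl(doses, emin, th[["emax"]], exp(th[["lm"]]), th[["lam"]])
  }
  obj <- function(th) sum((resp - pred(th))^2)
  half <- (min(resp) + max(resp)) / 2
  m0 <- doses[which.min(abs(resp - half))]
  if (m0 <= 0) m0 <- min(pos)
  lower <- c(emin = 0, emax = 0, lm = log(mRef) - 20, lam = 1e-3)
  upper <- c(emin = 1, emax = 1, lm = log(mRef) + 20, lam = 10)
  if (!is.null(eminFix)) {
    lower <- lower[-1]; upper <- upper[-1]
  }
  best <- NULL
  for (l0 in c(0.5, 1, 3)) {
    th0 <- c(emin = max(0, min(resp)), emax = min(1, max(resp)),
             lm = log(m0), lam = l0)
    if (!is.null(eminFix)) th0 <- th0[-1]
    ans <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 10, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(ans) && (is.null(best) || ans$value < best$value))
      best <- ans
  }
  th <- best$par
  emin <- if (is.null(eminFix)) th[["emin"]] else eminFix
  c(emin = emin, emax = th[["emax"]], m = exp(th[["lm"]]), lam = th[["lam"]])
}

oraLoewe <- function(p1, p2, x1, x2) {
  lo <- max(p1["emin"], p2["emin"]) + 1e-9
  hi <- min(p1["emax"], p2["emax"]) - 1e-12
  g <- function(y) x1 / oraInv(p1, y) + x2 / oraInv(p2, y) - 1
  if (g(hi) > 0) return(unname(min(p1["emax"], p2["emax"])))
  if (g(lo) < 0) return(unname(max(p1["emin"], p2["emin"])))
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

# full per-condition score table for a 2-drug block: loops and direct
# formulas only
oracleScores2 <- function(block) {
  g <- conditionGrid(block)
  means <- conditionMeans(block)
  lad1 <- doseLadders(block)[[1]]; lad2 <- doseLadders(block)[[2]]
  at <- function(x1, x2) means[which(g[, 1] == x1 & g[, 2] == x2)]
  mono1 <- vapply(lad1, function(d) at(d, 0), numeric(1))
  mono2 <- vapply(lad2, function(d) at(0, d), numeric(1))
  y0 <- at(0, 0)
  p1 <- oraFit(c(0, lad1), c(y0, mono1))
  p2 <- oraFit(c(0, lad2), c(y0, mono2))
  cl <- function(v) pmin(pmax(v, 0), 1)

  out <- list()
  for (x1 in lad1) for (x2 in lad2) {
    yc <- at(x1, x2)
    y1 <- mono1[match(x1, lad1)]; y2 <- mono2[match(x2, lad2)]
    sHsa <- (yc - max(y1, y2)) * 100
    sBliss <- (yc - (1 - (1 - cl(y1)) * (1 - cl(y2)))) * 100
    sLoewe <- (yc - oraLoewe(p1, p2, x1, x2)) * 100
    # ZIP: conditional fits along each drug, floor pinned at the partner's
    # fitted monotherapy response
    pin1 <- ora4pl(x2, p2["emin"], p2["emax"], p2["m"], p2["lam"])
    c1 <- oraFit(lad1, vapply(lad1, function(d) at(d, x2), numeric(1)),
                 eminFix = unname(pin1))
    v1 <- ora4pl(x1, c1["emin"], c1["emax"], c1["m"], c1["lam"])
    pin2 <- ora4pl(x1, p1["emin"], p1["emax"], p1["m"], p1["lam"])
    c2 <- oraFit(lad2, vapply(lad2, function(d) at(x1, d), numeric(1)),
                 eminFix = unname(pin2))
    v2 <- ora4pl(x2, c2["emin"], c2["emax"], c2["m"], c2["lam"])
    f1 <- ora4pl(x1, p1["emin"], p1["emax"], p1["m"], p1["lam"])
    f2 <- ora4pl(x2, p2["emin"], p2["emax"], p2["m"], p2["lam"])
    yZip <- 1 - (1 - cl(f1)) * (1 - cl(f2))
    sZip <- ((v1 + v2) / 2 - yZip) * 100
    out[[length(out) + 1L]] <- data.frame(
      x1 = x1, x2 = x2, sHsa = sHsa, sBliss = unname(sBliss),
      sLoewe = unname(sLoewe), sZip = unname(sZip))
  }
  do.call(rbind, out)
}
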