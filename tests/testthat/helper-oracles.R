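# Independent oracle implementations used to cross-check the package.
# Deliberately naive: plain loops and direct formulas.

# ssGSEA running sum, summed position by position.
oracleSsgsea <- function(expr, genes, alpha = 0.25) {
  sapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    inSet <- rownames(expr)[ord] %in% genes
    N <- nrow(expr)
    wSum <- sum(abs(r[ord][inSet])^alpha)
    es <- 0; cin <- 0; cout <- 0
    for (i in seq_len(N)) {
      if (inSet[i]) cin <- cin + abs(r[ord][i])^alpha / wSum
      else cout <- cout + 1 / (N - sum(inSet))
      es <- es + (cin - cout)
    }
    unname(es)
  })
}

# All-pairs minimum distance (quadratic loop).
oracleMinDist <- function(anchors, targets) {
  sapply(seq_len(nrow(targets)), function(i) {
    min(sqrt((anchors$x - targets$x[i])^2 + (anchors$y - targets$y[i])^2))
  })
}

# Flood fill of connected components among TCA spots.
oracleComponents <- function(regions, grid, radiusFactor = 1.2) {
  ids <- spotIds(grid)
  xy <- spotCoords(grid)
  tca <- which(as.character(regions) == "TCA")
  comp <- rep(NA_integer_, length(ids)); names(comp) <- ids
  maxD2 <- (radiusFactor * gridPitch(grid))^2
  unvisited <- tca
  label <- 0L
  while (length(unvisited)) {
    label <- label + 1L
    stack <- unvisited[1L]
    members <- integer()
    while (length(stack)) {
      cur <- stack[1L]; stack <- stack[-1L]
      if (cur %in% members) next
      members <- c(members, cur)
      d2 <- (xy[unvisited, 1L] - xy[cur, 1L])^2 +
        (xy[unvisited, 2L] - xy[cur, 2L])^2
      nb <- unvisited[d2 <= maxD2]
      stack <- c(stack, setdiff(nb, members))
    }
    comp[members] <- label
    unvisited <- setdiff(unvisited, members)
  }
  # relabel by minimum spot id per component, as the package does
  present <- !is.na(comp)
  minId <- tapply(ids[present], comp[present], min)
  comp[present] <- as.integer(rank(minId)[as.character(comp[present])])
  comp
}

# Cox partial log-likelihood for a single binary covariate, Efron ties.
oracleCoxLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumRisk <- sum(exp(beta * x[R]))
    sumTie <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumRisk - l / d * sumTie)
    }
  }
  ll
}

oracleCoxBetaHat <- function(time, event, x) {
  optimize(function(b) -oracleCoxLogLik(b, time, event, x),
           interval = c(-10, 10), tol = 1e-7)$minimum
}

# Hand product-limit estimator (no grouping).
oracleKM <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    atRisk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / atRisk)
    out[i] <- s
  }
  data.frame(time = tt, survival = out)
}

# Two-group log-rank chi-square from the O-E table.
oracleLogrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  tt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# A small lognorm-like matrix with heterogeneous gene baselines and
# homogeneous units: gene g has value base_g + noise.
makeHomogeneousMatrix <- function(nGenes, nUnits, seed = 1, noiseSd = 0.1) {
  withr::local_seed(seed)
  base <- runif(nGenes, 0, 5)
  m <- base + matrix(rnorm(nGenes * nUnits, 0, noiseSd), nGenes, nUnits)
  dimnames(m) <- list(sprintf("g%04d", seq_len(nGenes)),
                      sprintf("u%04d", seq_len(nUnits)))
  m
}
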