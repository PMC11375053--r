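#' Aggregate raw Stereo-seq spots into square bins
#'
#' Sums counts of raw capture spots (0.5 micron pitch) inside square
#' windows of `binWidth` x `binWidth` spots (bin100 by default, i.e.
#' 10,000 raw spots covering roughly 50 microns per side). Partial windows
#' at the tissue edge are kept and flagged.
#'
#' @param counts gene x raw-spot count matrix.
#' @param grid [SpotGrid-class] of the raw spots (platform
#'   `"stereo-raw"`); binned grids are rejected.
#' @param binWidth number of raw spots per bin side (default 100).
#' @return list with `counts` (gene x bin), `grid` (a square
#'   [SpotGrid-class] at `binWidth * rawPitch` micrometres, bin
#'   coordinates at window centres) and `partial` (logical per bin: fewer
#'   raw spots than a full window).
#' @export
binStereoSpots <- function(counts, grid, binWidth = 100) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (gridPlatform(grid) == "stereo-bin")
    stop("grid is already binned; refusing to bin twice")
  m <- getAssay(counts, "counts")
  stopifnot(ncol(m) == length(grid))
  w <- binWidth * gridPitch(grid)
  xy <- spotCoords(grid)
  ix <- floor(xy[, 1L] / w)
  iy <- floor(xy[, 2L] / w)
  key <- paste(ix, iy, sep = "_")
  bins <- sort(unique(key))
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = match(key, bins),
                              x = 1, dims = c(length(key), length(bins)))
  out <- m %*% ind
  colnames(out) <- paste0("bin_", bins)
  rownames(out) <- rownames(m)
  nRaw <- tabulate(match(key, bins), nbins = length(bins))
  cxy <- do.call(rbind, strsplit(bins, "_"))
  bx <- (as.numeric(cxy[, 1L]) + 0.5) * w
  by <- (as.numeric(cxy[, 2L]) + 0.5) * w
  list(counts = methods::as(out, "CsparseMatrix"),
       grid = SpotGrid(colnames(out), bx, by, platform = "stereo-bin",
                       pitch = w),
       partial = setNames(nRaw < binWidth^2, colnames(out)))
}

#' Call TLS / TCA / stroma regions from signature scores
#'
#' Scores are z-standardised across spots. A spot is TCA when its
#' malignant z-score exceeds the threshold and is (weakly) the maximum of
#' the three; TLS when the larger of the B and T z-scores exceeds the
#' threshold and strictly exceeds the malignant z-score; otherwise
#' stroma. Exact ties are resolved with precedence TCA > TLS > stroma.
#'
#' @param scores spot x signature matrix containing columns named
#'   `malignant`, `B` and `T` (e.g. from [moduleScoreMatrix()]).
#' @param zThreshold z-score cut for calling a region (default 0.5).
#' @return named factor of regions per spot.
#' @export
callRegions <- function(scores, zThreshold = 0.5) {
  need <- c("malignant", "B", "T")
  if (!all(need %in% colnames(scores)))
    stop("scores must contain columns malignant, B, T")
  z <- zScoreColumns(scores[, need, drop = FALSE])
  lymph <- pmax(z[, "B"], z[, "T"])
  region <- ifelse(z[, "malignant"] > zThreshold & z[, "malignant"] >= lymph,
                   "TCA",
                   ifelse(lymph > zThreshold & lymph > z[, "malignant"],
                          "TLS", "stroma"))
  factor(setNames(region, rownames(scores)),
         levels = c("TLS", "TCA", "stroma"))
}

# Neighbour pairs among points with centre distance <= maxDist,
# via cell-list bucketing (exact).
.neighbourPairs <- function(xy, maxDist) {
  n <- nrow(xy)
  if (n < 2L) return(matrix(integer(), ncol = 2L))
  cs <- maxDist
  cx <- floor(xy[, 1L] / cs)
  cy <- floor(xy[, 2L] / cs)
  key <- paste(cx, cy, sep = "_")
  byCell <- split(seq_len(n), key)
  cellXY <- do.call(rbind, strsplit(names(byCell), "_", fixed = TRUE))
  ccx <- as.numeric(cellXY[, 1L])
  ccy <- as.numeric(cellXY[, 2L])
  pairs <- list()
  for (off in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nbKey <- paste(ccx + off[1L], ccy + off[2L], sep = "_")
    for (i in seq_along(byCell)) {
      a <- byCell[[i]]
      b <- if (identical(off, c(0, 0))) a else byCell[[nbKey[i]]]
      if (is.null(b)) next
      if (identical(off, c(0, 0))) {
        if (length(a) < 2L) next
        cmb <- utils::combn(a, 2L)
        cand <- cbind(cmb[1L, ], cmb[2L, ])
      } else {
        cand <- cbind(rep(a, each = length(b)), rep(b, length(a)))
      }
      d2 <- (xy[cand[, 1L], 1L] - xy[cand[, 2L], 1L])^2 +
        (xy[cand[, 1L], 2L] - xy[cand[, 2L], 2L])^2
      keep <- d2 <= maxDist^2
      if (any(keep)) pairs[[length(pairs) + 1L]] <- cand[keep, , drop = FALSE]
    }
  }
  if (length(pairs) == 0L) return(matrix(integer(), ncol = 2L))
  do.call(rbind, pairs)
}

#' Connected TCA components on the spot lattice
#'
#' TCA spots whose centres lie within `radiusFactor * pitch` of each other
#' are connected; connected components are the tumour-cell aggregates. The
#' default factor 1.2 yields 6-connectivity on the hexagonal Visium
#' lattice and 4-connectivity on square bins. Components are labelled
#' deterministically: the component containing the smallest spot id gets
#' id 1, and so on.
#'
#' @param regions named factor from [callRegions()].
#' @param grid [SpotGrid-class] aligned with `regions`.
#' @param radiusFactor multiple of the pitch defining adjacency.
#' @return named integer vector over all spots: component id on TCA spots,
#'   `NA` elsewhere.
#' @export
findTcaComponents <- function(regions, grid, radiusFactor = 1.2) {
  stopifnot(length(regions) == length(grid))
  ids <- spotIds(grid)
  comp <- rep(NA_integer_, length(ids))
  names(comp) <- ids
  tca <- which(as.character(regions) == "TCA")
  if (length(tca) == 0L) return(comp)
  xy <- spotCoords(grid)[tca, , drop = FALSE]
  pr <- .neighbourPairs(xy, radiusFactor * gridPitch(grid))
  g <- igraph::graph_from_edgelist(
    matrix(as.character(pr), ncol = 2L), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_along(tca)),
                                    igraph::V(g)$name))
  mem <- igraph::components(g)$membership
  mem <- mem[as.character(seq_along(tca))]
  # relabel deterministically by each component's minimum spot id
  minId <- tapply(ids[tca], mem, min)
  newId <- rank(minId)
  comp[tca] <- as.integer(newId[as.character(mem)])
  comp
}

#' Stratify TCA components by EBV signature quartiles
#'
#' EBV signature scores of all TCA spots in the sample are split at their
#' quartiles: spots strictly above Q3 are high, strictly below Q1 low,
#' and mid otherwise. Each component takes the majority class of its
#' spots, with ties resolved to mid. With fewer than 4 TCA spots all
#' components are mid (with a warning).
#'
#' @param components named integer vector from [findTcaComponents()].
#' @param ebvScore named numeric EBV signature score per spot (at least
#'   the TCA spots).
#' @return list with `spotClass` (named factor high/mid/low over TCA
#'   spots) and `componentClass` (data.frame `component`, `ebvClass`).
#' @export
stratifyEbv <- function(components, ebvScore) {
  tcaSpots <- names(components)[!is.na(components)]
  if (length(tcaSpots) == 0L)
    return(list(spotClass = factor(character(), levels = c("high", "mid", "low")),
                componentClass = data.frame(component = integer(),
                                            ebvClass = character())))
  s <- ebvScore[tcaSpots]
  if (anyNA(s)) stop("EBV score missing for some TCA spots")
  if (length(s) < 4L) {
    warning("fewer than 4 TCA spots; all components classed mid")
    cls <- factor(rep("mid", length(s)), levels = c("high", "mid", "low"))
  } else {
    qs <- quantile(s, c(0.25, 0.75), names = FALSE)
    cls <- factor(ifelse(s > qs[2L], "high", ifelse(s < qs[1L], "low", "mid")),
                  levels = c("high", "mid", "low"))
  }
  names(cls) <- tcaSpots
  comp <- components[tcaSpots]
  compClass <- vapply(split(as.character(cls), comp), function(v) {
    tab <- table(factor(v, levels = c("high", "mid", "low")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) "mid" else top
  }, character(1L))
  list(spotClass = cls,
       componentClass = data.frame(component = as.integer(names(compClass)),
                                   ebvClass = unname(compClass),
                                   stringsAsFactors = FALSE))
}

#' Classify plasma-cell co-occurrence of TCA components
#'
#' A component is "wP" (with plasma cells) when at least one of its spots,
#' or a spot within one neighbourhood radius of any of its spots, has a
#' plasma signature score strictly above the sample's `q`-quantile;
#' otherwise "woP". With `q = 0` every component is wP (degenerate rule).
#'
#' @param components named integer vector from [findTcaComponents()].
#' @param plasmaScore named numeric plasma signature score for all spots.
#' @param grid [SpotGrid-class] for the halo lookup.
#' @param q occupancy quantile (default 0.75).
#' @param radiusFactor halo radius as a multiple of the pitch
#'   (default 1.2, one lattice neighbourhood).
#' @return data.frame with columns `component`, `plasmaFlag` (wP/woP).
#' @export
classifyPlasmaCooccurrence <- function(components, plasmaScore, grid,
                                       q = 0.75, radiusFactor = 1.2) {
  stopifnot(q >= 0, q <= 1)
  comps <- sort(unique(components[!is.na(components)]))
  if (length(comps) == 0L)
    return(data.frame(component = integer(), plasmaFlag = character()))
  if (q == 0) {
    return(data.frame(component = comps,
                      plasmaFlag = rep("wP", length(comps)),
                      stringsAsFactors = FALSE))
  }
  thr <- quantile(plasmaScore, q, names = FALSE)
  ids <- spotIds(grid)
  xy <- spotCoords(grid)
  hot <- ids[plasmaScore[ids] > thr]
  hotXY <- xy[hot, , drop = FALSE]
  r2 <- (radiusFactor * gridPitch(grid))^2
  flag <- vapply(comps, function(cp) {
    member <- names(components)[!is.na(components) & components == cp]
    if (any(member %in% hot)) return("wP")
    if (length(hot) == 0L) return("woP")
    mXY <- xy[member, , drop = FALSE]
    for (i in seq_len(nrow(mXY))) {
      d2 <- (hotXY[, 1L] - mXY[i, 1L])^2 + (hotXY[, 2L] - mXY[i, 2L])^2
      if (any(d2 <= r2)) return("wP")
    }
    "woP"
  }, character(1L))
  data.frame(component = comps, plasmaFlag = unname(flag),
             stringsAsFactors = FALSE)
}

#' End-to-end compartment calling
#'
#' Convenience wrapper running the full spatial pipeline on raw counts:
#' log-normalisation, module scoring of the malignant/B/T/EBV/plasma
#' signatures, region calling, TCA component detection, EBV quartile
#' stratification and plasma co-occurrence classification.
#'
#' @param counts gene x spot count matrix.
#' @param grid matching [SpotGrid-class].
#' @param signatures [SignatureSet-class] containing signatures named
#'   `malignant`, `B`, `T`, `ebv`, `plasma` (and optionally others).
#' @param zThreshold region-calling z cut (default 0.5).
#' @param plasmaQ plasma occupancy quantile (default 0.75).
#' @param radiusFactor adjacency radius as multiple of pitch (default 1.2).
#' @param nBins,nCtrl,seed passed to [moduleScore()].
#' @return a [CompartmentMap-class]; the spot x signature score matrix is
#'   attached as attribute `"scores"`.
#' @export
callCompartments <- function(counts, grid, signatures, zThreshold = 0.5,
                             plasmaQ = 0.75, radiusFactor = 1.2,
                             nBins = 24, nCtrl = 100, seed = 0) {
  need <- c("malignant", "B", "T", "ebv", "plasma")
  if (!all(need %in% names(signatures)))
    stop("signatures must include: ", paste(need, collapse = ", "))
  ln <- logNormalize(counts)
  scores <- moduleScoreMatrix(ln, signatures, nBins = nBins, nCtrl = nCtrl,
                              seed = seed)
  region <- callRegions(scores, zThreshold = zThreshold)
  comp <- findTcaComponents(region, grid, radiusFactor = radiusFactor)
  ebv <- stratifyEbv(comp, setNames(scores[, "ebv"], rownames(scores)))
  plasma <- classifyPlasmaCooccurrence(
    comp, setNames(scores[, "plasma"], rownames(scores)), grid,
    q = plasmaQ, radiusFactor = radiusFactor)
  cc <- merge(ebv$componentClass, plasma, by = "component")
  out <- methods::new("CompartmentMap", region = region,
                      componentId = comp, componentClass = cc)
  attr(out, "scores") <- scores
  out
}

#' Compare apoptosis scores across TCA classes
#'
#' Summarises a per-spot apoptosis score by TCA class (EBV class x plasma
#' flag) and performs two-sided t-tests (Welch by default) between every
#' class pair. Classes with fewer than 2 spots are excluded with a
#' warning.
#'
#' @param cmap a [CompartmentMap-class].
#' @param apoptosisScore named numeric score per spot.
#' @param varEqual use pooled-variance t-tests instead of Welch.
#' @return list with `summary` (class, n, mean, median, IQR), `tests`
#'   (pairwise t statistics and p-values) and `topClass` (class with the
#'   highest mean score).
#' @export
compareApoptosis <- function(cmap, apoptosisScore, varEqual = FALSE) {
  df <- as.data.frame(cmap)
  df <- df[df$region == "TCA", ]
  df$class <- paste0("EBV", df$ebvClass, "-", df$plasmaFlag)
  df$score <- apoptosisScore[df$spot]
  if (anyNA(df$score)) stop("apoptosis score missing for some TCA spots")
  sizes <- table(df$class)
  drop <- names(sizes)[sizes < 2L]
  if (length(drop)) {
    warning("excluding class(es) with fewer than 2 spots: ",
            paste(drop, collapse = ", "))
    df <- df[!df$class %in% drop, ]
  }
  classes <- sort(unique(df$class))
  if (length(classes) < 2L) stop("need at least 2 TCA classes to compare")
  summ <- do.call(rbind, lapply(classes, function(cl) {
    x <- df$score[df$class == cl]
    data.frame(class = cl, n = length(x), mean = mean(x),
               median = median(x), IQR = IQR(x), stringsAsFactors = FALSE)
  }))
  prs <- utils::combn(classes, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    a <- df$score[df$class == prs[1L, i]]
    b <- df$score[df$class == prs[2L, i]]
    tt <- t.test(a, b, var.equal = varEqual)
    data.frame(classA = prs[1L, i], classB = prs[2L, i],
               t = unname(tt$statistic), pValue = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, tests = tests,
       topClass = summ$class[which.max(summ$mean)])
}

#' Normalised cell-cell connection value
#'
#' Divides an interaction connection value by the product of the two
#' clusters' cell numbers, removing the dependence on cluster size.
#'
#' @param value raw connection value.
#' @param nA,nB cell counts of the two clusters (both at least 1).
#' @return normalised connection (symmetric in A and B).
#' @export
normalizedConnection <- function(value, nA, nB) {
  if (any(c(nA, nB) < 1)) stop("cell counts must be at least 1")
  value / (nA * nB)
}

#' Immune-infiltration bin of a tumour-area fraction
#'
#' Maps the fraction of tumour area infiltrated by immune cells to the
#' four-level score 1-4 representing 0-25%, 26-50%, 51-75% and 76-100%
#' (boundaries 0.25, 0.50, 0.75 fall in the lower bin; 0 maps to 1).
#'
#' @param fraction numeric in \[0, 1\].
#' @return integer bin(s) in 1..4.
#' @export
infiltrationBin <- function(fraction) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must lie in [0, 1]")
  out <- pmax(1L, as.integer(ceiling(fraction * 4)))
  out
}
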