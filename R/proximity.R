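#' Count targets within a radius of any anchor
#'
#' For phenotyped cell points from multiplex imaging: counts the target
#' cells whose minimum Euclidean distance to any anchor cell is at most
#' `r` (closed boundary, so a target exactly at distance `r` is counted),
#' and returns every target's minimum distance. Distances are computed
#' exactly, chunking the target set to bound memory.
#'
#' @param anchors data.frame with numeric columns `x`, `y` (micrometres);
#'   e.g. IgG+ plasma cells.
#' @param targets data.frame with numeric columns `x`, `y`; e.g.
#'   CASP3+PanCK+ apoptotic tumour cells.
#' @param r radius in micrometres (default 20).
#' @return list with `count` (targets within `r`) and `minDistance`
#'   (numeric per target; `Inf` when there are no anchors, with a
#'   warning).
#' @export
countWithinRadius <- function(anchors, targets, r = 20) {
  stopifnot(r > 0)
  nT <- nrow(targets)
  if (nT == 0L) return(list(count = 0L, minDistance = numeric()))
  if (nrow(anchors) == 0L) {
    warning("no anchor cells; count is 0")
    return(list(count = 0L, minDistance = rep(Inf, nT)))
  }
  ax <- anchors$x; ay <- anchors$y
  md <- numeric(nT)
  chunk <- max(1L, floor(2e6 / nrow(anchors)))
  for (s in seq(1L, nT, by = chunk)) {
    e <- min(s + chunk - 1L, nT)
    dx <- outer(targets$x[s:e], ax, "-")
    dy <- outer(targets$y[s:e], ay, "-")
    md[s:e] <- sqrt(apply(dx * dx + dy * dy, 1L, min))
  }
  list(count = sum(md <= r), minDistance = md)
}

#' Histogram of minimum distances
#'
#' Bins per-target minimum distances into right-closed intervals
#' `(e_i, e_{i+1}]`, the first interval including its lower edge. Counts
#' over bins sum to the number of finite distances inside the edge range.
#'
#' @param distances numeric vector (e.g. `minDistance` from
#'   [countWithinRadius()]); non-finite values are dropped.
#' @param edges increasing numeric vector of bin edges in micrometres.
#' @return named integer vector of bin counts.
#' @export
distanceHistogram <- function(distances, edges) {
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be increasing")
  d <- distances[is.finite(distances)]
  labs <- paste0("(", utils::head(edges, -1L), ",", edges[-1L], "]")
  if (length(d) == 0L) return(setNames(rep(0L, length(labs)), labs))
  ct <- table(cut(d, breaks = edges, right = TRUE, include.lowest = TRUE))
  setNames(as.integer(ct), labs)
}

#' Expected within-radius count under complete spatial randomness
#'
#' Closed form for the number of targets having at least one of
#' `nAnchors` independently uniform anchors within radius `r` in a field
#' of the given area (edge effects ignored):
#' `nTargets * (1 - (1 - pi r^2 / A)^nAnchors)`.
#'
#' @param nAnchors,nTargets point counts.
#' @param r radius (same length unit as the field).
#' @param area field area; must exceed `pi * r^2`.
#' @return expected count (numeric).
#' @export
csrExpectedCount <- function(nAnchors, nTargets, r, area) {
  stopifnot(area > 0, r >= 0)
  p <- pi * r^2 / area
  if (p > 1) stop("anchor disc exceeds the field area")
  nTargets * (1 - (1 - p)^nAnchors)
}
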