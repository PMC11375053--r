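#' Bin somatic hypermutation frequencies
#'
#' Immunoglobulin heavy-chain SHM frequencies are annotated `none` at
#' exactly 0, `low` in (0, 0.02\] and `high` above 0.02.
#'
#' @param freq numeric vector of SHM frequencies in \[0, 1\].
#' @return factor with levels none, low, high.
#' @export
binShm <- function(freq) {
  if (any(freq < 0 | freq > 1)) stop("SHM frequencies must lie in [0, 1]")
  factor(ifelse(freq == 0, "none", ifelse(freq <= 0.02, "low", "high")),
         levels = c("none", "low", "high"))
}

#' Isotype composition per group
#'
#' Fraction of cells carrying each isotype within each group (cluster,
#' sample, SHM bin, ...). Fractions sum to 1 per group; isotypes absent
#' from a group are reported as 0. Empty groups are dropped with a
#' warning.
#'
#' @param table repertoire data.frame with an `isotype` column.
#' @param groupBy name of the grouping column (default `"cluster"`).
#' @return matrix of fractions, groups in rows, isotypes in columns.
#' @export
isotypeComposition <- function(table, groupBy = "cluster") {
  stopifnot("isotype" %in% colnames(table), groupBy %in% colnames(table))
  g <- table[[groupBy]]
  if (!is.factor(g)) g <- factor(g)
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty)) warning("dropping empty group(s): ",
                             paste(empty, collapse = ", "))
  tab <- table(droplevels(g), factor(table$isotype))
  prop.table(tab, margin = 1L)
}

#' Normalised clonal diversity of a cluster
#'
#' Shannon entropy of the clone-size distribution normalised by `ln k`
#' (k = number of clonotypes in the cluster), so the value lies in
#' \[0, 1\]: 0 for a single clonotype (fully expanded), 1 for all
#' singletons. Equals `1 - expansion`, where expansion is the normalised
#' entropy deficit.
#'
#' @param table repertoire data.frame with columns `cluster`, `clonotype`.
#' @param cluster cluster label to evaluate.
#' @return diversity in \[0, 1\].
#' @export
clonalDiversity <- function(table, cluster) {
  cl <- table[table$cluster == cluster, , drop = FALSE]
  if (nrow(cl) == 0L) stop("cluster '", cluster, "' is empty")
  sizes <- table(cl$clonotype)
  k <- length(sizes)
  if (k == 1L) return(0)
  p <- as.numeric(sizes) / sum(sizes)
  H <- -sum(p * log(p))
  H / log(k)
}

#' Transition index between two cell clusters
#'
#' Clone-size-weighted pairwise split entropy: restricting to the cells
#' of clusters A and B, every clonotype c present contributes the entropy
#' of its (n_cA, n_cB) split normalised by `ln 2`, weighted by its share
#' n_c / N of those cells. The index is 0 when no clonotype spans both
#' clusters and 1 when every clonotype is split 50/50; it is symmetric in
#' A and B.
#'
#' @param table repertoire data.frame with columns `cluster`, `clonotype`.
#' @param clusterA,clusterB cluster labels (both non-empty).
#' @return transition index in \[0, 1\].
#' @export
transitionIndex <- function(table, clusterA, clusterB) {
  a <- table[table$cluster == clusterA, , drop = FALSE]
  b <- table[table$cluster == clusterB, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both clusters must be non-empty")
  cl <- unique(c(a$clonotype, b$clonotype))
  nA <- table(factor(a$clonotype, levels = cl))
  nB <- table(factor(b$clonotype, levels = cl))
  n <- as.numeric(nA + nB)
  h <- vapply(seq_along(cl), function(i) {
    p <- c(nA[i], nB[i]) / n[i]
    p <- p[p > 0]
    if (length(p) < 2L) return(0)
    -sum(p * log(p)) / log(2)
  }, numeric(1L))
  sum(n / sum(n) * h)
}

#' Sharing of a reference cluster's top clonotypes
#'
#' Identifies the `k` most frequent clonotypes of the reference cluster
#' (by within-reference cell count, ties broken by lexicographic
#' clonotype id) and reports, for every cluster, the fraction of its
#' cells whose clonotype belongs to that top-k set.
#'
#' @param table repertoire data.frame with columns `cluster`, `clonotype`.
#' @param refCluster reference cluster label.
#' @param k number of top clonotypes (default 10).
#' @return named numeric vector of sharing fractions per cluster, with
#'   the top-k clonotype ids attached as attribute `"topClonotypes"`.
#' @export
topClonotypeSharing <- function(table, refCluster, k = 10) {
  if (k <= 0) stop("k must be positive")
  ref <- table[table$cluster == refCluster, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference cluster is empty")
  sizes <- table(ref$clonotype)
  ordTab <- sizes[order(-as.numeric(sizes), names(sizes))]
  top <- utils::head(names(ordTab), k)
  frac <- vapply(split(table$clonotype, table$cluster),
                 function(cl) mean(cl %in% top), numeric(1L))
  attr(frac, "topClonotypes") <- top
  frac
}
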