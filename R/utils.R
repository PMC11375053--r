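#' @import methods
#' @importFrom Matrix colSums rowSums rowMeans colMeans t Diagonal sparseMatrix
#' @importFrom stats rnbinom rnorm runif rbeta rbinom rexp quantile sd
#'   prcomp wilcox.test p.adjust t.test hclust cutree dist pchisq uniroot
#'   median IQR setNames aggregate
NULL

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
withSeed <- function(seed, code) {
  force(seed)  # evaluate before snapshotting: the promise may use the RNG
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Extract a gene x unit matrix from a matrix-like object or a
# SummarizedExperiment carrying the named assay.
getAssay <- function(x, layer = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    if (is.null(layer)) layer <- nm[1L]
    if (!layer %in% nm) {
      stop("assay '", layer, "' not found; available: ",
           paste(nm, collapse = ", "))
    }
    return(SummarizedExperiment::assay(x, layer))
  }
  x
}

# Column-wise z-standardisation; errors on constant columns.
zScoreColumns <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2L, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("cannot z-standardise: constant score column(s): ",
         paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)
}

#' Circular correlation between two angle vectors
#'
#' Fisher--Lee circular correlation coefficient, invariant to rotating
#' either set of angles by a constant. A reflection of one axis flips the
#' sign, so take the absolute value when orientation is arbitrary (as for
#' PCA-derived angles).
#'
#' @param theta,phi numeric vectors of angles in radians, equal length.
#' @return a single correlation value in \[-1, 1\].
#' @export
circularCorrelation <- function(theta, phi) {
  stopifnot(length(theta) == length(phi), length(theta) >= 3L)
  s1 <- sin(outer(theta, theta, "-"))
  s2 <- sin(outer(phi, phi, "-"))
  num <- sum(s1[lower.tri(s1)] * s2[lower.tri(s2)])
  den <- sqrt(sum(s1[lower.tri(s1)]^2) * sum(s2[lower.tri(s2)]^2))
  if (den == 0) return(NA_real_)
  num / den
}
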