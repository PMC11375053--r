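#' Quality-control thresholds for cells or spots
#'
#' Default values retain units with at least 1001 total UMIs, at least 501
#' detected genes, and at most 25% of UMIs assigned to mitochondrial
#' genes (units strictly below 1001 UMIs, below 501 genes, or strictly
#' over 25% mitochondrial are removed).
#'
#' @param minUMIs minimum total UMI count retained.
#' @param minGenes minimum number of detected genes retained.
#' @param maxMitoFrac maximum mitochondrial UMI fraction retained.
#' @return a named list of thresholds.
#' @export
qcThresholds <- function(minUMIs = 1001, minGenes = 501, maxMitoFrac = 0.25) {
  stopifnot(minUMIs > 0, minGenes > 0, maxMitoFrac > 0)
  list(minUMIs = minUMIs, minGenes = minGenes, maxMitoFrac = maxMitoFrac)
}

#' Filter low-quality cells or spots from a count matrix
#'
#' Keeps exactly the units satisfying all three rules of
#' [qcThresholds()]. Mitochondrial genes are identified either by an
#' explicit gene set or by name prefix (default `"MT-"`); with no
#' mitochondrial genes present the mitochondrial fraction is 0 for every
#' unit.
#'
#' @param counts gene x unit count matrix (dense, sparse, or a
#'   SummarizedExperiment with a `counts` assay).
#' @param mitoGenes character vector of mitochondrial gene ids, or `NULL`
#'   to use `mitoPrefix`.
#' @param thresholds list from [qcThresholds()].
#' @param mitoPrefix prefixes marking mitochondrial genes when
#'   `mitoGenes` is `NULL`.
#' @return the filtered count matrix, with an attribute `"removed"`
#'   giving the number of units failing each rule (a unit may fail
#'   several) and the total removed.
#' @examples
#' m <- matrix(rpois(2000, 5), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("c", 1:200)))
#' f <- qcFilter(m, thresholds = qcThresholds(minUMIs = 40, minGenes = 5))
#' attr(f, "removed")
#' @export
qcFilter <- function(counts, mitoGenes = NULL, thresholds = qcThresholds(),
                     mitoPrefix = "MT-") {
  m <- getAssay(counts, "counts")
  neg <- if (methods::is(m, "sparseMatrix")) any(m@x < 0) else any(m < 0)
  if (isTRUE(neg)) stop("counts must be non-negative")
  if (ncol(m) == 0L) return(m)
  umis <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  if (is.null(mitoGenes)) {
    pat <- paste0("^(", paste(mitoPrefix, collapse = "|"), ")")
    mitoGenes <- grep(pat, rownames(m), value = TRUE)
  } else {
    mitoGenes <- intersect(mitoGenes, rownames(m))
  }
  mitoFrac <- if (length(mitoGenes)) {
    mf <- Matrix::colSums(m[mitoGenes, , drop = FALSE]) / umis
    mf[umis == 0] <- 0
    mf
  } else rep(0, ncol(m))
  failUMI <- umis < thresholds$minUMIs
  failGene <- ngene < thresholds$minGenes
  failMito <- mitoFrac > thresholds$maxMitoFrac
  keep <- !(failUMI | failGene | failMito)
  out <- m[, keep, drop = FALSE]
  if (ncol(out) == 0L) warning("all units removed by QC filtering")
  attr(out, "removed") <- c(lowUMIs = sum(failUMI), fewGenes = sum(failGene),
                            highMito = sum(failMito), total = sum(!keep))
  out
}

#' Log-normalise a count matrix
#'
#' Per-unit library-size normalisation followed by a natural-log
#' transform: `ln(1 + count * scaleFactor / unitTotal)`. Units with a zero
#' total are kept as all-zero columns with a warning.
#'
#' @param counts gene x unit count matrix.
#' @param scaleFactor library-size target (default 10,000).
#' @return a matrix of the same shape tagged with attribute
#'   `layer = "lognorm"`; sparsity is preserved.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
  stopifnot(scaleFactor > 0)
  m <- getAssay(counts, "counts")
  if (methods::is(m, "sparseMatrix")) {
    if (any(m@x < 0)) stop("counts must be non-negative")
  } else if (any(m < 0)) stop("counts must be non-negative")
  tot <- Matrix::colSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " unit(s) with zero total count left as all-zero")
    tot[zero] <- 1
  }
  if (methods::is(m, "sparseMatrix")) {
    out <- m %*% Matrix::Diagonal(x = scaleFactor / tot)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(m)
  } else {
    out <- log1p(sweep(m, 2L, tot, "/") * scaleFactor)
  }
  attr(out, "layer") <- "lognorm"
  out
}

#' Relative EBV DNA load by the Livak 2^-ddCt method
#'
#' Computes `2^-[(Ct_target - Ct_ref)_sample - (Ct_target - Ct_ref)_calibrator]`
#' per sample, then splits the cohort into high/low EBV-load groups at the
#' arithmetic mean of the relative values ("mean fold of difference").
#'
#' @param ct data.frame with columns `sample`, `ctTarget`, `ctRef`
#'   (cycle-threshold values for the viral target and the reference gene).
#' @param calibrator numeric length-2 vector `c(ctTarget, ctRef)` of the
#'   positive-control calibrator.
#' @return data.frame with columns `sample`, `relativeLoad`, `group`
#'   (high/low) and attribute `"cohortMean"`.
#' @examples
#' ddctEbvLoad(data.frame(sample = "s1", ctTarget = 25, ctRef = 20),
#'             calibrator = c(22, 20))
#' @export
ddctEbvLoad <- function(ct, calibrator) {
  if (missing(calibrator) || is.null(calibrator))
    stop("a calibrator (ctTarget, ctRef) is required")
  stopifnot(all(c("sample", "ctTarget", "ctRef") %in% colnames(ct)),
            length(calibrator) == 2L)
  vals <- c(ct$ctTarget, ct$ctRef, calibrator)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct$ctTarget - ct$ctRef) - (calibrator[1L] - calibrator[2L])
  rel <- 2^(-ddct)
  mu <- mean(rel)
  out <- data.frame(sample = ct$sample, relativeLoad = rel,
                    group = ifelse(rel > mu, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "cohortMean") <- mu
  out
}
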