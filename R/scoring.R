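#' Control-bin gene module score
#'
#' Mean expression of a gene set minus the mean of expression-matched
#' control genes, per cell or spot. All genes are ranked by their
#' dataset-average expression and cut into `nBins` equal-size bins; for
#' each signature gene, `nCtrl` control genes are sampled (without
#' replacement, excluding signature genes) from the gene's bin. The score
#' of a unit is the mean of its signature-gene expression minus the mean
#' over all sampled control genes. Bins with fewer than `nCtrl` eligible
#' genes are sampled with replacement (with a warning), falling back to
#' the whole non-signature gene universe if a bin holds no eligible gene.
#'
#' @param expr gene x unit log-normalised matrix (see [logNormalize()]).
#' @param genes character vector, the signature.
#' @param nBins number of average-expression bins (default 24).
#' @param nCtrl number of control genes sampled per signature gene
#'   (default 100).
#' @param seed integer seed controlling the control-gene draw.
#' @return named numeric vector of per-unit scores.
#' @export
moduleScore <- function(expr, genes, nBins = 24, nCtrl = 100, seed = 0) {
  m <- getAssay(expr, "lognorm")
  sig <- intersect(genes, rownames(m))
  if (length(sig) == 0L)
    stop("none of the signature genes are present in the matrix")
  avg <- Matrix::rowMeans(m)
  rk <- rank(avg, ties.method = "average")
  nBins <- min(nBins, nrow(m))
  bins <- cut(rk, breaks = nBins, labels = FALSE)
  names(bins) <- rownames(m)
  nonSig <- setdiff(rownames(m), sig)
  smallBin <- FALSE
  emptyBin <- FALSE
  ctrl <- withSeed(seed, {
    unlist(lapply(sig, function(g) {
      pool <- nonSig[bins[nonSig] == bins[[g]]]
      if (length(pool) >= nCtrl) {
        sample(pool, nCtrl)
      } else if (length(pool) > 0L) {
        smallBin <<- TRUE
        sample(pool, nCtrl, replace = TRUE)
      } else {
        emptyBin <<- TRUE
        sample(nonSig, nCtrl, replace = TRUE)
      }
    }), use.names = FALSE)
  })
  if (smallBin)
    warning("control bin smaller than nCtrl; sampling with replacement")
  if (emptyBin)
    warning("empty control bin; sampling all non-signature genes with replacement")
  sigMean <- Matrix::colMeans(m[sig, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(m[ctrl, , drop = FALSE])
  setNames(as.numeric(sigMean - ctrlMean), colnames(m))
}

#' Score several signatures at once
#'
#' Applies [moduleScore()] to every signature of a [SignatureSet-class]
#' (or named list), returning a unit x signature matrix.
#'
#' @inheritParams moduleScore
#' @param signatures a [SignatureSet-class] or named list of gene vectors.
#' @return numeric matrix, units in rows, signatures in columns.
#' @export
moduleScoreMatrix <- function(expr, signatures, nBins = 24, nCtrl = 100,
                              seed = 0) {
  sigs <- if (methods::is(signatures, "SignatureSet"))
    signatures@signatures else signatures
  out <- vapply(seq_along(sigs), function(i) {
    moduleScore(expr, sigs[[i]], nBins = nBins, nCtrl = nCtrl,
                seed = seed + i - 1L)
  }, numeric(ncol(getAssay(expr))))
  colnames(out) <- names(sigs)
  rownames(out) <- colnames(getAssay(expr))
  out
}

#' Single-sample GSEA enrichment score
#'
#' Rank-based running-sum enrichment of each gene set in each sample.
#' Genes are ranked per sample (average ranks on ties); walking the genes
#' in decreasing rank order, the score is the sum over all positions of
#' the weighted in-set empirical CDF minus the out-of-set CDF, with
#' in-set weights `|rank|^alpha`.
#'
#' @param expr gene x sample expression matrix (bulk or pseudo-bulk).
#' @param signatures [SignatureSet-class] or named list of gene vectors;
#'   each set must share at least one gene with the matrix and must not
#'   cover every gene.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param rescale if `TRUE`, divide all scores by the range of scores
#'   across the whole matrix (a common normalisation before comparing
#'   samples); default `FALSE`.
#' @return numeric matrix, samples in rows, signatures in columns.
#' @export
ssgseaScore <- function(expr, signatures, alpha = 0.25, rescale = FALSE) {
  m <- as.matrix(getAssay(expr))
  sigs <- if (methods::is(signatures, "SignatureSet"))
    signatures@signatures else signatures
  nGenes <- nrow(m)
  es <- matrix(NA_real_, nrow = ncol(m), ncol = length(sigs),
               dimnames = list(colnames(m), names(sigs)))
  sigIdx <- lapply(sigs, function(g) {
    idx <- which(rownames(m) %in% g)
    if (length(idx) == 0L) stop("signature has no overlap with the matrix")
    if (length(idx) == nGenes)
      stop("signature covers every gene; the complement is empty")
    idx
  })
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    rOrd <- r[ord]
    for (k in seq_along(sigIdx)) {
      inSet <- ord %in% sigIdx[[k]]
      w <- abs(rOrd)^alpha
      stepIn <- cumsum(w * inSet) / sum(w * inSet)
      stepOut <- cumsum(!inSet) / (nGenes - sum(inSet))
      es[j, k] <- sum(stepIn - stepOut)
    }
  }
  if (rescale) {
    rng <- range(es)
    if (diff(rng) > 0) es <- es / diff(rng)
  }
  es
}

#' Rank cluster marker genes by Wilcoxon test
#'
#' For each cluster, each gene is compared against all remaining units
#' with a two-sided Wilcoxon rank-sum test on log-normalised expression;
#' p-values are adjusted over genes (Bonferroni by default, matching the
#' single-cell convention of this analysis). Genes with adjusted p below
#' `alpha` and log2 fold-change of at least `minLog2FC` are retained,
#' sorted by decreasing fold-change. The log2 fold-change is the
#' difference of mean log-expression divided by `ln 2`.
#'
#' @param expr gene x unit log-normalised matrix.
#' @param labels cluster label per unit (length `ncol(expr)`); clusters
#'   with fewer than 3 units are excluded with a warning.
#' @param minLog2FC minimum average log2 fold-change (default 0.25).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param adjust p-value adjustment method (default `"bonferroni"`;
#'   `"BH"` available).
#' @return data.frame with columns `cluster`, `gene`, `log2FC`, `pValue`,
#'   `pAdj`, sorted by cluster then decreasing `log2FC`.
#' @export
rankMarkers <- function(expr, labels, minLog2FC = 0.25, alpha = 0.05,
                        adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  m <- as.matrix(getAssay(expr, "lognorm"))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  if (length(unique(labels)) < 2L) stop("at least two cluster labels required")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("excluding cluster(s) with fewer than 3 units: ",
            paste(small, collapse = ", "))
  }
  res <- lapply(setdiff(names(sizes), small), function(cl) {
    inCl <- labels == cl
    p <- apply(m, 1L, function(x) {
      suppressWarnings(wilcox.test(x[inCl], x[!inCl], exact = FALSE)$p.value)
    })
    lfc <- (rowMeans(m[, inCl, drop = FALSE]) -
              rowMeans(m[, !inCl, drop = FALSE])) / log(2)
    padj <- p.adjust(p, method = adjust)
    keep <- !is.na(padj) & padj < alpha & lfc >= minLog2FC
    if (!any(keep)) return(NULL)
    df <- data.frame(cluster = cl, gene = rownames(m)[keep],
                     log2FC = lfc[keep], pValue = p[keep], pAdj = padj[keep],
                     stringsAsFactors = FALSE)
    df[order(-df$log2FC), ]
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(cluster = character(), gene = character(),
                      log2FC = numeric(), pValue = numeric(),
                      pAdj = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Top-k marker signature per cluster
#'
#' Takes the first `k` genes per cluster from a [rankMarkers()] table
#' (which is sorted by fold-change) as that cluster's signature; clusters
#' with fewer than `k` markers contribute all of them, with a warning.
#'
#' @param markers data.frame from [rankMarkers()].
#' @param k number of genes per cluster signature (default 100).
#' @return a [SignatureSet-class], one signature per cluster.
#' @export
topKSignature <- function(markers, k = 100) {
  stopifnot(nrow(markers) > 0, k >= 1)
  sigs <- lapply(split(markers, markers$cluster), function(df) {
    if (nrow(df) < k) {
      warning(sprintf("cluster %s has only %d markers (< k = %d)",
                      df$cluster[1L], nrow(df), k))
    }
    utils::head(df$gene, k)
  })
  SignatureSet(sigs, setNames(rep("cluster-markers", length(sigs)),
                              names(sigs)))
}
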