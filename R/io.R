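#' Read a count matrix in MatrixMarket format
#'
#' Expects a directory (or explicit paths) with `matrix.mtx`,
#' `genes.tsv` and `barcodes.tsv` (one id per line, first column used).
#'
#' @param dir directory containing the three files, or `NULL` when paths
#'   are given explicitly.
#' @param mtx,genes,barcodes file paths (defaults relative to `dir`).
#' @return sparse gene x unit count matrix.
#' @export
readCountsMTX <- function(dir = NULL, mtx = file.path(dir, "matrix.mtx"),
                          genes = file.path(dir, "genes.tsv"),
                          barcodes = file.path(dir, "barcodes.tsv")) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  g <- utils::read.table(genes, sep = "\t", stringsAsFactors = FALSE)
  b <- utils::read.table(barcodes, sep = "\t", stringsAsFactors = FALSE)
  rownames(m) <- g[[1L]]
  colnames(m) <- b[[1L]]
  m
}

#' Write a count matrix in MatrixMarket format
#'
#' @param counts gene x unit matrix.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCountsMTX <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(getAssay(counts, "counts"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read gene signatures from a GMT file
#'
#' @param path GMT file path.
#' @param role role tag applied to every signature (default `"custom"`).
#' @return a [SignatureSet-class].
#' @export
readSignaturesGMT <- function(path, role = "custom") {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  SignatureSet(sets, setNames(rep(role, length(sets)), names(sets)))
}

#' Read gene signatures from a JSON file
#'
#' The JSON maps signature names either to gene arrays or to objects with
#' fields `genes` and optional `role`.
#'
#' @param path JSON file path.
#' @return a [SignatureSet-class].
#' @export
readSignaturesJSON <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigs <- lapply(raw, function(x) {
    if (is.list(x) && !is.null(x$genes)) as.character(x$genes)
    else as.character(x)
  })
  roles <- vapply(raw, function(x) {
    if (is.list(x) && !is.null(x$role)) as.character(x$role) else "custom"
  }, character(1L))
  SignatureSet(sigs, setNames(roles, names(sigs)))
}

#' Read a spot grid from CSV
#'
#' Columns: `spot`, `x`, `y` (micrometres) and optionally `platform`,
#' `pitch` (taken from the first row).
#'
#' @param path CSV file path.
#' @param platform,pitch used when the file lacks those columns.
#' @return a [SpotGrid-class].
#' @export
readSpotGridCSV <- function(path, platform = "visium-hex", pitch = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("platform" %in% colnames(df)) platform <- df$platform[1L]
  if ("pitch" %in% colnames(df)) pitch <- df$pitch[1L]
  SpotGrid(df$spot, df$x, df$y, platform = platform, pitch = pitch)
}

#' Write a spot grid to CSV
#' @param grid a [SpotGrid-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSpotGridCSV <- function(grid, path) {
  xy <- spotCoords(grid)
  utils::write.csv(data.frame(spot = spotIds(grid), x = xy[, 1L],
                              y = xy[, 2L], platform = gridPlatform(grid),
                              pitch = gridPitch(grid)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a compartment map to CSV
#'
#' One row per spot: region, TCA component id, component EBV class and
#' plasma flag.
#'
#' @param cmap a [CompartmentMap-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeCompartmentMapCSV <- function(cmap, path) {
  utils::write.csv(as.data.frame(cmap), path, row.names = FALSE)
  invisible(path)
}

#' Read a repertoire table from TSV
#'
#' @param path TSV path with a header row.
#' @param columns named map from the canonical column names (`cell`,
#'   `cluster`, `clonotype`, `isotype`, `shmFreq`, `sample`) to the file's
#'   column names; identity by default.
#' @return data.frame with the canonical columns that are present.
#' @export
readRepertoireTSV <- function(path, columns = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  canon <- c("cell", "cluster", "clonotype", "isotype", "shmFreq", "sample")
  if (is.null(columns)) columns <- setNames(canon, canon)
  out <- list()
  for (nm in names(columns)) {
    if (columns[[nm]] %in% colnames(df)) out[[nm]] <- df[[columns[[nm]]]]
  }
  if (is.null(out$clonotype) || is.null(out$cluster))
    stop("repertoire table needs cluster and clonotype columns")
  as.data.frame(out, stringsAsFactors = FALSE)
}
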