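#' Built-in gene signatures
#'
#' The gene lists printed in the study this package operationalises:
#' region markers for malignant, B and T cells used to call spatial
#' compartments in nasopharyngeal carcinoma, EBV-encoded transcripts, the
#' pan-immunoglobulin proxy for antibody production, the plasma-spot
#' genes, and the eleven immunosuppressive genes. Apoptosis, dark-zone /
#' light-zone and TLS cell-cluster signatures are study- or
#' cohort-specific (top-100 differential genes or cited panels) and must
#' be supplied by the user at run time.
#'
#' @return a [SignatureSet-class] with signatures `malignant`, `B`, `T`,
#'   `ebvEncoded`, `panIg`, `plasmaSpot`, `immunosuppressive`.
#' @examples
#' builtinSignatures()
#' @export
builtinSignatures <- function() {
  panIg <- c("IGHA1", "IGHA2", "IGHG1", "IGHG2", "IGHG3", "IGHG4")
  SignatureSet(
    list(
      malignant = c("EPCAM", "KRT13", "KRT8", "KRT5"),
      B = c("CD19", "MS4A1", "CD79A", "CD79B"),
      T = c("CD2", "CD3D", "CD3E", "CD3G", "CD7"),
      ebvEncoded = c("RPMS1", "A73", "BARF0", "BALF3", "BALF4",
                     "LMP-1", "BNLF2a", "BNLF2b", "LMP-2A", "LMP-2B",
                     "EBNA1", "EBNA2", "EBNA3A", "EBNA3B", "EBNA3C",
                     "EBNA-LP"),
      panIg = panIg,
      plasmaSpot = c("CD79A", "CD79B", "MZB1", "XBP1", panIg),
      immunosuppressive = c("CD47", "PVR", "CD276", "LGALS9", "ADORA2B",
                            "ADAM10", "HLA-G", "CD274", "FASLG", "TGFB1",
                            "IL10")
    ),
    roles = c(malignant = "malignant", B = "B", T = "T",
              ebvEncoded = "EBV", panIg = "pan-Ig", plasmaSpot = "plasma",
              immunosuppressive = "immunosuppressive")
  )
}

#' Names of the seven TLS-associated cell-cluster signatures
#'
#' The TLS cell signature (TLS-CS) stratification scores patients over
#' seven cell-cluster signatures: naive, memory and germinal-centre B
#' cells, plasma cells, CXCR5+ CD4 T cells, CXCL13+ CD8 T cells and
#' CXCL13+ inflammatory CAFs. Gene lists for these clusters are derived
#' per cohort (top differential genes), so only the canonical names are
#' fixed here.
#'
#' @return character vector of the seven signature names.
#' @export
tlsSignatureNames <- function() {
  c("Naive_B", "Memory_B", "GC_B", "Plasma",
    "CD4_C8_CXCR5", "CD8_C8_CXCL13", "iCAF_C2_CXCL13")
}
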