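#' SignatureSet: named gene lists with role tags
#'
#' Container for gene signatures used throughout the package: region
#' markers (malignant, B, T), EBV-encoded genes, plasma-spot genes, pan-Ig,
#' apoptosis and immunosuppressive modules, and TLS cell-cluster
#' signatures. Each signature is a non-empty character vector of unique
#' gene identifiers with a free-text role tag.
#'
#' @slot signatures named list of character vectors (gene ids).
#' @slot roles named character vector, same names as `signatures`.
#' @export
setClass("SignatureSet",
  representation(signatures = "list", roles = "character"))

setValidity("SignatureSet", function(object) {
  sig <- object@signatures
  if (length(sig) == 0L) return("at least one signature required")
  if (is.null(names(sig)) || anyDuplicated(names(sig)) || any(names(sig) == ""))
    return("signatures must have unique non-empty names")
  for (nm in names(sig)) {
    g <- sig[[nm]]
    if (!is.character(g) || length(g) == 0L)
      return(sprintf("signature '%s' must be a non-empty character vector", nm))
    if (anyDuplicated(g))
      return(sprintf("signature '%s' contains duplicated genes", nm))
  }
  if (!identical(sort(names(object@roles)), sort(names(sig))))
    return("roles must be named for exactly the signatures present")
  TRUE
})

#' Construct a SignatureSet
#'
#' @param signatures named list of character vectors of gene ids.
#' @param roles named character vector of role tags; defaults to
#'   `"custom"` for every signature.
#' @return a [SignatureSet-class] object.
#' @examples
#' ss <- SignatureSet(list(B = c("CD19", "MS4A1")), c(B = "B"))
#' geneIds(ss, "B")
#' @export
SignatureSet <- function(signatures, roles = NULL) {
  if (is.null(roles)) {
    roles <- setNames(rep("custom", length(signatures)), names(signatures))
  }
  methods::new("SignatureSet", signatures = signatures, roles = roles[names(signatures)])
}

#' @describeIn SignatureSet-class signature names.
#' @param x a `SignatureSet`.
#' @export
setMethod("names", "SignatureSet", function(x) names(x@signatures))

#' @describeIn SignatureSet-class number of signatures.
#' @export
setMethod("length", "SignatureSet", function(x) length(x@signatures))

#' Gene ids of one signature
#' @param x a [SignatureSet-class].
#' @param name signature name.
#' @return character vector of gene ids.
#' @export
geneIds <- function(x, name) {
  stopifnot(methods::is(x, "SignatureSet"))
  if (!name %in% names(x)) stop("no signature named '", name, "'")
  x@signatures[[name]]
}

#' Role tags of the signatures
#' @param x a [SignatureSet-class].
#' @return named character vector of roles.
#' @export
signatureRoles <- function(x) x@roles

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet with", length(object), "signature(s)\n")
  for (nm in names(object)) {
    g <- object@signatures[[nm]]
    cat(sprintf("  %s [%s]: %d genes (%s%s)\n", nm, object@roles[[nm]],
                length(g), paste(utils::head(g, 4L), collapse = ", "),
                if (length(g) > 4L) ", ..." else ""))
  }
})

#' SpotGrid: spot identifiers with planar coordinates
#'
#' Positions of spatial capture units in micrometres together with the
#' platform geometry. The Visium hexagonal lattice has a 100 micron
#' centre-to-centre pitch; Stereo-seq bin100 units form a square lattice
#' of roughly 49.72 micron pitch (raw Stereo-seq spots sit 0.5 micron
#' apart).
#'
#' @slot spotIds character, unique spot identifiers.
#' @slot coords numeric matrix (n x 2), columns x and y in micrometres.
#' @slot platform one of `"visium-hex"`, `"stereo-bin"`, `"stereo-raw"`,
#'   `"square"`.
#' @slot pitch centre-to-centre distance in micrometres.
#' @export
setClass("SpotGrid",
  representation(spotIds = "character", coords = "matrix",
                 platform = "character", pitch = "numeric"))

setValidity("SpotGrid", function(object) {
  if (anyDuplicated(object@spotIds)) return("spot ids must be unique")
  if (nrow(object@coords) != length(object@spotIds))
    return("coords must have one row per spot")
  if (ncol(object@coords) != 2L) return("coords must have columns x, y")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
    return("pitch must be a single positive number")
  if (!object@platform %in% c("visium-hex", "stereo-bin", "stereo-raw", "square"))
    return("unknown platform")
  TRUE
})

#' Construct a SpotGrid
#' @param spotIds character vector of unique spot ids.
#' @param x,y numeric coordinates in micrometres.
#' @param platform platform tag (see [SpotGrid-class]).
#' @param pitch centre-to-centre distance in micrometres.
#' @return a [SpotGrid-class] object.
#' @export
SpotGrid <- function(spotIds, x, y, platform = "visium-hex", pitch = 100) {
  methods::new("SpotGrid", spotIds = as.character(spotIds),
               coords = cbind(x = as.numeric(x), y = as.numeric(y)),
               platform = platform, pitch = as.numeric(pitch))
}

#' @describeIn SpotGrid-class spot identifiers.
#' @param x a `SpotGrid`.
#' @export
spotIds <- function(x) x@spotIds

#' @describeIn SpotGrid-class coordinate matrix (micrometres).
#' @export
spotCoords <- function(x) {
  out <- x@coords
  rownames(out) <- x@spotIds
  out
}

#' @describeIn SpotGrid-class platform tag.
#' @export
gridPlatform <- function(x) x@platform

#' @describeIn SpotGrid-class centre-to-centre pitch in micrometres.
#' @export
gridPitch <- function(x) x@pitch

setMethod("length", "SpotGrid", function(x) length(x@spotIds))

setMethod("show", "SpotGrid", function(object) {
  cat(sprintf("SpotGrid: %d spots, platform %s, pitch %.4g um\n",
              length(object), object@platform, object@pitch))
})

#' CompartmentMap: spot regions and TCA component classes
#'
#' Result of compartment calling: a region label per spot
#' (TLS/TCA/stroma), a connected-component id for every TCA spot, and a
#' per-component EBV class (high/mid/low, quartiles of an EBV signature)
#' plus a plasma co-occurrence flag (wP/woP).
#'
#' @slot region named factor per spot with levels TLS, TCA, stroma.
#' @slot componentId named integer per spot; `NA` outside TCA.
#' @slot componentClass data.frame with columns `component`, `ebvClass`,
#'   `plasmaFlag`.
#' @export
setClass("CompartmentMap",
  representation(region = "factor", componentId = "integer",
                 componentClass = "data.frame"))

setValidity("CompartmentMap", function(object) {
  if (!all(levels(object@region) %in% c("TLS", "TCA", "stroma")))
    return("region levels must be TLS, TCA, stroma")
  if (length(object@componentId) != length(object@region))
    return("componentId must align with region")
  isTCA <- object@region == "TCA"
  if (any(!is.na(object@componentId[!isTCA])))
    return("component ids are only defined on TCA spots")
  if (any(is.na(object@componentId[isTCA])))
    return("every TCA spot must belong to exactly one component")
  comps <- sort(unique(object@componentId[isTCA]))
  cc <- object@componentClass
  if (length(comps) > 0L) {
    need <- c("component", "ebvClass", "plasmaFlag")
    if (!all(need %in% colnames(cc)))
      return("componentClass needs columns component, ebvClass, plasmaFlag")
    if (!setequal(cc$component, comps))
      return("EBV class and plasma flag must be defined for every component")
    if (!all(cc$ebvClass %in% c("high", "mid", "low")))
      return("ebvClass must be high/mid/low")
    if (!all(cc$plasmaFlag %in% c("wP", "woP")))
      return("plasmaFlag must be wP/woP")
  }
  TRUE
})

#' @describeIn CompartmentMap-class per-spot region labels (named factor).
#' @param x a `CompartmentMap`.
#' @export
regionLabels <- function(x) x@region

#' @describeIn CompartmentMap-class per-spot TCA component ids (named
#'   integer, `NA` off TCA).
#' @export
componentIds <- function(x) x@componentId

#' @describeIn CompartmentMap-class per-component EBV class and plasma
#'   flag.
#' @export
componentClasses <- function(x) x@componentClass

setMethod("show", "CompartmentMap", function(object) {
  tab <- table(object@region)
  cat("CompartmentMap:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cc <- object@componentClass
  if (nrow(cc)) {
    cat(sprintf("  %d TCA component(s): %s\n", nrow(cc),
                paste(sprintf("%s-%s", cc$ebvClass, cc$plasmaFlag),
                      collapse = ", ")))
  }
})

#' Convert a CompartmentMap to a per-spot data.frame
#'
#' One row per spot with region, component id, and the component's EBV
#' class and plasma flag (NA outside TCA).
#'
#' @param x a [CompartmentMap-class].
#' @param ... unused.
#' @return data.frame with columns spot, region, component, ebvClass,
#'   plasmaFlag.
#' @export
setMethod("as.data.frame", "CompartmentMap", function(x, ...) {
  cc <- x@componentClass
  idx <- match(x@componentId, cc$component)
  data.frame(spot = names(x@region), region = as.character(x@region),
             component = x@componentId,
             ebvClass = cc$ebvClass[idx], plasmaFlag = cc$plasmaFlag[idx],
             row.names = NULL, stringsAsFactors = FALSE)
})

#' GCEmbedding: germinal-centre polar embedding
#'
#' Per-cell principal components, polar radius and angle of the
#' germinal-centre B cell embedding, plus the radial offset used.
#'
#' @slot cells data.frame with columns PC1, PC2, rho, theta.
#' @slot offset radial offset constant added to the raw radius.
#' @export
setClass("GCEmbedding",
  representation(cells = "data.frame", offset = "numeric"))

setValidity("GCEmbedding", function(object) {
  need <- c("PC1", "PC2", "rho", "theta")
  if (!all(need %in% colnames(object@cells)))
    return("cells needs columns PC1, PC2, rho, theta")
  th <- object@cells$theta
  if (any(th < 0 | th >= 2 * pi)) return("theta must lie in [0, 2*pi)")
  if (any(object@cells$rho < object@offset - 1e-8))
    return("rho must be at least the radial offset")
  TRUE
})

#' @describeIn GCEmbedding-class per-cell embedding table.
#' @param x a `GCEmbedding`.
#' @export
embeddingTable <- function(x) x@cells

#' @describeIn GCEmbedding-class radial offset constant.
#' @export
radialOffset <- function(x) x@offset

setMethod("show", "GCEmbedding", function(object) {
  cat(sprintf("GCEmbedding: %d cells, radial offset %.4g\n",
              nrow(object@cells), object@offset))
})
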