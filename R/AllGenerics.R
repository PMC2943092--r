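#' Pixel matrix of an image object
#' @param x a FundusImage
#' @return numeric matrix
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Binary mask of a centerline image
#' @param x a CenterlineImage
#' @return logical matrix
#' @export
setGeneric("mask", function(x) standardGeneric("mask"))

#' Node table of a vascular graph
#' @param x a VascularGraph
#' @return data.frame of nodes
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Edge table of a vascular graph
#' @param x a VascularGraph
#' @return data.frame of edges
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Apply a geometric transform to points
#'
#' @param transform a SimilarityTransform or QuadraticTransform
#' @param points n x 2 matrix of 0-based (row, col) coordinates
#' @return n x 2 matrix of transformed coordinates
#' @export
setGeneric("applyTransform",
  function(transform, points) standardGeneric("applyTransform"))

#' Invert a geometric transform
#'
#' For a SimilarityTransform the inverse is closed form.  For a
#' QuadraticTransform the inverse is evaluated pointwise by Newton iteration
#' (the map must be locally invertible over the queried domain), so the
#' inverse is returned as a function of a point matrix rather than an object.
#'
#' @param transform the transform to invert
#' @param ... further arguments for methods
#' @return a SimilarityTransform, or a function(points) for quadratic maps
#' @export
setGeneric("invertTransform",
  function(transform, ...) standardGeneric("invertTransform"))

#' Matched pairs of a correspondence set
#' @param x a CorrespondenceSet
#' @return data.frame with columns g1, g2, confidence
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @describeIn pixels method for FundusImage
#' @export
setMethod("pixels", "FundusImage", function(x) x@pixels)

#' @describeIn mask method for CenterlineImage
#' @export
setMethod("mask", "CenterlineImage", function(x) x@mask)

#' @describeIn nodes method for VascularGraph
#' @export
setMethod("nodes", "VascularGraph", function(x) x@nodes)

#' @describeIn edges method for VascularGraph
#' @export
setMethod("edges", "VascularGraph", function(x) x@edges)

#' @describeIn matchedPairs method for CorrespondenceSet
#' @export
setMethod("matchedPairs", "CorrespondenceSet", function(x) x@pairs)

setMethod("show", "FundusImage", function(object) {
  cat(sprintf("FundusImage %d x %d (%s channel), range [%.3f, %.3f]\n",
              nrow(object@pixels), ncol(object@pixels), object@channel,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "CenterlineImage", function(object) {
  cat(sprintf("CenterlineImage %d x %d, %d foreground px%s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              if (object@guaranteedThin) " (thin)" else ""))
})

setMethod("show", "VascularGraph", function(object) {
  cat(sprintf("VascularGraph: %d nodes (%d bifurcations), %d edges\n",
              nrow(object@nodes),
              sum(object@nodes$kind == "bifurcation"),
              nrow(object@edges)))
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: scale %.4f, rotation %.2f deg, t = (%.2f, %.2f)\n",
    object@scale, object@rotation * 180 / pi,
    object@translation[1], object@translation[2]))
})

setMethod("show", "QuadraticTransform", function(object) {
  cat("QuadraticTransform, coefficients (row; col):\n")
  print(signif(object@coeffs, 6))
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet (%s): %d pairs\n",
              object@method, nrow(object@pairs)))
})

setMethod("show", "RegistrationReport", function(object) {
  cat(sprintf(
    "RegistrationReport: status=%s CEM=%.3f px, NCC=%.4f, NMI=%.4f, overlap=%.1f%%, %s\n",
    object@status, object@cem, object@ncc, object@nmi, object@overlapPct,
    if (isTRUE(object@success)) "success" else "failure"))
})
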