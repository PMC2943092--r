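#' @import methods
NULL

#' FundusImage: a 2-D intensity grid
#'
#' Container for a single-channel fundus photograph (or any 2-D grayscale
#' raster) with intensities normalized to \code{[0,1]}.  Pixel coordinates are
#' 0-based \code{(row, col)} with pixel centers at integer positions.
#'
#' @slot pixels numeric matrix of intensities in \code{[0,1]}
#' @slot channel character, which source channel the grid came from
#'   (\code{"green"} for RGB fundus input by default, \code{"gray"} otherwise)
#' @export
setClass("FundusImage",
  representation(pixels = "matrix", channel = "character"),
  prototype(channel = "gray"))

setValidity("FundusImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 32 || ncol(p) < 32) return("image must be at least 32 x 32")
  if (any(!is.finite(p))) return("intensities must be finite")
  if (min(p) < 0 || max(p) > 1) return("intensities must lie in [0,1]")
  TRUE
})

#' ResponseImage: oriented matched-filter responses
#'
#' Per-pixel maximum of the matched-filter response over an orientation bank,
#' together with the winning orientation index.
#'
#' @slot responses numeric matrix, max response over orientations
#' @slot orientationIndex integer matrix, 1-based index into \code{angles}
#' @slot angles numeric vector of bank orientations (degrees, in [0,180))
#' @export
setClass("ResponseImage",
  representation(responses = "matrix", orientationIndex = "matrix",
                 angles = "numeric"))

setValidity("ResponseImage", function(object) {
  if (!all(dim(object@responses) == dim(object@orientationIndex)))
    return("responses and orientationIndex must have the same shape")
  if (any(!is.finite(object@responses))) return("responses must be finite")
  TRUE
})

#' CenterlineImage: a binary vessel skeleton
#'
#' @slot mask logical matrix of foreground (vessel) pixels
#' @slot guaranteedThin logical; when TRUE the mask is a one-pixel-wide
#'   8-connected skeleton
#' @export
setClass("CenterlineImage",
  representation(mask = "matrix", guaranteedThin = "logical"),
  prototype(guaranteedThin = FALSE))

setValidity("CenterlineImage", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  TRUE
})

#' VascularGraph: attributed undirected vascular structure graph
#'
#' Nodes are vessel bifurcations and segment endpoints; edges are vessel
#' segments carrying the vessel path distance \code{dvp}, the Euclidean
#' endpoint distance \code{de} and their scale-normalized versions
#' \code{a1}, \code{a2} (each normalized by its mean over edges, so the mean
#' of \code{a1} and of \code{a2} is exactly 1).
#'
#' @slot nodes data.frame with columns id, row, col, degree, kind
#' @slot edges data.frame with columns from, to, dvp, de, a1, a2 and a
#'   list-column \code{path} of n x 2 matrices of skeleton coordinates
#' @slot sourceShape integer(2), dimensions of the source image
#' @export
setClass("VascularGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 sourceShape = "integer"))

setValidity("VascularGraph", function(object) {
  n <- object@nodes; e <- object@edges
  if (nrow(e) > 0) {
    if (!all(c(e$from, e$to) %in% n$id)) return("edge endpoints must exist")
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$dvp + 1e-9 < e$de)) return("dvp must be >= de")
    if (any(e$de <= 0)) return("de must be > 0")
    if (!is.null(e$a1) && !anyNA(e$a1) && !anyNA(e$a2)) {
      if (abs(mean(e$a1) - 1) > 1e-9 || abs(mean(e$a2) - 1) > 1e-9)
        return("a1 and a2 must each average to 1 over edges")
    }
  }
  TRUE
})

#' SimilarityTransform: scale + rotation + translation in the image plane
#'
#' Maps a 0-based (row, col) point p to
#' \code{scale * R(rotation) \%*\% p + translation}.
#'
#' @slot scale positive scale factor
#' @slot rotation rotation angle in radians
#' @slot translation numeric(2), (drow, dcol) in pixels
#' @export
setClass("SimilarityTransform",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric"),
  prototype(scale = 1, rotation = 0, translation = c(0, 0)))

setValidity("SimilarityTransform", function(object) {
  if (object@scale <= 0) return("scale must be positive")
  if (length(object@translation) != 2) return("translation must be length 2")
  TRUE
})

#' QuadraticTransform: 12-parameter second-order polynomial map
#'
#' Maps (r, c) to the pair of quadratic polynomials with monomial basis
#' \code{(r^2, c^2, r*c, r, c, 1)}; \code{coeffs[1, ]} produces the output
#' row and \code{coeffs[2, ]} the output column.  With the three quadratic
#' coefficients of each row equal to zero the map is exactly affine.
#'
#' @slot coeffs numeric 2 x 6 coefficient matrix
#' @export
setClass("QuadraticTransform",
  representation(coeffs = "matrix"))

setValidity("QuadraticTransform", function(object) {
  if (!all(dim(object@coeffs) == c(2, 6))) return("coeffs must be 2 x 6")
  if (any(!is.finite(object@coeffs))) return("coeffs must be finite")
  TRUE
})

#' CorrespondenceSet: one-to-one node matches between two graphs
#'
#' @slot pairs data.frame with columns g1, g2 (node ids) and confidence
#' @slot method provenance tag ("graduated-assignment", "struct-sac", ...)
#' @export
setClass("CorrespondenceSet",
  representation(pairs = "data.frame", method = "character"))

setValidity("CorrespondenceSet", function(object) {
  p <- object@pairs
  if (anyDuplicated(p$g1) || anyDuplicated(p$g2))
    return("correspondences must be one-to-one")
  TRUE
})

#' RegistrationReport: assessment of one registered image pair
#'
#' @slot cem vessel centerline error measure in pixels (median distance over
#'   corresponding centerline points; NA when undefined)
#' @slot ncc normalized (Pearson) correlation coefficient over the overlap
#' @slot nmi normalized mutual information over the overlap
#' @slot success logical, TRUE iff cem < the success threshold (3.0 px)
#' @slot overlapPct percentage of reference pixels mapped from inside the
#'   floating image domain
#' @slot runtime seconds
#' @slot status "ok" or a failure tag (segmentation_failure,
#'   no_stable_structures, icp_divergence, undefined_cem)
#' @export
setClass("RegistrationReport",
  representation(cem = "numeric", ncc = "numeric", nmi = "numeric",
                 success = "logical", overlapPct = "numeric",
                 runtime = "numeric", status = "character"),
  prototype(cem = NA_real_, ncc = NA_real_, nmi = NA_real_,
            success = FALSE, overlapPct = NA_real_, runtime = NA_real_,
            status = "ok"))
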