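# Registration assessment: vessel centerline error measure (CEM, the median
# distance over corresponding centerline points after registration; success
# means CEM < 3.0 px), normalized correlation, normalized mutual
# information and the image-overlap percentage.

#' Vessel centerline error measure
#'
#' Median of \code{|p - T(q)|} over the mutual-nearest-neighbour
#' correspondence set (within \code{gate} pixels) between the reference
#' centerline and the transformed floating centerline.
#'
#' @param refCenterline n x 2 reference centerline points
#' @param floatCenterline m x 2 floating centerline points
#' @param transform transform mapping floating points into the reference
#'   frame
#' @param gate correspondence gating radius in pixels
#' @return the CEM in pixels
#' @export
cem <- function(refCenterline, floatCenterline, transform, gate = 10) {
  p <- matrix(as.numeric(refCenterline), ncol = 2)
  q <- applyTransform(transform, matrix(as.numeric(floatCenterline),
                                        ncol = 2))
  mn <- mutualNearest(p, q, gate)
  if (nrow(mn) == 0L)
    stop(errorCondition("no corresponding centerline points within gate",
                        class = c("fundusregUndefinedCem",
                                  "error", "condition")))
  stats::median(mn$dist)
}

#' Registration success rule
#'
#' @param cemValue CEM in pixels (NA counts as failure)
#' @param threshold success threshold in pixels (default 3.0, strict)
#' @return logical
#' @export
registrationSuccess <- function(cemValue, threshold = 3.0) {
  !is.na(cemValue) & cemValue < threshold
}

#' Normalized correlation coefficient over an overlap region
#'
#' Pearson correlation of the two intensity grids restricted to the mask.
#'
#' @param ref,warpedFloat FundusImage objects or matrices of equal shape
#' @param maskRegion logical matrix selecting the overlap
#' @return value in [-1, 1]
#' @export
ncc <- function(ref, warpedFloat, maskRegion = NULL) {
  a <- if (is(ref, "FundusImage")) pixels(ref) else ref
  b <- if (is(warpedFloat, "FundusImage")) pixels(warpedFloat) else warpedFloat
  if (is.null(maskRegion)) maskRegion <- matrix(TRUE, nrow(a), ncol(a))
  x <- a[maskRegion]; y <- b[maskRegion]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(errorCondition("zero-variance overlap region",
                        class = c("fundusregUndefinedMetric",
                                  "error", "condition")))
  stats::cor(x, y)
}

#' Normalized mutual information over an overlap region
#'
#' Joint-histogram estimate over \code{bins} equal-width bins.  The
#' \code{"sum"} variant reports \code{(H(A) + H(B)) / H(A, B)} (2 for
#' identical images); the \code{"normalized"} variant reports
#' \code{2 I(A; B) / (H(A) + H(B))} in [0, 1].
#'
#' @param ref,warpedFloat FundusImage objects or matrices
#' @param maskRegion logical overlap mask
#' @param bins histogram bins per axis
#' @param variant "sum" or "normalized"
#' @return the NMI value
#' @export
nmi <- function(ref, warpedFloat, maskRegion = NULL, bins = 64L,
                variant = c("sum", "normalized")) {
  variant <- match.arg(variant)
  a <- if (is(ref, "FundusImage")) pixels(ref) else ref
  b <- if (is(warpedFloat, "FundusImage")) pixels(warpedFloat) else warpedFloat
  if (is.null(maskRegion)) maskRegion <- matrix(TRUE, nrow(a), ncol(a))
  x <- a[maskRegion]; y <- b[maskRegion]
  if (length(x) == 0)
    stop(errorCondition("empty overlap region",
                        class = c("fundusregUndefinedMetric",
                                  "error", "condition")))
  bx <- pmin(pmax(1L, ceiling(x * bins)), bins)
  by <- pmin(pmax(1L, ceiling(y * bins)), bins)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  pj <- joint / sum(joint)
  px <- tapply(pj, rep(seq_len(bins), each = bins), sum)
  py <- tapply(pj, rep(seq_len(bins), times = bins), sum)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py); hxy <- ent(pj)
  if (variant == "sum") (hx + hy) / hxy else 2 * (hx + hy - hxy) / (hx + hy)
}

#' Percentage of the reference frame covered by the floating image
#'
#' Fraction of reference-frame pixels whose pre-image under the transform
#' (floating -> reference) lies inside the floating image bounds.
#'
#' @param refShape integer(2), reference image dimensions (rows, cols)
#' @param transform the registration transform (floating -> reference)
#' @param floatShape integer(2), floating image dimensions (defaults to
#'   refShape)
#' @param stride evaluation stride in pixels (1 = every pixel)
#' @return overlap percentage in [0, 100]
#' @export
overlapPct <- function(refShape, transform, floatShape = refShape,
                       stride = 2L) {
  rs <- seq(0, refShape[1] - 1, by = stride)
  cs <- seq(0, refShape[2] - 1, by = stride)
  g <- as.matrix(expand.grid(row = rs, col = cs))
  inv <- if (is(transform, "SimilarityTransform")) {
    ti <- invertTransform(transform)
    applyTransform(ti, g)
  } else {
    invertTransform(transform)(g)
  }
  inside <- inv[, 1] >= 0 & inv[, 1] <= floatShape[1] - 1 &
    inv[, 2] >= 0 & inv[, 2] <= floatShape[2] - 1
  100 * mean(inside)
}

#' Resample the floating image into the reference frame
#'
#' Inverse warping: each reference pixel samples the floating image at its
#' pre-image under the transform (bilinear).  Pixels mapping outside the
#' floating domain are set to \code{fill} and excluded from the returned
#' overlap mask, which is eroded to suppress border interpolation
#' artifacts.
#'
#' @param floatImage a FundusImage (the floating image)
#' @param transform floating -> reference transform
#' @param refShape output (reference) dimensions
#' @param fill fill value outside the overlap
#' @param erodePx erosion of the overlap mask in pixels
#' @return list with \code{image} (FundusImage) and \code{mask} (logical)
#' @export
warpToReference <- function(floatImage, transform, refShape,
                            fill = 0, erodePx = 2L) {
  m <- pixels(floatImage)
  g <- as.matrix(expand.grid(row = seq_len(refShape[1]) - 1,
                             col = seq_len(refShape[2]) - 1))
  inv <- if (is(transform, "SimilarityTransform")) {
    applyTransform(invertTransform(transform), g)
  } else {
    invertTransform(transform)(g)
  }
  inside <- inv[, 1] >= 0 & inv[, 1] <= nrow(m) - 1 &
    inv[, 2] >= 0 & inv[, 2] <= ncol(m) - 1
  val <- rep(fill, nrow(g))
  if (any(inside))
    val[inside] <- bilinearSample(m, inv[inside, 1], inv[inside, 2])
  img <- matrix(val, refShape[1], refShape[2])
  msk <- matrix(inside, refShape[1], refShape[2])
  if (erodePx > 0 && any(msk)) {
    kern <- EBImage::makeBrush(2L * erodePx + 1L, shape = "box")
    msk <- as.matrix(EBImage::erode(msk * 1, kern)) > 0.5
  }
  list(image = FundusImage(clamp01(img)), mask = msk)
}
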