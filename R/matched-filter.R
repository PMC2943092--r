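# Oriented second-order Gaussian-Hermite matched filtering.
#
# The vessel cross-section is modelled by the 1-D kernel
#   H(x) = (1 + a (x^2 - 1)) * (1 / sqrt(2 pi sigma^2)) * exp(-x^2 / (2 sigma^2))
# with x in pixels; a = 0 recovers the plain Gaussian, a > 0 adds the
# second-order Hermite term that accounts for the central light reflection
# seen on wide vessels.  At each orientation the 2-D filtering separates into
# two 1-D convolutions: the analytic second derivative H_vv across the vessel
# followed by the smoothing kernel H along it, applied in a coordinate frame
# rotated so the orientation under test is horizontal.

#' Sampled second-order Gaussian-Hermite kernel
#'
#' @param a dimensionless Hermite weight (0 gives a pure Gaussian)
#' @param sigma kernel scale in pixels; must be positive
#' @param halfwidth support half-length in pixels; defaults to
#'   \code{ceiling(3 * sigma)}
#' @param zeroMeanHvv subtract the sample mean from the sampled second
#'   derivative so that flat image regions yield exactly zero response
#'   (truncation of the support otherwise leaves a small residual)
#' @return list with \code{x} (integer offsets), \code{h} (kernel samples)
#'   and \code{hvv} (analytic second-derivative samples)
#' @export
gaussianHermiteKernel <- function(a, sigma, halfwidth = ceiling(3 * sigma),
                                  zeroMeanHvv = FALSE) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (halfwidth < 1) stop("halfwidth must be at least 1")
  x <- seq.int(-halfwidth, halfwidth)
  phi <- exp(-x^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
  p <- 1 + a * (x^2 - 1)
  h <- p * phi
  # H'' = [P'' + 2 P' phi'/phi + P phi''/phi] phi with P = 1 + a(x^2 - 1)
  hvv <- (2 * a - 4 * a * x^2 / sigma^2 +
            p * (x^2 - sigma^2) / sigma^4) * phi
  if (zeroMeanHvv) hvv <- hvv - mean(hvv)
  list(x = x, h = h, hvv = hvv)
}

#' Default matched-filter parameter set
#'
#' @param a Hermite weight
#' @param sigma cross-profile kernel scale (pixels)
#' @param sigmaAlong along-vessel smoothing scale (pixels); longer than the
#'   cross scale because vessels are locally straight over many pixels,
#'   which suppresses isolated noise without blurring the cross profile
#' @param halfwidth kernel support half-length (pixels)
#' @param nOrientations number of orientations covering [0, 180) degrees
#' @return list of parameters; \code{angleStep = 180 / nOrientations}
#' @export
matchedFilterParams <- function(a = 0.3, sigma = 1.5, sigmaAlong = 3,
                                halfwidth = ceiling(3 * sigma),
                                nOrientations = 12L) {
  if (sigma <= 0 || sigmaAlong <= 0) stop("sigma must be positive")
  if (halfwidth < ceiling(3 * sigma))
    stop("halfwidth must be at least ceiling(3 * sigma)")
  list(a = a, sigma = sigma, sigmaAlong = sigmaAlong,
       halfwidth = as.integer(halfwidth),
       nOrientations = as.integer(nOrientations),
       angleStep = 180 / nOrientations)
}

#' Matched-filter response at a single orientation
#'
#' The image coordinate frame is rotated by \code{theta} (bilinear
#' interpolation, reflected borders) so that structures oriented at
#' \code{theta} become horizontal; the zero-mean second-derivative kernel is
#' then applied across the structure and the smoothing kernel along it, and
#' the response is rotated back.  Dark-on-bright vessels yield positive
#' response at their centerline.
#'
#' @param image a FundusImage
#' @param theta orientation in degrees, in [0, 180)
#' @param params a \code{\link{matchedFilterParams}} list
#' @return numeric response matrix of the same shape
#' @export
matchedFilterResponse <- function(image, theta, params = matchedFilterParams()) {
  if (theta < 0 || theta >= 180) stop("theta must lie in [0, 180)")
  m <- pixels(image)
  k <- gaussianHermiteKernel(params$a, params$sigma, params$halfwidth,
                             zeroMeanHvv = TRUE)
  sa <- if (is.null(params$sigmaAlong)) params$sigma else params$sigmaAlong
  ka <- gaussianHermiteKernel(0, sa, ceiling(3 * sa))
  rot <- rotateImage(m, theta)
  # cross-profile second derivative (vertical in the rotated frame), then
  # smoothing along the vessel (horizontal).  The sign convention makes
  # dark-on-bright vessels yield positive response at their centerline:
  # a smoothed intensity dip has positive second derivative at its minimum.
  resp <- conv1dCols(conv1dRows(rot, k$hvv), ka$h)
  out <- rotateImage(resp, -theta)
  # invalidate pixels whose rotated-frame source fell outside the frame
  # (border clamping would otherwise streak edge content into the corner
  # wedges that open up under large rotations)
  if (theta %% 360 != 0) {
    th <- theta * pi / 180
    ct <- cos(th); st <- sin(th)
    nr <- nrow(m); nc <- ncol(m)
    cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
    g <- centeredGrid(nr, nc)
    sr <- ct * g$dr + st * g$dc + cr    # forward rotation A(theta)
    sc <- -st * g$dr + ct * g$dc + cc
    pad <- max(params$halfwidth, ceiling(3 * sa))
    bad <- sr < pad | sr > nr - 1 - pad | sc < pad | sc > nc - 1 - pad
    out[matrix(bad, nr, nc)] <- 0
  }
  out
}

#' Cross-profile non-maximum suppression of an oriented response
#'
#' Keeps the pixels whose response is a local maximum along the normal of
#' the winning orientation (bilinear samples one pixel to each side).
#' Thinning a thresholded response band localizes the centerline at the
#' band's medial axis, which drifts wherever neighbouring bands merge;
#' the response ridge itself is a far more repeatable centerline estimate.
#'
#' @param response a \linkS4class{ResponseImage}
#' @return logical matrix marking ridge pixels
#' @export
nmsRidge <- function(response) {
  r <- response@responses
  th <- response@angles[response@orientationIndex] * pi / 180
  nr <- nrow(r); nc <- ncol(r)
  g <- expand.grid(i = seq_len(nr) - 1, j = seq_len(nc) - 1)
  up <- bilinearSample(r, g$i + cos(th), g$j + sin(th))
  dn <- bilinearSample(r, g$i - cos(th), g$j - sin(th))
  matrix(as.vector(r) >= up & as.vector(r) >= dn, nr, nc)
}

#' Maximum matched-filter response over an orientation bank
#'
#' Computes the response at \code{nOrientations} equally spaced orientations
#' (default 12 orientations, 15-degree increment) and keeps, per pixel, the
#' maximum response and the winning orientation.
#'
#' @param image a FundusImage
#' @param params a \code{\link{matchedFilterParams}} list
#' @return a \linkS4class{ResponseImage}
#' @export
maxResponse <- function(image, params = matchedFilterParams()) {
  angles <- (seq_len(params$nOrientations) - 1L) * params$angleStep
  best <- matrix(-Inf, nrow(pixels(image)), ncol(pixels(image)))
  arg <- matrix(1L, nrow(best), ncol(best))
  for (i in seq_along(angles)) {
    r <- matchedFilterResponse(image, angles[i], params)
    upd <- r > best
    best[upd] <- r[upd]
    arg[upd] <- i
  }
  new("ResponseImage", responses = best, orientationIndex = arg,
      angles = angles)
}
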