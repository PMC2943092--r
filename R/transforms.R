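# Geometric transforms: the similarity model used for global alignment and
# the 12-parameter quadratic polynomial model used at fine level.

#' Construct a SimilarityTransform
#' @param scale positive scale factor
#' @param rotation rotation in radians
#' @param translation numeric(2) (drow, dcol)
#' @return a \linkS4class{SimilarityTransform}
#' @export
SimilarityTransform <- function(scale = 1, rotation = 0,
                                translation = c(0, 0)) {
  new("SimilarityTransform", scale = scale, rotation = rotation,
      translation = as.numeric(translation))
}

#' Construct a QuadraticTransform
#' @param coeffs 2 x 6 coefficient matrix over the basis
#'   (r^2, c^2, r*c, r, c, 1)
#' @return a \linkS4class{QuadraticTransform}
#' @export
QuadraticTransform <- function(coeffs) {
  new("QuadraticTransform", coeffs = matrix(as.numeric(coeffs), 2, 6))
}

#' Identity quadratic transform
#' @return a \linkS4class{QuadraticTransform} leaving points unchanged
#' @export
identityQuadratic <- function() {
  QuadraticTransform(rbind(c(0, 0, 0, 1, 0, 0), c(0, 0, 0, 0, 1, 0)))
}

#' @describeIn applyTransform similarity: p -> scale * R(rotation) p + t
#' @export
setMethod("applyTransform", "SimilarityTransform", function(transform, points) {
  p <- matrix(as.numeric(points), ncol = 2)
  ct <- cos(transform@rotation); st <- sin(transform@rotation)
  s <- transform@scale
  cbind(s * (ct * p[, 1] - st * p[, 2]) + transform@translation[1],
        s * (st * p[, 1] + ct * p[, 2]) + transform@translation[2])
})

## monomial basis of the quadratic model
#' @keywords internal
quadBasis <- function(p) {
  cbind(p[, 1]^2, p[, 2]^2, p[, 1] * p[, 2], p[, 1], p[, 2], 1)
}

#' @describeIn applyTransform quadratic: per-point polynomial evaluation
#' @export
setMethod("applyTransform", "QuadraticTransform", function(transform, points) {
  p <- matrix(as.numeric(points), ncol = 2)
  quadBasis(p) %*% t(transform@coeffs)
})

#' @describeIn invertTransform closed-form similarity inverse
#' @export
setMethod("invertTransform", "SimilarityTransform", function(transform, ...) {
  s <- 1 / transform@scale
  th <- -transform@rotation
  t0 <- transform@translation
  ct <- cos(th); st <- sin(th)
  SimilarityTransform(scale = s, rotation = th,
    translation = c(-s * (ct * t0[1] - st * t0[2]),
                    -s * (st * t0[1] + ct * t0[2])))
})

#' @describeIn invertTransform pointwise Newton inverse of the quadratic
#'   map; returns \code{function(points)} evaluating the pre-image, with
#'   \code{maxIter} Newton steps from the affine-part initialization
#' @param maxIter Newton iterations
#' @export
setMethod("invertTransform", "QuadraticTransform",
          function(transform, maxIter = 6L, ...) {
  co <- transform@coeffs
  # affine part for initialization
  A <- co[, 4:5]; b <- co[, 6]
  Ainv <- solve(A)
  function(points) {
    q <- matrix(as.numeric(points), ncol = 2)
    p <- t(Ainv %*% (t(q) - b))
    for (i in seq_len(maxIter)) {
      f <- quadBasis(p) %*% t(co) - q
      # Jacobian per point
      j11 <- 2 * co[1, 1] * p[, 1] + co[1, 3] * p[, 2] + co[1, 4]
      j12 <- 2 * co[1, 2] * p[, 2] + co[1, 3] * p[, 1] + co[1, 5]
      j21 <- 2 * co[2, 1] * p[, 1] + co[2, 3] * p[, 2] + co[2, 4]
      j22 <- 2 * co[2, 2] * p[, 2] + co[2, 3] * p[, 1] + co[2, 5]
      det <- j11 * j22 - j12 * j21
      det[abs(det) < 1e-12] <- NA
      dr <- (j22 * f[, 1] - j12 * f[, 2]) / det
      dc <- (-j21 * f[, 1] + j11 * f[, 2]) / det
      dr[is.na(dr)] <- 0; dc[is.na(dc)] <- 0
      p <- p - cbind(dr, dc)
    }
    p
  }
})

#' Embed a similarity transform into quadratic coefficients
#' @param transform a \linkS4class{SimilarityTransform}
#' @return the equivalent \linkS4class{QuadraticTransform}
#' @export
similarityToQuadratic <- function(transform) {
  s <- transform@scale; ct <- cos(transform@rotation)
  st <- sin(transform@rotation); t0 <- transform@translation
  QuadraticTransform(rbind(c(0, 0, 0, s * ct, -s * st, t0[1]),
                           c(0, 0, 0, s * st,  s * ct, t0[2])))
}

#' Closed-form least-squares similarity transform between matched points
#'
#' Umeyama's solution: the similarity (scale, rotation, translation)
#' minimizing the sum of squared distances \code{sum(|p - T(q)|^2)} over
#' matched pairs, constrained to a proper rotation (no reflection).
#'
#' @param src n x 2 source points (will be transformed)
#' @param dst n x 2 destination points
#' @param weights optional nonnegative per-pair weights
#' @return a \linkS4class{SimilarityTransform} mapping src onto dst
#' @export
estimateSimilarity <- function(src, dst, weights = NULL) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  if (n < 2) stop("at least 2 pairs are required")
  w <- if (is.null(weights)) rep(1, n) else weights / sum(weights) * n
  mu_s <- colSums(src * w) / sum(w)
  mu_d <- colSums(dst * w) / sum(w)
  xs <- sweep(src, 2, mu_s); xd <- sweep(dst, 2, mu_d)
  var_s <- sum(w * rowSums(xs^2)) / sum(w)
  if (var_s < 1e-12)
    stop(errorCondition("degenerate (coincident) source points",
                        class = c("fundusregDegenerate", "error", "condition")))
  S <- t(xd * w) %*% xs / sum(w)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  scale <- sum(diag(D) * sv$d) / var_s
  t0 <- mu_d - scale * as.vector(R %*% mu_s)
  SimilarityTransform(scale = scale, rotation = atan2(R[2, 1], R[1, 1]),
                      translation = t0)
}

#' Weighted least-squares fit of the quadratic transformation
#'
#' Fits the 12 coefficients of the second-order polynomial map from matched
#' point pairs by weighted linear regression on the monomial basis
#' (r^2, c^2, r*c, r, c, 1), solved independently per output coordinate.
#' Coordinates are internally rescaled to [-1, 1] about \code{center} to
#' condition the design matrix; the returned coefficients are in pixel units.
#'
#' @param src n x 2 source points
#' @param dst n x 2 destination points
#' @param weights optional nonnegative weights
#' @param center,halfspan normalization: points are mapped to
#'   (p - center) / halfspan before fitting; defaults derive from the data
#' @return a \linkS4class{QuadraticTransform}
#' @export
fitQuadratic <- function(src, dst, weights = NULL,
                         center = NULL, halfspan = NULL) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  if (n < 6) stop("at least 6 pairs are required")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (sum(w > 0) < 6) stop("at least 6 pairs with positive weight required")
  if (is.null(center)) center <- colMeans(src)
  if (is.null(halfspan)) {
    halfspan <- max(abs(sweep(src, 2, center)), 1)
  }
  u <- sweep(src, 2, center) / halfspan
  X <- quadBasis(u)
  sw <- sqrt(w)
  qrX <- qr(X * sw)
  if (qrX$rank < 6)
    stop(errorCondition(
      sprintf("rank-deficient quadratic design (rank %d < 6)", qrX$rank),
      class = c("fundusregDegenerate", "error", "condition")))
  beta <- qr.coef(qrX, dst * sw)           # 6 x 2, normalized frame -> pixels
  # expand the polynomial in u = (p - center)/h back to pixel coordinates
  cr <- center[1]; cc <- center[2]; h <- halfspan
  co <- matrix(0, 2, 6)
  for (k in 1:2) {
    b <- beta[, k]
    co[k, 1] <- b[1] / h^2
    co[k, 2] <- b[2] / h^2
    co[k, 3] <- b[3] / h^2
    co[k, 4] <- (-2 * b[1] * cr - b[3] * cc) / h^2 + b[4] / h
    co[k, 5] <- (-2 * b[2] * cc - b[3] * cr) / h^2 + b[5] / h
    co[k, 6] <- (b[1] * cr^2 + b[2] * cc^2 + b[3] * cr * cc) / h^2 -
      (b[4] * cr + b[5] * cc) / h + b[6]
  }
  QuadraticTransform(co)
}
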