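# Fine-level registration of vessel centerline point sets: a revised ICP
# under the 12-parameter quadratic transformation model, run coarse-to-fine
# over subsampled point sets with a gated nearest-neighbour correspondence
# search and a per-iteration point-pair weighting that rejects inconsistent
# matches.

#' Gated closest-point pairs between two point sets
#'
#' For each source point, the nearest target point within \code{maxDist}
#' (exact, ties broken by lowest target index); unmatched points are
#' excluded.  Pairs carry a weight, 1 initially.
#'
#' @param source,target n x 2 point matrices (0-based (row, col))
#' @param maxDist gating distance in pixels
#' @return data.frame with columns sourceIdx, targetIdx, dist, weight
#' @export
closestPairs <- function(source, target, maxDist) {
  nn <- gatedNearest(matrix(as.numeric(source), ncol = 2),
                     matrix(as.numeric(target), ncol = 2), maxDist)
  data.frame(sourceIdx = nn$src, targetIdx = nn$tgt, dist = nn$dist,
             weight = rep(1, nrow(nn)))
}

#' Default ICP schedule
#'
#' @param strides per-level subsampling strides, coarse to fine
#' @param gates per-level gating distances (pixels)
#' @param maxIter iterations per level
#' @param tol convergence threshold on the mean-residual change (pixels)
#' @param weighting "trim" keeps pairs with residual <= 2.5 x median
#'   (recomputed each iteration); "huber" downweights by the Huber kernel
#' @param sigmaHuber scale for the "huber" weighting
#' @param affineOnly restrict the model to its affine part (the quadratic
#'   block pinned at zero)
#' @return a named list of settings
#' @export
icpConfig <- function(strides = c(4L, 2L, 1L), gates = c(20, 10, 5),
                      maxIter = 50L, tol = 1e-3,
                      weighting = c("trim", "huber"), sigmaHuber = 3,
                      affineOnly = FALSE) {
  stopifnot(length(strides) == length(gates))
  list(strides = as.integer(strides), gates = gates,
       maxIter = as.integer(maxIter), tol = tol,
       weighting = match.arg(weighting), sigmaHuber = sigmaHuber,
       affineOnly = affineOnly)
}

## affine-only weighted fit on the same interface as fitQuadratic
#' @keywords internal
fitAffine <- function(src, dst, weights) {
  X <- cbind(src, 1)
  sw <- sqrt(weights)
  qrX <- qr(X * sw)
  if (qrX$rank < 3)
    stop(errorCondition("rank-deficient affine design",
                        class = c("fundusregDegenerate", "error", "condition")))
  b <- qr.coef(qrX, dst * sw)        # 3 x 2
  QuadraticTransform(rbind(c(0, 0, 0, b[1, 1], b[2, 1], b[3, 1]),
                           c(0, 0, 0, b[1, 2], b[2, 2], b[3, 2])))
}

#' Quadratic-model iterative closest point refinement
#'
#' Coarse-to-fine loop: at each resolution level the point sets are
#' subsampled with a level stride; iterations alternate a gated
#' closest-point search from the transformed source, a weight update that
#' rejects inconsistent pairs, and a weighted least-squares re-fit of the
#' quadratic map from the original source points to their matched targets.
#' The initial transform is the similarity estimate from the global stage
#' embedded into quadratic coefficients.
#'
#' @param source n x 2 floating centerline points (will be mapped onto the
#'   target)
#' @param target m x 2 reference centerline points
#' @param init a \linkS4class{SimilarityTransform} or
#'   \linkS4class{QuadraticTransform} initial estimate
#' @param cfg an \code{\link{icpConfig}} schedule
#' @return list with \code{transform} (\linkS4class{QuadraticTransform}),
#'   \code{residualTrace} (list of per-level mean-residual vectors) and
#'   \code{nPairs}
#' @export
icpRefine <- function(source, target, init = SimilarityTransform(),
                      cfg = icpConfig()) {
  source <- matrix(as.numeric(source), ncol = 2)
  target <- matrix(as.numeric(target), ncol = 2)
  cur <- if (is(init, "SimilarityTransform")) similarityToQuadratic(init)
         else init
  center <- colMeans(source)
  halfspan <- max(abs(sweep(source, 2, center)), 1)
  traces <- list()
  lastPairs <- 0L
  for (lev in seq_along(cfg$strides)) {
    s <- source[seq(1, nrow(source), by = cfg$strides[lev]), , drop = FALSE]
    t <- target[seq(1, nrow(target), by = cfg$strides[lev]), , drop = FALSE]
    gate <- cfg$gates[lev]
    trace <- numeric(0)
    prevRes <- Inf
    for (it in seq_len(cfg$maxIter)) {
      p <- applyTransform(cur, s)
      pairs <- closestPairs(p, t, gate)
      lastPairs <- nrow(pairs)
      if (nrow(pairs) < 6) break
      w <- if (cfg$weighting == "trim") {
        as.numeric(pairs$dist <= 2.5 * stats::median(pairs$dist))
      } else {
        pmin(1, cfg$sigmaHuber / pmax(pairs$dist, 1e-12))
      }
      if (sum(w > 0) < 6) w <- rep(1, nrow(pairs))
      fit <- tryCatch({
        if (cfg$affineOnly)
          fitAffine(s[pairs$sourceIdx, , drop = FALSE],
                    t[pairs$targetIdx, , drop = FALSE], w)
        else
          fitQuadratic(s[pairs$sourceIdx, , drop = FALSE],
                       t[pairs$targetIdx, , drop = FALSE], w,
                       center = center, halfspan = halfspan)
      }, fundusregDegenerate = function(e) NULL)
      if (is.null(fit)) break
      cur <- fit
      p2 <- applyTransform(cur, s[pairs$sourceIdx, , drop = FALSE])
      res <- mean(sqrt(rowSums(
        (p2 - t[pairs$targetIdx, , drop = FALSE])^2)))
      trace <- c(trace, res)
      if (abs(prevRes - res) < cfg$tol) break
      prevRes <- res
    }
    traces[[lev]] <- trace
  }
  if (lastPairs < 6)
    stop(errorCondition("fewer than 6 usable pairs at the finest level",
                        class = c("fundusregIcpDivergence",
                                  "error", "condition")))
  list(transform = cur, residualTrace = traces, nPairs = lastPairs)
}

#' Extract centerline points from a skeleton
#' @param skeleton a \linkS4class{CenterlineImage}
#' @return n x 2 matrix of 0-based (row, col) coordinates
#' @export
centerlinePoints <- function(skeleton) {
  which(skeleton@mask, arr.ind = TRUE) - 1
}
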