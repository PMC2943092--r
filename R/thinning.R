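# Morphological thinning of a binary vessel mask to a one-pixel-wide,
# 8-connected skeleton (two-subiteration Zhang-Suen scheme, plus a
# staircase clean-up pass that removes redundant pixels of residual 2 x 2
# foreground blocks while preserving connectivity).

## out[i, j] = m[i + dr, j + dc], zero outside
#' @keywords internal
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

## 8-neighbourhood stack in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
#' @keywords internal
neighborStack <- function(m) {
  list(p2 = shiftMat(m, -1L,  0L), p3 = shiftMat(m, -1L,  1L),
       p4 = shiftMat(m,  0L,  1L), p5 = shiftMat(m,  1L,  1L),
       p6 = shiftMat(m,  1L,  0L), p7 = shiftMat(m,  1L, -1L),
       p8 = shiftMat(m,  0L, -1L), p9 = shiftMat(m, -1L, -1L))
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Iterative two-subiteration thinning on 8-connectivity; preserves the
#' topology (connected components and holes) of the input mask and is
#' idempotent on its own output.
#'
#' @param x a \linkS4class{CenterlineImage}, logical or 0/1 numeric matrix
#' @return a \linkS4class{CenterlineImage} with \code{guaranteedThin = TRUE}
#' @export
thinMask <- function(x) {
  m0 <- if (is(x, "CenterlineImage")) x@mask else x
  m <- matrix(as.integer(m0 != 0), nrow(m0), ncol(m0))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      n <- neighborStack(m)
      b <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + as.integer(seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      cond <- m == 1L & b >= 2L & b <= 6L & a == 1L
      cond <- cond & if (sub == 1L) {
        (n$p2 * n$p4 * n$p6 == 0L) & (n$p4 * n$p6 * n$p8 == 0L)
      } else {
        (n$p2 * n$p4 * n$p8 == 0L) & (n$p2 * n$p6 * n$p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- removeStaircases(m)
  new("CenterlineImage", mask = m == 1L, guaranteedThin = TRUE)
}

#' Remove skeleton segments that cross mask blobs
#'
#' Where vessel response bands merge (crossings, crowded branches) the
#' segmentation mask forms blobs whose medial axis is not a vessel
#' centerline.  Skeleton pixels lying deeper inside the mask than any
#' plausible vessel radius are removed; the remaining fragments are cleaned
#' up by the graph-level pruning.
#'
#' @param skeleton a thin \linkS4class{CenterlineImage}
#' @param vesselMask the binary mask the skeleton was thinned from
#' @param maxRadius maximum plausible vessel half-width in pixels
#' @return the filtered \linkS4class{CenterlineImage}
#' @export
pruneSkeletonBlobs <- function(skeleton, vesselMask, maxRadius = 6) {
  vm <- if (is(vesselMask, "CenterlineImage")) vesselMask@mask else vesselMask
  depth <- as.matrix(EBImage::distmap(matrix(as.numeric(vm), nrow(vm),
                                             ncol(vm))))
  keep <- skeleton@mask & depth <= maxRadius
  new("CenterlineImage", mask = keep, guaranteedThin = skeleton@guaranteedThin)
}

## sequentially delete pixels that belong to a 2 x 2 foreground block and
## whose removal keeps the local 8-connectivity intact (crossing number 1)
#' @keywords internal
removeStaircases <- function(m) {
  repeat {
    n <- neighborStack(m)
    blocks <- m & ((n$p4 & n$p5 & n$p6) | (n$p6 & n$p7 & n$p8) |
                   (n$p8 & n$p9 & n$p2) | (n$p2 & n$p3 & n$p4))
    idx <- which(blocks)
    if (length(idx) == 0L) return(m)
    deleted <- FALSE
    for (k in idx) {
      rc <- arrayInd(k, dim(m))
      if (deletableQ(m, rc[1], rc[2])) { m[k] <- 0L; deleted <- TRUE }
    }
    if (!deleted) return(m)
  }
}

## can pixel (r, c) be deleted without changing local topology?
#' @keywords internal
deletableQ <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  p <- integer(8)
  for (i in 1:8) {
    rr <- r + off[i, 1]; cc <- c + off[i, 2]
    p[i] <- if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) m[rr, cc] else 0L
  }
  b <- sum(p)
  if (b < 2L || b > 6L) return(FALSE)
  s <- c(p, p[1])
  a <- sum(s[-9] == 0L & s[-1] == 1L)
  a == 1L
}
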