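# Low-level raster helpers shared by the matched filter, warping and the
# phantom renderer.  All heavy lifting is vectorized over whole images.
#
# Conventions used throughout the package:
#  * images are plain numeric matrices indexed [row, col], intensities in [0,1]
#  * exported point coordinates are 0-based (row, col) with pixel centers at
#    integer positions; matrix access adds 1

#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

## reflect-101 index folding: maps arbitrary 1-based indices into [1, n]
#' @keywords internal
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

## correlation of a symmetric 1-D kernel along the row dimension (vertical)
#' @keywords internal
conv1dRows <- function(m, k) {
  hw <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (t in seq_along(k)) {
    idx <- reflectIndex(seq_len(nr) + (t - 1L - hw), nr)
    out <- out + k[t] * m[idx, , drop = FALSE]
  }
  out
}

## correlation along the column dimension (horizontal)
#' @keywords internal
conv1dCols <- function(m, k) {
  hw <- (length(k) - 1L) %/% 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  for (t in seq_along(k)) {
    idx <- reflectIndex(seq_len(nc) + (t - 1L - hw), nc)
    out <- out + k[t] * m[, idx, drop = FALSE]
  }
  out
}

## full (non-separable) 2-D correlation with reflect-101 borders; the
## brute-force reference used by tests to certify the separable path
#' @keywords internal
conv2dFull <- function(m, kernel) {
  hr <- (nrow(kernel) - 1L) %/% 2L
  hc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(kernel))) {
    ri <- reflectIndex(seq_len(nr) + (a - 1L - hr), nr)
    for (b in seq_len(ncol(kernel))) {
      ci <- reflectIndex(seq_len(nc) + (b - 1L - hc), nc)
      out <- out + kernel[a, b] * m[ri, ci, drop = FALSE]
    }
  }
  out
}

## bilinear sampling at fractional 0-based (row, col); out-of-range
## coordinates are folded back by reflection
#' @keywords internal
bilinearSample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i0 <- reflectIndex(as.integer(r0) + 1L, nr)
  i1 <- reflectIndex(as.integer(r0) + 2L, nr)
  j0 <- reflectIndex(as.integer(c0) + 1L, nc)
  j1 <- reflectIndex(as.integer(c0) + 2L, nc)
  (1 - fr) * (1 - fc) * m[cbind(i0, j0)] +
    (1 - fr) * fc * m[cbind(i0, j1)] +
    fr * (1 - fc) * m[cbind(i1, j0)] +
    fr * fc * m[cbind(i1, j1)]
}

## centered coordinate offsets for an nr x nc frame, cached per shape
## (the oriented filter bank reuses them for every orientation)
.gridCache <- new.env(parent = emptyenv())
#' @keywords internal
centeredGrid <- function(nr, nc) {
  key <- paste(nr, nc)
  g <- .gridCache[[key]]
  if (is.null(g)) {
    g <- list(dr = rep(seq_len(nr) - 1 - (nr - 1) / 2, times = nc),
              dc = rep(seq_len(nc) - 1 - (nc - 1) / 2, each = nr))
    .gridCache[[key]] <- g
  }
  g
}

## rotate image content so that structures oriented at `thetaDeg` become
## horizontal: output(q) = input(A(-theta) (q - ctr) + ctr).  Same shape,
## bilinear interpolation, reflected borders.  rotateImage(x, -theta)
## undoes rotateImage(x, theta) up to interpolation error.
#' @keywords internal
rotateImage <- function(m, thetaDeg) {
  if (thetaDeg %% 360 == 0) return(m)
  th <- thetaDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  g <- centeredGrid(nr, nc)
  # inverse rotation A(-theta) = [[ct, -st], [st, ct]]; source coordinates
  # outside the frame are clamped to the border (reflection would fold
  # distant content back in and create ghost structures)
  sr <- pmin(pmax(ct * g$dr - st * g$dc + cr, 0), nr - 1)
  sc <- pmin(pmax(st * g$dr + ct * g$dc + cc, 0), nc - 1)
  matrix(bilinearSample(m, sr, sc), nr, nc)
}

## exact 3 x 3 median via the 19-comparator median-of-9 sorting network,
## vectorized over the whole image (replicated borders)
#' @keywords internal
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc)
    m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
      pmin(pmax(seq_len(nc) + dc, 1L), nc)]
  p <- list(sh(-1, -1), sh(-1, 0), sh(-1, 1),
            sh(0, -1),  sh(0, 0),  sh(0, 1),
            sh(1, -1),  sh(1, 0),  sh(1, 1))
  s <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  s(2, 3); s(5, 6); s(8, 9); s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9); s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6); s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  p[[5]]
}

## 8-connected component labelling (EBImage::bwlabel is 4-connected, which
## splits diagonal skeleton runs); merges 4-connected labels that touch
## diagonally with a union-find pass
#' @keywords internal
label8 <- function(m) {
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(-1L, -1L), c(-1L, 1L))) {
    a <- lab[max(1, 1 - off[1]):min(nr, nr - off[1]),
             max(1, 1 - off[2]):min(nc, nc - off[2])]
    b <- lab[max(1, 1 + off[1]):min(nr, nr + off[1]),
             max(1, 1 + off[2]):min(nc, nc + off[2])]
    touch <- which(a > 0L & b > 0L & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  relab <- match(root, sort(unique(root)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

## gated nearest neighbour from each source point to the target set,
## exact within `maxDist`, via a data.table grid-hash join (no kd-tree
## package is required; tests certify equality with brute force)
#' @keywords internal
gatedNearest <- function(src, tgt, maxDist) {
  stopifnot(ncol(src) == 2, ncol(tgt) == 2, maxDist > 0)
  ns <- nrow(src)
  if (ns == 0L || nrow(tgt) == 0L)
    return(data.frame(src = integer(0), tgt = integer(0), dist = numeric(0)))
  cell <- maxDist
  s <- data.table::data.table(si = seq_len(ns),
                              sr = src[, 1], sc = src[, 2],
                              gr = as.integer(floor(src[, 1] / cell)),
                              gc = as.integer(floor(src[, 2] / cell)))
  t <- data.table::data.table(ti = seq_len(nrow(tgt)),
                              tr = tgt[, 1], tc = tgt[, 2],
                              gr = as.integer(floor(tgt[, 1] / cell)),
                              gc = as.integer(floor(tgt[, 2] / cell)))
  off <- data.table::CJ(dr = -1:1, dc = -1:1)
  # expand each source point to its 9 candidate cells
  sx <- s[rep(seq_len(ns), each = 9L)]
  sx[, `:=`(gr = gr + rep(off$dr, ns), gc = gc + rep(off$dc, ns))]
  cand <- merge(sx, t, by = c("gr", "gc"), allow.cartesian = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(src = integer(0), tgt = integer(0), dist = numeric(0)))
  cand[, d2 := (sr - tr)^2 + (sc - tc)^2]
  cand <- cand[d2 <= maxDist^2]
  if (nrow(cand) == 0L)
    return(data.frame(src = integer(0), tgt = integer(0), dist = numeric(0)))
  # smallest distance wins; ties broken by lowest target index
  data.table::setorder(cand, si, d2, ti)
  best <- cand[, .SD[1L], by = si]
  data.frame(src = best$si, tgt = best$ti, dist = sqrt(best$d2))
}

## mutual (symmetric) nearest neighbours within a gate
#' @keywords internal
mutualNearest <- function(a, b, maxDist) {
  f <- gatedNearest(a, b, maxDist)
  g <- gatedNearest(b, a, maxDist)
  if (nrow(f) == 0L || nrow(g) == 0L)
    return(data.frame(a = integer(0), b = integer(0), dist = numeric(0)))
  back <- integer(nrow(b)); back[g$src] <- g$tgt
  keep <- back[f$tgt] == f$src
  data.frame(a = f$src[keep], b = f$tgt[keep], dist = f$dist[keep])
}
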