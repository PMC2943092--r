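# Synthetic vascular phantoms: branching vessel trees with Gaussian-like
# cross profiles (optionally with a central light-reflection ridge) on an
# unevenly illuminated background, with known ground-truth warps, node
# correspondences and controllable structure noise.  The phantoms stand in
# for clinical image pairs in every test and experiment sweep.

## run expr under a private RNG stream, restoring global RNG state
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Bundles every knob of the synthetic generator; the same spec always
#' produces bit-identical phantoms.
#'
#' @param seed RNG seed (mandatory; the phantom owns its RNG stream)
#' @param imageShape image dimensions (rows, cols); default 600 x 700
#' @param nTrees number of vessel trees
#' @param treeDepth binary branching depth
#' @param rootLength first-segment length in pixels
#' @param lengthDecay per-generation segment length factor
#' @param branchAngleMean,branchAngleSd branching half-angle distribution
#'   (degrees)
#' @param curvatureSd within-segment direction drift (degrees, total)
#' @param widthRoot,widthDecay vessel half-width profile (pixels)
#' @param background background intensity
#' @param vesselContrast vessel darkness relative to background
#' @param reflectionAmp amplitude of the central light-reflection ridge on
#'   wide vessels (0 disables it)
#' @param illuminationAmp amplitude of the smooth background gradient
#' @param noiseSd additive Gaussian intensity noise
#' @param structureNoise fraction of floating-graph nodes without a
#'   ground-truth partner, in [0, 0.9]
#' @param deleteFraction fraction of floating leaf branches deleted
#' @param warp ground-truth transform (floating -> reference);
#'   a \linkS4class{SimilarityTransform} or \linkS4class{QuadraticTransform}
#' @param overlapTarget when set, the warp translation is adjusted so the
#'   image overlap is approximately this percentage
#' @return a phantom spec list
#' @export
phantomSpec <- function(seed, imageShape = c(600L, 700L), nTrees = 2L,
                        treeDepth = 4L, rootLength = 170,
                        lengthDecay = 0.72, branchAngleMean = 32,
                        branchAngleSd = 7, curvatureSd = 9,
                        widthRoot = 3.2, widthDecay = 0.85,
                        background = 0.85, vesselContrast = 0.38,
                        reflectionAmp = 0, illuminationAmp = 0.12,
                        noiseSd = 0.015, structureNoise = 0,
                        deleteFraction = 0,
                        warp = SimilarityTransform(),
                        overlapTarget = NULL) {
  stopifnot(structureNoise >= 0, structureNoise <= 0.9)
  list(seed = seed, imageShape = as.integer(imageShape), nTrees = nTrees,
       treeDepth = treeDepth, rootLength = rootLength,
       lengthDecay = lengthDecay, branchAngleMean = branchAngleMean,
       branchAngleSd = branchAngleSd, curvatureSd = curvatureSd,
       widthRoot = widthRoot, widthDecay = widthDecay,
       background = background, vesselContrast = vesselContrast,
       reflectionAmp = reflectionAmp, illuminationAmp = illuminationAmp,
       noiseSd = noiseSd, structureNoise = structureNoise,
       deleteFraction = deleteFraction, warp = warp,
       overlapTarget = overlapTarget)
}

## polyline of a single curved segment, sampled every ~1.5 px
#' @keywords internal
segmentPolyline <- function(start, dirDeg, len, driftDeg) {
  nStep <- max(2L, ceiling(len / 1.5))
  ang <- (dirDeg + seq(0, driftDeg, length.out = nStep)) * pi / 180
  step <- len / nStep
  dr <- -sin(ang) * step; dc <- cos(ang) * step
  cbind(start[1] + cumsum(c(0, dr[-1])), start[2] + cumsum(c(0, dc[-1])))
}

#' Generate a random branching vessel tree
#'
#' Recursive binary tree of curved segments inside the image bounds; every
#' junction and terminal point is recorded as a ground-truth node.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @return list with \code{nodes} (data.frame id, row, col, kind) and
#'   \code{segments} (data.frame from, to, depth, width + \code{path}
#'   list-column of polylines)
#' @export
generateTree <- function(spec) {
  withSeed(spec$seed, {
    nr <- spec$imageShape[1]; nc <- spec$imageShape[2]
    margin <- 6
    env <- new.env()
    env$nodes <- list(); env$segs <- list(); env$nid <- 0L
    addNode <- function(p, kind) {
      env$nid <- env$nid + 1L
      env$nodes[[env$nid]] <- data.frame(id = env$nid, row = p[1],
                                         col = p[2], kind = kind)
      env$nid
    }
    inB <- function(p) p[1] >= margin & p[1] <= nr - margin &
      p[2] >= margin & p[2] <= nc - margin
    grow <- function(fromId, pos, dirDeg, depth) {
      # wide length jitter: the distinctiveness of real vascular trees
      # comes from their irregular segment lengths, which is exactly what
      # attribute-based graph matching keys on
      len <- spec$rootLength * spec$lengthDecay^depth *
        stats::runif(1, 0.55, 1.6)
      drift <- stats::rnorm(1, 0, spec$curvatureSd)
      path <- segmentPolyline(pos, dirDeg, len, drift)
      keep <- apply(path, 1, inB)
      clipped <- !all(keep)
      if (clipped) {
        lastIn <- if (any(keep)) max(which(keep[1:max(which(!keep)[1] - 1, 1)])) else 0L
        if (lastIn < 3) return(invisible())       # too short to keep
        path <- path[seq_len(lastIn), , drop = FALSE]
      }
      endPos <- path[nrow(path), ]
      terminal <- clipped || depth >= spec$treeDepth
      endId <- addNode(endPos, if (terminal) "endpoint" else "bifurcation")
      env$segs[[length(env$segs) + 1L]] <-
        list(from = fromId, to = endId, depth = depth,
             width = spec$widthRoot * spec$widthDecay^depth, path = path)
      if (!terminal) {
        endDir <- dirDeg + drift
        a1 <- abs(stats::rnorm(1, spec$branchAngleMean, spec$branchAngleSd))
        a2 <- abs(stats::rnorm(1, spec$branchAngleMean, spec$branchAngleSd))
        grow(endId, endPos, endDir + a1, depth + 1L)
        grow(endId, endPos, endDir - a2, depth + 1L)
      }
      invisible()
    }
    # arcade-like layout: trees root near one edge and fan out in
    # diverging directions, as the temporal arcades do, so their branches
    # rarely superimpose
    baseDirs <- if (spec$nTrees == 1) 0
                else seq(-30, 30, length.out = spec$nTrees)
    for (k in seq_len(spec$nTrees)) {
      rootPos <- c(nr * (0.3 + 0.4 * (k - 1) / max(1, spec$nTrees - 1)),
                   nc * stats::runif(1, 0.08, 0.14))
      rootDir <- baseDirs[k] + stats::rnorm(1, 0, 6)
      rootId <- addNode(rootPos, "endpoint")
      grow(rootId, rootPos, rootDir, 0L)
    }
    nodes <- do.call(rbind, env$nodes)
    segs <- data.frame(from = vapply(env$segs, `[[`, 0L, "from"),
                       to = vapply(env$segs, `[[`, 0L, "to"),
                       depth = vapply(env$segs, `[[`, 0L, "depth"),
                       width = vapply(env$segs, `[[`, 0, "width"))
    segs$path <- lapply(env$segs, `[[`, "path")
    list(nodes = nodes, segments = segs)
  })
}

## arc length of a polyline
#' @keywords internal
polylineLength <- function(p) sum(sqrt(rowSums(diff(p)^2)))

#' Build a vascular graph directly from tree geometry
#'
#' Ground-truth counterpart of the extraction pipeline: tree junctions and
#' terminals become nodes, segments become edges with the polyline arc
#' length as vessel path distance.  Segments with an endpoint outside the
#' image bounds are dropped.
#'
#' @param tree output of \code{\link{generateTree}} (possibly transformed)
#' @param shape image dimensions for bounds clipping
#' @return a \linkS4class{VascularGraph}
#' @export
treeGraph <- function(tree, shape) {
  n <- tree$nodes; s <- tree$segments
  inB <- n$row >= 0 & n$row <= shape[1] - 1 & n$col >= 0 &
    n$col <= shape[2] - 1
  okNodes <- n$id[inB]
  keep <- s$from %in% okNodes & s$to %in% okNodes
  s <- s[keep, , drop = FALSE]
  if (nrow(s) == 0L)
    stop(errorCondition("no tree segment lies inside the bounds",
                        class = c("fundusregEmptyGraph", "error", "condition")))
  dvp <- vapply(s$path, polylineLength, 0)
  p1 <- as.matrix(n[match(s$from, n$id), c("row", "col")])
  p2 <- as.matrix(n[match(s$to, n$id), c("row", "col")])
  de <- sqrt(rowSums((p1 - p2)^2))
  edges <- data.frame(from = s$from, to = s$to,
                      dvp = pmax(dvp, de), de = de)
  edges$path <- s$path
  used <- unique(c(edges$from, edges$to))
  nodes <- n[n$id %in% used, , drop = FALSE]
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$degree <- as.integer(deg)
  nodes <- nodes[, c("id", "row", "col", "degree", "kind")]
  rownames(nodes) <- NULL
  makeVascularGraph(nodes, edges, shape)
}

#' Render a vessel tree as a fundus-like image
#'
#' Dark vessels with Gaussian cross profile (optionally a central bright
#' reflection ridge on wide vessels) on a bright background with a smooth
#' illumination gradient and additive Gaussian noise.
#'
#' @param tree output of \code{\link{generateTree}}
#' @param spec the \code{\link{phantomSpec}} (controls appearance and noise)
#' @param noiseSeed seed for the illumination direction and pixel noise
#' @return a \linkS4class{FundusImage}
#' @export
renderPhantom <- function(tree, spec, noiseSeed = spec$seed + 1L) {
  nr <- spec$imageShape[1]; nc <- spec$imageShape[2]
  dark <- matrix(0, nr, nc)
  ridge <- matrix(0, nr, nc)
  widths <- sort(unique(round(tree$segments$width, 3)), decreasing = TRUE)
  for (w in widths) {
    sel <- abs(tree$segments$width - w) < 5e-3
    m <- matrix(FALSE, nr, nc)
    for (p in tree$segments$path[sel]) {
      # densify so rounding leaves no gaps
      steps <- pmax(1L, ceiling(sqrt(rowSums(diff(p)^2)) / 0.5))
      rr <- unlist(mapply(function(a, b, k) seq(a, b, length.out = k + 1),
                          p[-nrow(p), 1], p[-1, 1], steps))
      cc <- unlist(mapply(function(a, b, k) seq(a, b, length.out = k + 1),
                          p[-nrow(p), 2], p[-1, 2], steps))
      ri <- round(rr) + 1L; ci <- round(cc) + 1L
      ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
      m[cbind(ri[ok], ci[ok])] <- TRUE
    }
    if (!any(m)) next
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(!m), nr, nc)))
    prof <- spec$vesselContrast * exp(-d^2 / (2 * w^2))
    dark <- pmax(dark, prof)
    if (spec$reflectionAmp > 0 && w >= 2.5) {
      ridge <- pmax(ridge,
                    spec$reflectionAmp * exp(-d^2 / (2 * (w / 4)^2)))
    }
  }
  withSeed(noiseSeed, {
    phi <- stats::runif(1, 0, 2 * pi)
    gr <- outer(seq_len(nr) / nr - 0.5, rep(1, nc))
    gc <- outer(rep(1, nr), seq_len(nc) / nc - 0.5)
    illum <- 1 - spec$illuminationAmp * 2 * (cos(phi) * gr + sin(phi) * gc)
    img <- spec$background * illum - dark + ridge
    if (spec$noiseSd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noiseSd), nr, nc)
    FundusImage(clamp01(img))
  })
}

## apply a transform to every node and path of a tree
#' @keywords internal
transformTree <- function(tree, mapFun) {
  tree$nodes[, c("row", "col")] <-
    mapFun(as.matrix(tree$nodes[, c("row", "col")]))
  tree$segments$path <- lapply(tree$segments$path, mapFun)
  tree
}

## delete a fraction of leaf segments and their terminal nodes
#' @keywords internal
deleteLeafSegments <- function(tree, fraction) {
  if (fraction <= 0) return(tree)
  s <- tree$segments
  isLeaf <- !(s$to %in% s$from)
  idx <- which(isLeaf)
  nDel <- round(fraction * length(idx))
  if (nDel == 0) return(tree)
  del <- sample(idx, nDel)
  gone <- s$to[del]
  tree$segments <- s[-del, , drop = FALSE]
  tree$nodes <- tree$nodes[!(tree$nodes$id %in% gone), , drop = FALSE]
  tree
}

## graft spurious short branches onto random tree nodes so that a target
## fraction of all nodes has no ground-truth partner
#' @keywords internal
addSpuriousBranches <- function(tree, fraction, spec) {
  if (fraction <= 0) return(tree)
  nTrue <- nrow(tree$nodes)
  nAdd <- round(nTrue * fraction / (1 - fraction))
  if (nAdd == 0) return(tree)
  nid <- max(tree$nodes$id)
  for (k in seq_len(nAdd)) {
    host <- tree$nodes[sample(nrow(tree$nodes), 1), ]
    dirDeg <- stats::runif(1, 0, 360)
    len <- stats::runif(1, 20, 70)
    path <- segmentPolyline(c(host$row, host$col), dirDeg, len,
                            stats::rnorm(1, 0, spec$curvatureSd))
    nid <- nid + 1L
    tree$nodes <- rbind(tree$nodes,
                        data.frame(id = nid, row = path[nrow(path), 1],
                                   col = path[nrow(path), 2],
                                   kind = "endpoint"))
    newSeg <- data.frame(from = host$id, to = nid, depth = NA_integer_,
                         width = spec$widthRoot * spec$widthDecay^3)
    newSeg$path <- list(path)
    tree$segments <- rbind(tree$segments, newSeg)
  }
  tree
}

## pick the warp translation reaching the requested overlap percentage
#' @keywords internal
solveOverlapTranslation <- function(warp, shape, target) {
  dir <- c(0, 1)                      # shift along columns
  f <- function(mag) {
    w <- SimilarityTransform(warp@scale, warp@rotation, dir * mag)
    overlapPct(shape, w, shape, stride = 8L)
  }
  lo <- 0; hi <- shape[2]
  for (i in 1:24) {
    mid <- (lo + hi) / 2
    if (f(mid) > target) lo <- mid else hi <- mid
  }
  SimilarityTransform(warp@scale, warp@rotation, dir * (lo + hi) / 2)
}

#' Generate a reference/floating phantom pair with ground truth
#'
#' Renders the reference image from a random vessel tree, derives the
#' floating tree through the inverse of the ground-truth warp (or, for a
#' quadratic warp, generates in the floating frame and maps forward),
#' optionally deletes branches and grafts spurious ones onto the floating
#' tree, and renders the floating image.  Ground-truth correspondences list
#' the node ids present in both clipped graphs.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @param render render the images (set FALSE for graph-only experiments)
#' @return list with imageRef, imageFloat (\linkS4class{FundusImage}),
#'   graphRef, graphFloat (\linkS4class{VascularGraph}), treeRef, treeFloat,
#'   trueTransform (floating -> reference), trueCorrespondences
#'   (data.frame ref, float) and the generating phantom spec
#' @export
makePhantomPair <- function(spec, render = TRUE) {
  warp <- spec$warp
  if (!is.null(spec$overlapTarget)) {
    if (!is(warp, "SimilarityTransform"))
      stop("overlapTarget requires a similarity warp")
    warp <- solveOverlapTranslation(warp, spec$imageShape,
                                    spec$overlapTarget)
  }
  if (is(warp, "SimilarityTransform")) {
    treeRef <- generateTree(spec)
    inv <- invertTransform(warp)
    treeFloat <- transformTree(treeRef, function(p) applyTransform(inv, p))
  } else {
    treeFloat <- generateTree(spec)
    treeRef <- transformTree(treeFloat,
                             function(p) applyTransform(warp, p))
  }
  treeFloat <- withSeed(spec$seed + 2L, {
    t <- deleteLeafSegments(treeFloat, spec$deleteFraction)
    addSpuriousBranches(t, spec$structureNoise, spec)
  })
  graphRef <- treeGraph(treeRef, spec$imageShape)
  graphFloat <- treeGraph(treeFloat, spec$imageShape)
  trueIds <- intersect(graphRef@nodes$id,
                       graphFloat@nodes$id[graphFloat@nodes$id <=
                                             max(treeRef$nodes$id)])
  list(imageRef = if (render) renderPhantom(treeRef, spec,
                                            noiseSeed = spec$seed + 11L),
       imageFloat = if (render) renderPhantom(treeFloat, spec,
                                              noiseSeed = spec$seed + 12L),
       graphRef = graphRef, graphFloat = graphFloat,
       treeRef = treeRef, treeFloat = treeFloat,
       trueTransform = warp,
       trueCorrespondences = data.frame(ref = trueIds, float = trueIds),
       spec = spec)
}

#' Recall of a correspondence set against phantom ground truth
#'
#' Correct matches divided by the number of reported correspondences.
#'
#' @param matches a \linkS4class{CorrespondenceSet}
#' @param truePairs data.frame with columns ref, float
#' @return recall in [0, 1] (NA when no correspondence was reported)
#' @export
matchingRecall <- function(matches, truePairs) {
  p <- matchedPairs(matches)
  if (nrow(p) == 0L) return(NA_real_)
  key <- paste(truePairs$ref, truePairs$float)
  mean(paste(p$g1, p$g2) %in% key)
}
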