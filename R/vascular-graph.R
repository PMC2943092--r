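# Vascular structure graph (VSG) construction: bifurcations and endpoints of
# a one-pixel skeleton become nodes, vessel segments between them become
# edges attributed with the vessel path distance (arc length along the
# skeleton, 1 per 4-neighbour step and sqrt(2) per diagonal step) and the
# Euclidean distance between the two endpoints, both scale-normalized by
# their mean over all edges.

## 8-neighbour offsets, 4-connected first (preferred when tracing)
NB_OFF <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))

## branch count (crossing number) and neighbour count for every pixel
#' @keywords internal
skeletonDegrees <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  n <- neighborStack(m)
  b <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
  seqs <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) a <- a + as.integer(seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
  list(b = b, a = a)
}

## locate feature pixels, merge adjacent clusters, snap to skeleton
#' @keywords internal
skeletonNodes <- function(sk) {
  deg <- skeletonDegrees(sk)
  feat <- sk & (deg$b == 1L | deg$a >= 3L)
  nodeMap <- matrix(0L, nrow(sk), ncol(sk))
  if (!any(feat)) {
    return(list(nodes = data.frame(id = integer(0), row = numeric(0),
                                   col = numeric(0), degree = integer(0),
                                   kind = character(0)),
                nodeMap = nodeMap))
  }
  lab <- label8(feat)
  ids <- sort(unique(lab[lab > 0]))
  rows <- cols <- numeric(length(ids))
  kind <- character(length(ids))
  for (i in seq_along(ids)) {
    px <- which(lab == ids[i], arr.ind = TRUE)
    ctr <- colMeans(px)
    d2 <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2
    snap <- px[which.min(d2), , drop = TRUE]
    rows[i] <- snap[1] - 1          # 0-based coordinates
    cols[i] <- snap[2] - 1
    kind[i] <- if (nrow(px) == 1L && deg$b[px[1, 1], px[1, 2]] == 1L)
      "endpoint" else "bifurcation"
    nodeMap[px] <- i
  }
  list(nodes = data.frame(id = seq_along(ids), row = rows, col = cols,
                          degree = 0L, kind = kind,
                          stringsAsFactors = FALSE),
       nodeMap = nodeMap)
}

#' Detect vascular feature points on a skeleton
#'
#' Feature pixels are skeleton pixels with exactly one branch (endpoints) or
#' at least three skeleton-connected branches leaving the 3 x 3
#' neighbourhood (bifurcations, by crossing number); clusters of adjacent
#' bifurcation pixels are merged into a single node at the cluster centroid
#' snapped to the nearest cluster pixel.
#'
#' @param skeleton a thin \linkS4class{CenterlineImage}
#' @return data.frame with columns id, row, col, degree, kind
#'   (0-based coordinates)
#' @export
detectFeaturePoints <- function(skeleton) {
  stopifnot(is(skeleton, "CenterlineImage"))
  skeletonNodes(skeleton@mask)$nodes
}

## step length between two adjacent (or nearly adjacent) pixels
#' @keywords internal
stepLen <- function(p, q) {
  d <- abs(p - q)
  if (max(d) <= 1) { if (sum(d) == 2) sqrt(2) else sum(d) }
  else sqrt(sum((p - q)^2))
}

#' Trace vessel segments between feature points
#'
#' Breadth-first walks along the skeleton starting at every node, stopping
#' at other nodes, yield one edge per vessel segment; the vessel path
#' distance accumulates 1 per 4-neighbour step and sqrt(2) per diagonal
#' step.  Self-loops and isolated cycles carrying no node are dropped.
#'
#' @param skeleton a thin \linkS4class{CenterlineImage}
#' @param featureNodes optional node table from
#'   \code{\link{detectFeaturePoints}} (recomputed when missing)
#' @return list with \code{nodes} (degrees filled in) and \code{edges}
#'   (data.frame from, to, dvp, de plus a \code{path} list-column)
#' @export
traceEdges <- function(skeleton, featureNodes = NULL) {
  sk <- skeleton@mask
  info <- skeletonNodes(sk)
  nodes <- info$nodes
  nodeMap <- info$nodeMap
  nr <- nrow(sk); nc <- ncol(sk)
  visited <- matrix(FALSE, nr, nc)
  from <- to <- integer(0); dvp <- de <- numeric(0); paths <- list()
  seenDirect <- character(0)
  nbrs <- function(p) {
    cand <- cbind(p[1] + NB_OFF[, 1], p[2] + NB_OFF[, 2])
    ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand[ok, , drop = FALSE]
  }
  addEdge <- function(a, b, path, d) {
    if (a == b) return(invisible())                    # self-loop: drop
    pa <- nodes[a, ]; pb <- nodes[b, ]
    ee <- sqrt((pa$row - pb$row)^2 + (pa$col - pb$col)^2)
    if (ee <= 0) return(invisible())
    # the same segment can be reached from both sides when branch pixels
    # interleave at a junction; keep one copy per endpoint pair unless
    # the lengths differ enough to be genuine parallel segments
    dup <- which((from == a & to == b) | (from == b & to == a))
    if (length(dup) > 0 && any(abs(dvp[dup] - max(d, ee)) <
                                 0.25 * max(d, ee) + 3))
      return(invisible())
    from <<- c(from, a); to <<- c(to, b)
    dvp <<- c(dvp, max(d, ee)); de <<- c(de, ee)
    paths[[length(paths) + 1L]] <<- path
  }
  ## node id within a +-2 px window, 0 if none (walks can be cut off one
  ## or two pixels short of a junction cluster by previously consumed
  ## connector pixels)
  nearNode <- function(p) {
    rs <- max(1, p[1] - 2):min(nr, p[1] + 2)
    cs <- max(1, p[2] - 2):min(nc, p[2] + 2)
    w <- nodeMap[rs, cs, drop = FALSE]
    hit <- which(w > 0, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(0L)
    d2 <- (rs[hit[, 1]] - p[1])^2 + (cs[hit[, 2]] - p[2])^2
    w[hit[which.min(d2), , drop = FALSE]]
  }
  for (nid in nodes$id) {
    clu <- which(nodeMap == nid, arr.ind = TRUE)
    snap <- c(nodes$row[nid], nodes$col[nid]) + 1     # 1-based
    for (ci in seq_len(nrow(clu))) {
      p0 <- clu[ci, ]
      for (qi in seq_len(nrow(nbrs(p0)))) {
        q <- nbrs(p0)[qi, ]
        if (!sk[q[1], q[2]]) next
        qn <- nodeMap[q[1], q[2]]
        if (qn == nid) next
        if (qn > 0) {                                  # direct node adjacency
          key <- paste(sort(c((p0[1] - 1) * nc + p0[2],
                              (q[1] - 1) * nc + q[2])), collapse = "-")
          if (key %in% seenDirect) next
          seenDirect <- c(seenDirect, key)
          d <- stepLen(snap, p0) + stepLen(p0, q) +
            stepLen(q, c(nodes$row[qn], nodes$col[qn]) + 1)
          addEdge(nid, qn, rbind(snap, q) - 1, d)
          next
        }
        if (visited[q[1], q[2]]) next
        # walk along the segment until another node (or a dead loop)
        path <- rbind(snap - 1)
        d <- stepLen(snap, p0)
        prev <- p0; cur <- q
        endNode <- 0L
        repeat {
          visited[cur[1], cur[2]] <- TRUE
          d <- d + stepLen(prev, cur)
          path <- rbind(path, cur - 1)
          nn <- nbrs(cur)
          keep <- sk[nn] & !(nn[, 1] == prev[1] & nn[, 2] == prev[2])
          nn <- nn[keep, , drop = FALSE]
          finish <- function(id) {
            endNode <<- id
            tSnap <- c(nodes$row[id], nodes$col[id]) + 1
            d <<- d + stepLen(cur, tSnap)
            path <<- rbind(path, tSnap - 1)
          }
          if (nrow(nn) == 0L) {                        # dead end
            nid2 <- nearNode(cur)
            if (nid2 > 0L && nid2 != nid) finish(nid2)
            break
          }
          isNode <- nodeMap[nn] > 0
          if (any(isNode)) {
            tgt <- nn[which(isNode)[1], ]
            finish(nodeMap[tgt[1], tgt[2]])
            break
          }
          unv <- !visited[nn]
          if (!any(unv)) {
            # connector pixels consumed by a sibling branch: close the
            # edge onto a junction cluster within reach, else drop (loop)
            nid2 <- nearNode(cur)
            if (nid2 > 0L && nid2 != nid) finish(nid2)
            break
          }
          prev <- cur; cur <- nn[which(unv)[1], ]
        }
        if (endNode > 0L) addEdge(nid, endNode, path, d)
      }
    }
  }
  edges <- data.frame(from = from, to = to, dvp = dvp, de = de)
  edges$path <- paths
  tab <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$degree <- as.integer(tab)
  list(nodes = nodes, edges = edges)
}

## assemble a VascularGraph from node/edge tables (normalizing attributes)
#' @keywords internal
makeVascularGraph <- function(nodes, edges, shape) {
  if (is.null(edges$path)) edges$path <- replicate(nrow(edges), NULL,
                                                   simplify = FALSE)
  edges$a1 <- NULL; edges$a2 <- NULL       # stale after editing: recompute
  g <- new("VascularGraph", nodes = nodes, edges = edges,
           sourceShape = as.integer(shape))
  if (nrow(edges) > 0) g <- normalizeAttributes(g) else g
}

#' Normalize edge attributes by their mean over edges
#'
#' Sets \code{a1 = dvp / mean(dvp)} and \code{a2 = de / mean(de)}, making
#' the attributes invariant to a uniform scaling of the image.
#'
#' @param graph a \linkS4class{VascularGraph} with at least one edge
#' @return the graph with a1, a2 recomputed
#' @export
normalizeAttributes <- function(graph) {
  e <- graph@edges
  if (nrow(e) == 0L)
    stop(errorCondition("cannot normalize a graph without edges",
                        class = c("fundusregEmptyGraph", "error", "condition")))
  e$a1 <- e$dvp / mean(e$dvp)
  e$a2 <- e$de / mean(e$de)
  graph@edges <- e
  graph
}

#' Build a vascular structure graph from a skeleton
#'
#' Detects feature points, traces segments, prunes short edges and
#' normalizes edge attributes.
#'
#' @param skeleton a thin \linkS4class{CenterlineImage}
#' @param minEdgePx edges with vessel path distance below this length are
#'   pruned (0 disables pruning)
#' @param minComponentPx components with total vessel path length below
#'   this are dropped (0 disables the filter)
#' @return a \linkS4class{VascularGraph}
#' @export
buildVascularGraph <- function(skeleton, minEdgePx = 10,
                               minComponentPx = 200) {
  te <- traceEdges(skeleton)
  g <- makeVascularGraph(te$nodes, te$edges, dim(skeleton@mask))
  if (minEdgePx > 0 && nrow(g@edges) > 0) g <- pruneGraph(g, minEdgePx)
  if (minComponentPx > 0) g <- filterComponents(g, minComponentPx)
  g
}

#' Prune short edges and dissolve resulting degree-2 nodes
#'
#' Topological clean-up of segmentation artifacts: short spur edges (vessel
#' path distance below \code{minEdgePx} with a degree-1 endpoint) are
#' removed; short internal edges between two junctions are contracted by
#' merging their endpoints (deleting them outright would disconnect the
#' vessel network); degree-2 nodes left behind are dissolved by
#' concatenating their incident edges (path distances add, the Euclidean
#' distance is recomputed between the outer endpoints); isolated nodes are
#' dropped and attributes renormalized.
#'
#' @param graph a \linkS4class{VascularGraph}
#' @param minEdgePx minimum retained vessel path distance in pixels
#' @return the pruned \linkS4class{VascularGraph}
#' @export
pruneGraph <- function(graph, minEdgePx = 10) {
  n <- graph@nodes; e <- graph@edges
  if (minEdgePx <= 0) return(makeVascularGraph(n, e, graph@sourceShape))
  emptyErr <- function()
    stop(errorCondition("pruning removed every edge",
                        class = c("fundusregEmptyGraph", "error", "condition")))
  degOf <- function() {
    d <- table(factor(c(e$from, e$to), levels = n$id))
    stats::setNames(as.integer(d), n$id)
  }
  touched <- integer(0)   # only nodes affected by removal are dissolved
  repeat {
    if (nrow(e) == 0L) emptyErr()
    deg <- degOf()
    short <- e$dvp < minEdgePx
    # 1) short spurs: an endpoint of the edge has degree 1
    spur <- which(short & (deg[as.character(e$from)] == 1L |
                             deg[as.character(e$to)] == 1L))
    if (length(spur) > 0L) {
      touched <- c(touched, e$from[spur[1]], e$to[spur[1]])
      e <- e[-spur[1], , drop = FALSE]
      next
    }
    # 2) short internal edges: contract, merging the two junctions
    intn <- which(short)
    if (length(intn) > 0L) {
      i <- intn[which.min(e$dvp[intn])]
      a <- e$from[i]; b <- e$to[i]
      touched <- c(touched, a)
      ia <- match(a, n$id); ib <- match(b, n$id)
      mid <- c((n$row[ia] + n$row[ib]) / 2, (n$col[ia] + n$col[ib]) / 2)
      n$row[ia] <- mid[1]; n$col[ia] <- mid[2]
      n$kind[ia] <- "bifurcation"
      e <- e[-i, , drop = FALSE]
      e$from[e$from == b] <- a; e$to[e$to == b] <- a
      e <- e[e$from != e$to, , drop = FALSE]          # collapsed loops
      n <- n[-ib, , drop = FALSE]
      # recompute de of edges touching the moved node
      touched <- which(e$from == a | e$to == a)
      for (j in touched) {
        p1 <- n[match(e$from[j], n$id), ]; p2 <- n[match(e$to[j], n$id), ]
        e$de[j] <- sqrt((p1$row - p2$row)^2 + (p1$col - p2$col)^2)
        e$dvp[j] <- max(e$dvp[j], e$de[j])
      }
      next
    }
    # 3) dissolve degree-2 nodes left behind by a removal
    d2 <- intersect(as.integer(names(deg))[deg == 2L], touched)
    if (length(d2) == 0L) break
    v <- d2[1]
    inc <- which(e$from == v | e$to == v)
    if (length(inc) == 1L) {            # parallel pair collapsed: drop node
      e <- e[-inc, , drop = FALSE]; next
    }
    e1 <- e[inc[1], ]; e2 <- e[inc[2], ]
    o1 <- if (e1$from == v) e1$to else e1$from
    o2 <- if (e2$from == v) e2$to else e2$from
    if (o1 != o2) {
      p1 <- n[match(o1, n$id), ]; p2 <- n[match(o2, n$id), ]
      path <- NULL
      if (!is.null(e1$path[[1]]) && !is.null(e2$path[[1]])) {
        a <- e1$path[[1]]
        if (e1$from != o1) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
        b <- e2$path[[1]]
        if (e2$from != v) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
        path <- rbind(a, b[-1, , drop = FALSE])
      }
      newRow <- data.frame(from = o1, to = o2, dvp = e1$dvp + e2$dvp,
                           de = sqrt((p1$row - p2$row)^2 +
                                       (p1$col - p2$col)^2))
      newRow$path <- list(path)
      for (extra in setdiff(names(e), names(newRow)))
        newRow[[extra]] <- NA_real_
      e <- rbind(e[-inc, , drop = FALSE], newRow[, names(e)])
    } else {
      e <- e[-inc, , drop = FALSE]      # would form a self-loop: drop both
    }
  }
  if (nrow(e) == 0L) emptyErr()
  used <- unique(c(e$from, e$to))
  n <- n[n$id %in% used, , drop = FALSE]
  degs <- table(factor(c(e$from, e$to), levels = n$id))
  n$degree <- as.integer(degs)
  rownames(n) <- rownames(e) <- NULL
  makeVascularGraph(n, e, graph@sourceShape)
}

#' Drop small connected components of a vascular graph
#'
#' Connected components whose total vessel path length falls below
#' \code{minComponentPx} are discarded; isolated noise squiggles survive
#' spur pruning but carry no usable structure for matching.
#'
#' @param graph a \linkS4class{VascularGraph}
#' @param minComponentPx minimum total vessel path length (pixels) of a
#'   retained component
#' @return the filtered \linkS4class{VascularGraph}
#' @export
filterComponents <- function(graph, minComponentPx = 200) {
  n <- graph@nodes; e <- graph@edges
  if (nrow(e) == 0L) return(graph)
  idx <- seq_len(nrow(n))
  parent <- idx
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ef <- match(e$from, n$id); et <- match(e$to, n$id)
  for (i in seq_along(ef)) {
    a <- find(ef[i]); b <- find(et[i])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(idx, find, 0L)
  compLen <- tapply(e$dvp, comp[ef], sum)
  keepComp <- as.integer(names(compLen))[compLen >= minComponentPx]
  keepNode <- n$id[comp %in% keepComp]
  e <- e[e$from %in% keepNode & e$to %in% keepNode, , drop = FALSE]
  if (nrow(e) == 0L)
    stop(errorCondition("component filtering removed every edge",
                        class = c("fundusregEmptyGraph", "error", "condition")))
  n <- n[n$id %in% unique(c(e$from, e$to)), , drop = FALSE]
  degs <- table(factor(c(e$from, e$to), levels = n$id))
  n$degree <- as.integer(degs)
  rownames(n) <- rownames(e) <- NULL
  makeVascularGraph(n, e, graph@sourceShape)
}

#' Apply a similarity transform to a vascular graph
#'
#' Node positions and edge paths are mapped, path and Euclidean distances
#' scale with the transform, and attributes are renormalized (they are
#' scale-invariant by construction).
#'
#' @param graph a \linkS4class{VascularGraph}
#' @param transform a \linkS4class{SimilarityTransform}
#' @param shape optional output image shape
#' @return the transformed \linkS4class{VascularGraph}
#' @export
transformGraph <- function(graph, transform, shape = graph@sourceShape) {
  n <- graph@nodes
  pts <- applyTransform(transform, as.matrix(n[, c("row", "col")]))
  n$row <- pts[, 1]; n$col <- pts[, 2]
  e <- graph@edges
  s <- transform@scale
  e$dvp <- e$dvp * s; e$de <- e$de * s
  e$path <- lapply(e$path, function(p)
    if (is.null(p)) NULL else applyTransform(transform, p))
  g <- new("VascularGraph", nodes = n, edges = e,
           sourceShape = as.integer(shape))
  if (nrow(e) > 0) normalizeAttributes(g) else g
}

#' Write a vascular graph as JSON
#' @param graph a \linkS4class{VascularGraph}
#' @param path output file
#' @param includePaths include per-edge pixel paths
#' @return invisibly, the path
#' @export
writeVascularGraph <- function(graph, path, includePaths = TRUE) {
  e <- graph@edges
  out <- list(
    coordinate_convention = "(row, col), 0-based, pixel centers at integers",
    source_shape = graph@sourceShape,
    nodes = graph@nodes,
    edges = data.frame(from = e$from, to = e$to, dvp = e$dvp, de = e$de,
                       a1 = e$a1, a2 = e$a2))
  if (includePaths)
    out$paths <- lapply(e$path, function(p) if (is.null(p)) list() else p)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vascular graph from JSON
#' @param path JSON file produced by \code{\link{writeVascularGraph}}
#' @return a \linkS4class{VascularGraph}
#' @export
readVascularGraph <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.data.frame(j$nodes)
  e <- as.data.frame(j$edges)
  e$path <- if (!is.null(j$paths)) {
    lapply(j$paths, function(p) if (length(p) == 0) NULL else as.matrix(p))
  } else replicate(nrow(e), NULL, simplify = FALSE)
  makeVascularGraph(n, e, j$source_shape)
}
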