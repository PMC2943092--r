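# STRUCT-SAC: structure-based sample consensus.  Instead of random
# sampling, candidate similarity transforms are hypothesized from the local
# structures of the graph-matching output -- a matched node of degree 2 or 3
# together with its matched neighbours -- validated by a local geometric
# consistency test (pairwise edge-attribute similarity and triplewise
# subtended-angle similarity), and verified globally by a Huber-robustified
# sum of squared distances over a fresh gated correspondence set.  The
# traversal of candidate nodes is deterministic, so the whole stage is a
# pure function of its inputs.

#' Huber kernel
#'
#' \code{rho(t) = t^2 / 2} for \code{|t| <= sigma}, and
#' \code{sigma |t| - sigma^2 / 2} beyond; continuous at the transition.
#'
#' @param t residual magnitude(s)
#' @param sigma transition scale (pixels), positive
#' @return penalized value(s)
#' @export
huber <- function(t, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  a <- abs(t)
  ifelse(a <= sigma, 0.5 * t^2, sigma * a - 0.5 * sigma^2)
}

#' Default STRUCT-SAC configuration
#'
#' @param sigmaHuber Huber transition scale in pixels
#' @param gateRadius gating radius for the global consistency test (pixels)
#' @param tolEdge maximum attribute difference relative to the attribute
#'   maximum in the local edge test
#' @param tolAngle maximum subtended-angle difference in degrees
#' @param maxNeighbors neighbour-set size above which the optional inner
#'   RANSAC subsampler kicks in
#' @param minInliers minimum gated correspondence count for a valid model
#' @param huberMode "literal" squares the Huber value (the printed form of
#'   the score); "conventional" applies the kernel to the squared norm
#' @param ransac enable the optional inner random subsampler
#' @param ransacDraws subsets drawn per oversized neighbour set
#' @return a named list of settings
#' @export
structSacConfig <- function(sigmaHuber = 3, gateRadius = 15, tolEdge = 0.25,
                            tolAngle = 20, maxNeighbors = 4L, minInliers = 3L,
                            huberMode = c("literal", "conventional"),
                            ransac = FALSE, ransacDraws = 8L) {
  list(sigmaHuber = sigmaHuber, gateRadius = gateRadius, tolEdge = tolEdge,
       tolAngle = tolAngle, maxNeighbors = as.integer(maxNeighbors),
       minInliers = as.integer(minInliers),
       huberMode = match.arg(huberMode), ransac = ransac,
       ransacDraws = as.integer(ransacDraws))
}

#' @keywords internal
nodePositions <- function(g) as.matrix(g@nodes[, c("row", "col")])

#' @keywords internal
edgeAttrRow <- function(g, u, v) {
  e <- g@edges
  hit <- which((e$from == u & e$to == v) | (e$from == v & e$to == u))
  if (length(hit) == 0L) NULL else e[hit[1], ]
}

#' @keywords internal
neighborIds <- function(g, v) {
  e <- g@edges
  unique(c(e$to[e$from == v], e$from[e$to == v]))
}

#' Global model consistency score
#'
#' Builds a fresh temporary correspondence set by mutual nearest-neighbour
#' pairing of the reference-graph nodes with the transformed floating-graph
#' nodes inside \code{gateRadius}, and scores the transform by the sum over
#' pairs of the squared Huber penalty of the residual norms.
#'
#' @param theta a \linkS4class{SimilarityTransform} mapping g2 coordinates
#'   into the g1 frame
#' @param g1,g2 \linkS4class{VascularGraph} objects
#' @param sigmaHuber Huber transition scale (pixels)
#' @param gateRadius gating radius (pixels)
#' @param huberMode see \code{\link{structSacConfig}}
#' @return list with \code{epsilon} (Inf when no pair falls inside the
#'   gate), \code{selectionScore} (epsilon plus a saturated penalty for
#'   every unmatchable node, making scores comparable between models with
#'   different gated-pair counts), \code{pairs} (data.frame g1, g2 node
#'   ids, dist) and \code{transform}
#' @export
scoreModel <- function(theta, g1, g2, sigmaHuber = 3, gateRadius = 15,
                       huberMode = "literal") {
  p1 <- nodePositions(g1)
  p2 <- applyTransform(theta, nodePositions(g2))
  nMax <- min(nrow(p1), nrow(p2))
  satPenalty <- huber(gateRadius, sigmaHuber)^2
  mn <- mutualNearest(p1, p2, gateRadius)
  if (nrow(mn) == 0L)
    return(list(epsilon = Inf, selectionScore = Inf,
                pairs = data.frame(g1 = integer(0), g2 = integer(0),
                                   dist = numeric(0)),
                transform = theta))
  eps <- if (huberMode == "literal") {
    sum(huber(mn$dist, sigmaHuber)^2)
  } else {
    sum(huber(mn$dist^2, sigmaHuber))
  }
  list(epsilon = eps,
       selectionScore = eps + satPenalty * (nMax - nrow(mn)),
       pairs = data.frame(g1 = g1@nodes$id[mn$a], g2 = g2@nodes$id[mn$b],
                          dist = mn$dist),
       transform = theta)
}

#' Local geometric consistency test of a matched structure sample
#'
#' A sample (a center node with >= 2 matched neighbours on both sides)
#' passes iff (a) every matched edge pair exists in both graphs and their
#' normalized attributes differ by at most \code{tolEdge} relative to the
#' attribute maximum over both graphs, and (b) for every neighbour pair the
#' angles subtended at the center in the two graphs differ by at most
#' \code{tolAngle} degrees (subtended angles are similarity-invariant).
#'
#' @param center1,center2 center node ids in g1 / g2
#' @param nbrs1,nbrs2 neighbour id vectors, aligned by correspondence
#' @param g1,g2 \linkS4class{VascularGraph} objects
#' @param tolEdge,tolAngle tolerances (ratio; degrees)
#' @return TRUE when the sample is locally consistent
#' @export
localConsistencyTest <- function(center1, nbrs1, center2, nbrs2, g1, g2,
                                 tolEdge = 0.25, tolAngle = 20) {
  stopifnot(length(nbrs1) == length(nbrs2), length(nbrs1) >= 2)
  L1 <- max(g1@edges$a1, g2@edges$a1)
  L2 <- max(g1@edges$a2, g2@edges$a2)
  for (k in seq_along(nbrs1)) {
    ea <- edgeAttrRow(g1, center1, nbrs1[k])
    eb <- edgeAttrRow(g2, center2, nbrs2[k])
    if (is.null(ea) || is.null(eb)) return(FALSE)
    if (abs(ea$a1 - eb$a1) / L1 > tolEdge) return(FALSE)
    if (abs(ea$a2 - eb$a2) / L2 > tolEdge) return(FALSE)
  }
  ang <- function(g, ctr, nb) {
    n <- g@nodes
    p0 <- unlist(n[match(ctr, n$id), c("row", "col")])
    d <- t(apply(as.matrix(n[match(nb, n$id), c("row", "col")]), 1,
                 function(p) p - p0))
    d / sqrt(rowSums(d^2))
  }
  u1 <- ang(g1, center1, nbrs1)
  u2 <- ang(g2, center2, nbrs2)
  np <- length(nbrs1)
  for (a in seq_len(np - 1)) for (b in (a + 1):np) {
    t1 <- acos(pmin(pmax(sum(u1[a, ] * u1[b, ]), -1), 1)) * 180 / pi
    t2 <- acos(pmin(pmax(sum(u2[a, ] * u2[b, ]), -1), 1)) * 180 / pi
    if (abs(t1 - t2) > tolAngle) return(FALSE)
  }
  TRUE
}

#' @keywords internal
neighborSubsets <- function(nbrs, cfg) {
  if (length(nbrs) <= cfg$maxNeighbors || !cfg$ransac)
    return(list(seq_along(nbrs)))
  lapply(seq_len(cfg$ransacDraws),
         function(i) sort(sample(seq_along(nbrs), cfg$maxNeighbors)))
}

#' Eliminate wrong correspondences by structure-based sample consensus
#'
#' Every matched node of degree 2 or 3 (searched symmetrically in both
#' graphs) spawns a candidate sample from its matched neighbours; samples
#' passing the local consistency test yield a closed-form similarity
#' hypothesis which is scored globally; the transform with the lowest
#' selection score (the Huber score of Eq.-style residuals plus a
#' saturated penalty per unmatchable node, so models with few gated pairs
#' cannot win on a short sum) and its gated inlier correspondences are
#' returned.
#'
#' @param matches a \linkS4class{CorrespondenceSet} from graph matching
#' @param g1,g2 \linkS4class{VascularGraph} objects (g1 = reference)
#' @param cfg a \code{\link{structSacConfig}} list
#' @return list with \code{transform} (\linkS4class{SimilarityTransform}
#'   mapping g2 into the g1 frame), \code{epsilon}, and \code{inliers}
#'   (a \linkS4class{CorrespondenceSet})
#' @export
structSac <- function(matches, g1, g2, cfg = structSacConfig()) {
  pr <- matchedPairs(matches)
  if (nrow(pr) < 2) stop("at least 2 input matches are required")
  map12 <- stats::setNames(pr$g2, pr$g1)
  map21 <- stats::setNames(pr$g1, pr$g2)
  best <- NULL
  consider <- function(c1, n1, c2, n2) {
    if (!localConsistencyTest(c1, n1, c2, n2, g1, g2,
                              cfg$tolEdge, cfg$tolAngle)) return()
    src <- as.matrix(g2@nodes[match(c(c2, n2), g2@nodes$id),
                              c("row", "col")])
    dst <- as.matrix(g1@nodes[match(c(c1, n1), g1@nodes$id),
                              c("row", "col")])
    th <- tryCatch(estimateSimilarity(src, dst), error = function(e) NULL)
    if (is.null(th)) return()
    sc <- scoreModel(th, g1, g2, cfg$sigmaHuber, cfg$gateRadius,
                     cfg$huberMode)
    if (nrow(sc$pairs) < cfg$minInliers) return()
    if (is.null(best) || sc$selectionScore < best$selectionScore)
      best <<- sc
  }
  for (side in 1:2) {
    g <- if (side == 1) g1 else g2
    map <- if (side == 1) map12 else map21
    for (v in g@nodes$id) {
      key <- as.character(v)
      if (!key %in% names(map)) next
      deg <- g@nodes$degree[match(v, g@nodes$id)]
      if (!deg %in% c(2L, 3L)) next
      nbrs <- neighborIds(g, v)
      nbrs <- nbrs[as.character(nbrs) %in% names(map)]
      if (length(nbrs) < 2) next
      for (sub in neighborSubsets(nbrs, cfg)) {
        nb <- nbrs[sub]
        partner <- unname(map[as.character(c(v, nb))])
        if (side == 1) consider(v, nb, partner[1], partner[-1])
        else consider(partner[1], partner[-1], v, nb)
      }
    }
  }
  if (is.null(best))
    stop(errorCondition("insufficient stable structures",
                        class = c("fundusregNoStableStructures",
                                  "error", "condition")))
  inl <- new("CorrespondenceSet",
             pairs = data.frame(g1 = best$pairs$g1, g2 = best$pairs$g2,
                                confidence = 1 / (1 + best$pairs$dist)),
             method = "struct-sac")
  list(transform = best$transform, epsilon = best$epsilon,
       selectionScore = best$selectionScore, inliers = inl)
}
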