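# Shared fixture builders: small images, skeletons and attributed graphs
# constructed in code.

## flat image with a dark bar of Gaussian cross profile at a given
## orientation through the center
barImage <- function(n = 64, thetaDeg = 0, depth = 0.5, width = 1.5,
                     bg = 0.8) {
  g <- expand.grid(r = seq_len(n) - 1, c = seq_len(n) - 1)
  ctr <- (n - 1) / 2
  # signed distance from the line through the center at thetaDeg
  d <- -(g$r - ctr) * cos(thetaDeg * pi / 180) -
    (g$c - ctr) * sin(thetaDeg * pi / 180)
  FundusImage(matrix(pmax(0, bg - depth * exp(-d^2 / (2 * width^2))), n, n))
}

## skeleton mask from 0-based point rows
maskFromPoints <- function(pts, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[cbind(pts[, 1] + 1, pts[, 2] + 1)] <- TRUE
  new("CenterlineImage", mask = m, guaranteedThin = TRUE)
}

## plus-sign skeleton centred in an n x n frame, arm length a
plusSkeleton <- function(n = 21, a = 8) {
  c0 <- (n - 1) %/% 2
  pts <- rbind(cbind(c0 - a:1, c0), cbind(c0 + 1:a, c0),
               cbind(c0, c0 - a:1), cbind(c0, c0 + 1:a), cbind(c0, c0))
  maskFromPoints(pts, n, n)
}

## straight horizontal line skeleton
lineSkeleton <- function(len = 10, n = 20, row = 10) {
  maskFromPoints(cbind(rep(row, len), seq_len(len) + 3), n, n)
}

## attributed graph from explicit tables (positions 0-based)
graphFromTables <- function(nodes, edges, shape = c(200L, 200L)) {
  if (is.null(nodes$degree)) {
    d <- table(factor(c(edges$from, edges$to), levels = nodes$id))
    nodes$degree <- as.integer(d)
  }
  if (is.null(nodes$kind))
    nodes$kind <- ifelse(nodes$degree == 1, "endpoint", "bifurcation")
  if (is.null(edges$path))
    edges$path <- replicate(nrow(edges), NULL, simplify = FALSE)
  fundusreg:::makeVascularGraph(nodes, edges, shape)
}

## random connected attributed graph: spanning tree plus extra edges,
## random node positions; dvp inflated above the Euclidean distance
randomGraph <- function(n, extraEdges = 1L, shape = c(200L, 200L)) {
  nodes <- data.frame(id = seq_len(n),
                      row = runif(n, 10, shape[1] - 10),
                      col = runif(n, 10, shape[2] - 10))
  from <- to <- integer(0)
  for (v in 2:n) { from <- c(from, sample(v - 1L, 1)); to <- c(to, v) }
  tries <- 0
  while (extraEdges > 0 && tries < 50) {
    cand <- sort(sample(n, 2))
    tries <- tries + 1
    if (any(from == cand[1] & to == cand[2])) next
    from <- c(from, cand[1]); to <- c(to, cand[2])
    extraEdges <- extraEdges - 1L
  }
  p1 <- as.matrix(nodes[from, c("row", "col")])
  p2 <- as.matrix(nodes[to, c("row", "col")])
  de <- sqrt(rowSums((p1 - p2)^2))
  edges <- data.frame(from = from, to = to,
                      dvp = de * runif(length(de), 1.0, 1.4), de = de)
  graphFromTables(nodes, edges, shape)
}

## node-index permutation of a graph (relabels ids by perm)
permuteGraph <- function(g, perm) {
  n <- nodes(g); e <- edges(g)
  map <- stats::setNames(perm, n$id)
  n$id <- unname(map[as.character(n$id)])
  e$from <- unname(map[as.character(e$from)])
  e$to <- unname(map[as.character(e$to)])
  o <- order(n$id)
  fundusreg:::makeVascularGraph(n[o, ], e, g@sourceShape)
}

## brute-force optimum of the matching objective over all permutations
## (equal-size graphs); returns the best objective value
bruteForceOptimum <- function(w) {
  n <- w@n1
  stopifnot(w@n2 == n, n <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    M <- matrix(0, n, n)
    M[cbind(seq_len(n), p)] <- 1
    val <- matchingObjective(w, M)
    if (val > best) best <- val
  }
  best
}

## default quick phantom spec for tests
testSpec <- function(seed, treeDepth = 3L, ...) {
  phantomSpec(seed = seed, imageShape = c(300L, 360L), rootLength = 95,
              treeDepth = treeDepth, ...)
}
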