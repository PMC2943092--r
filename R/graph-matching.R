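# Global node correspondences between two vascular structure graphs by
# graduated assignment on a bistochastically normalized edge-compatibility
# matrix.  The matching objective is
#   E(M) = sum_{i,i',j,j'} M[i,i'] M[j,j'] W[i,i',j,j']
# over one-to-one (doubly substochastic) assignments M, where the
# compatibility W[i,i',j,j'] compares the normalized vessel-path and
# Euclidean attributes of edge (i,j) in G1 with edge (i',j') in G2 and is
# zero when either edge is absent.

#' CompatibilityMatrix: pairwise edge affinities between two graphs
#'
#' Sparse representation over existing edge pairs: the full
#' \code{N1 N2 x N1 N2} compatibility matrix is fully determined by the
#' \code{|E1| x |E2|} edge similarity grid \code{sim} plus the edge-to-node
#' incidence of both graphs.
#'
#' @slot sim numeric |E1| x |E2| edge similarity matrix
#' @slot e1,e2 integer matrices (|E| x 2) of node indices per edge
#' @slot n1,n2 node counts of the two graphs
#' @export
setClass("CompatibilityMatrix",
  representation(sim = "matrix", e1 = "matrix", e2 = "matrix",
                 n1 = "integer", n2 = "integer"))

setMethod("show", "CompatibilityMatrix", function(object) {
  cat(sprintf("CompatibilityMatrix: %d x %d edge pairs (graphs %d / %d nodes)\n",
              nrow(object@sim), ncol(object@sim), object@n1, object@n2))
})

#' SoftAssignment: continuous match variables of graduated assignment
#'
#' @slot m numeric N1 x N2 matrix of nonnegative match variables (the
#'   non-slack block of the slack-augmented doubly substochastic matrix)
#' @slot beta final annealing inverse temperature
#' @slot objective trace of the matching objective per annealing step
#' @export
setClass("SoftAssignment",
  representation(m = "matrix", beta = "numeric", objective = "numeric"))

setMethod("show", "SoftAssignment", function(object) {
  cat(sprintf("SoftAssignment %d x %d, beta = %.3f, objective = %.5f\n",
              nrow(object@m), ncol(object@m), object@beta,
              utils::tail(object@objective, 1)))
})

#' Edge-compatibility between two vascular graphs
#'
#' \code{W = omega1 (1 - |dA1| / L1) + omega2 (1 - |dA2| / L2)} over pairs
#' of existing edges, where \code{dAr} compares the normalized attributes
#' (vessel-path, Euclidean) and \code{Lr} is the maximum of attribute r over
#' both graphs; absent edge pairs have zero compatibility.
#'
#' @param g1,g2 \linkS4class{VascularGraph} objects with at least one edge
#' @param omega1,omega2 attribute weights summing to 1 (defaults 0.5 / 0.5)
#' @return a \linkS4class{CompatibilityMatrix}
#' @export
computeCompatibility <- function(g1, g2, omega1 = 0.5, omega2 = 0.5) {
  e1 <- g1@edges; e2 <- g2@edges
  if (nrow(e1) == 0L || nrow(e2) == 0L)
    stop(errorCondition("both graphs need at least one edge",
                        class = c("fundusregEmptyGraph", "error", "condition")))
  stopifnot(abs(omega1 + omega2 - 1) < 1e-9)
  L1 <- max(e1$a1, e2$a1)
  L2 <- max(e1$a2, e2$a2)
  sim <- omega1 * (1 - abs(outer(e1$a1, e2$a1, "-")) / L1) +
         omega2 * (1 - abs(outer(e1$a2, e2$a2, "-")) / L2)
  idx1 <- cbind(match(e1$from, g1@nodes$id), match(e1$to, g1@nodes$id))
  idx2 <- cbind(match(e2$from, g2@nodes$id), match(e2$to, g2@nodes$id))
  new("CompatibilityMatrix", sim = sim,
      e1 = matrix(as.integer(idx1), ncol = 2),
      e2 = matrix(as.integer(idx2), ncol = 2),
      n1 = nrow(g1@nodes), n2 = nrow(g2@nodes))
}

#' Bistochastic (Sinkhorn) normalization of an edge similarity matrix
#'
#' Alternating row then column normalization until the change between
#' successive full sweeps falls below \code{tol} or \code{maxIter} sweeps
#' are reached.  All-zero rows or columns are left untouched.  Balancing the
#' similarity matrix suppresses non-discriminative edges with many potential
#' partners and sharpens edges with few.
#'
#' @param s nonnegative matrix (or \linkS4class{CompatibilityMatrix})
#' @param tol convergence threshold on \code{max |S^(t+2) - S^t|}
#' @param maxIter maximum number of row+column sweeps
#' @return the normalized object, same class as the input
#' @export
bistochasticNormalize <- function(s, tol = 1e-6, maxIter = 100L) {
  obj <- NULL
  if (is(s, "CompatibilityMatrix")) { obj <- s; s <- s@sim }
  for (it in seq_len(maxIter)) {
    prev <- s
    rs <- rowSums(s); rs[rs == 0] <- 1
    s <- s / rs
    cs <- colSums(s); cs[cs == 0] <- 1
    s <- sweep(s, 2, cs, "/")
    if (max(abs(s - prev)) < tol) break
    if (it == maxIter)
      warning("bistochastic normalization did not converge; returning iterate")
  }
  if (is.null(obj)) s else { obj@sim <- s; obj }
}

## sparse (N1 N2) x (N1 N2) compatibility operator: each existing edge pair
## (i,j)~(i',j') supports the four assignment pairs (i,i')-(j,j'),
## (j,j')-(i,i'), (i,j')-(j,i'), (j,i')-(i,j')
#' @keywords internal
compatibilityOperator <- function(w) {
  n1 <- w@n1; n2 <- w@n2
  M1 <- nrow(w@sim); M2 <- ncol(w@sim)
  ep <- expand.grid(e1 = seq_len(M1), e2 = seq_len(M2))
  v <- as.vector(w@sim)
  keep <- v > 0
  ep <- ep[keep, ]; v <- v[keep]
  i <- w@e1[ep$e1, 1]; j <- w@e1[ep$e1, 2]
  u <- w@e2[ep$e2, 1]; vv <- w@e2[ep$e2, 2]
  k <- function(a, b) a + (b - 1L) * n1
  rows <- c(k(i, u), k(j, vv), k(i, vv), k(j, u))
  cols <- c(k(j, vv), k(i, u), k(j, u), k(i, vv))
  Matrix::sparseMatrix(i = rows, j = cols, x = rep(v, 4),
                       dims = c(n1 * n2, n1 * n2))
}

#' Matching objective for a (soft or hard) assignment
#'
#' Evaluates \code{sum M[i,i'] M[j,j'] W[i,i',j,j']} for an assignment
#' matrix over the compatibility of two graphs.
#'
#' @param w a \linkS4class{CompatibilityMatrix}
#' @param m N1 x N2 assignment matrix (binary or soft)
#' @return the scalar objective value
#' @export
matchingObjective <- function(w, m) {
  W <- compatibilityOperator(w)
  v <- as.vector(m)
  as.numeric(v %*% (W %*% v))
}

#' Graduated assignment over a compatibility matrix
#'
#' Deterministic-annealing softassign: at each inverse temperature
#' \code{beta}, the gradient \code{Q[i,i'] = sum_j sum_j' M[j,j'] W[i,i',j,j']}
#' drives the exponential update \code{M <- exp(beta Q)} followed by Sinkhorn
#' row/column normalization on a slack-augmented matrix (one slack row and
#' column absorb unmatched nodes, so graphs of unequal size are handled);
#' \code{beta} grows geometrically from \code{beta0} to \code{betaMax}.
#' The procedure is deterministic: the assignment starts uniform.
#'
#' @param w a \linkS4class{CompatibilityMatrix} (normalize it first with
#'   \code{\link{bistochasticNormalize}} for best results)
#' @param beta0,betaMax,betaGrowth geometric annealing schedule
#' @param innerIter softassign iterations per beta
#' @param sinkhornIter Sinkhorn iterations per softassign step
#' @param tol convergence threshold on the assignment change
#' @return a \linkS4class{SoftAssignment}
#' @export
graduatedAssignment <- function(w, beta0 = 0.5, betaMax = 10,
                                betaGrowth = 1.075, innerIter = 30L,
                                sinkhornIter = 30L, tol = 1e-3) {
  n1 <- w@n1; n2 <- w@n2
  W <- compatibilityOperator(w)
  # the annealing schedule assumes O(1) compatibilities; bistochastic
  # normalization shrinks entries by ~1/|E|, so rescale the gradient so
  # the mean positive compatibility is 1 (a uniform rescaling of W is
  # equivalent to rescaling beta and leaves the objective's argmax
  # unchanged)
  wScale <- mean(w@sim[w@sim > 0])
  if (isTRUE(wScale > 0)) W <- W / wScale
  M <- matrix(1 / (n1 * n2), n1 + 1L, n2 + 1L)   # slack-augmented, uniform
  beta <- beta0
  objTrace <- numeric(0)
  while (beta <= betaMax) {
    for (inner in seq_len(innerIter)) {
      M0 <- M
      Q <- matrix(as.numeric(W %*% as.vector(M[seq_len(n1), seq_len(n2)])),
                  n1, n2)
      # per-row max subtraction avoids overflow; a diagonal row scaling
      # does not change the Sinkhorn limit
      mxr <- pmax(apply(Q, 1, max), 0)
      A <- matrix(1, n1 + 1L, n2 + 1L)           # slack row: Q = 0
      A[seq_len(n1), seq_len(n2)] <- exp(beta * (Q - mxr))
      A[seq_len(n1), n2 + 1L] <- exp(beta * (0 - mxr))
      for (s in seq_len(sinkhornIter)) {
        rs <- rowSums(A)[seq_len(n1)]
        A[seq_len(n1), ] <- A[seq_len(n1), ] / rs
        cs <- colSums(A)[seq_len(n2)]
        A[, seq_len(n2)] <- sweep(A[, seq_len(n2), drop = FALSE], 2, cs, "/")
        if (max(abs(rowSums(A)[seq_len(n1)] - 1)) < 1e-9) break
      }
      M <- A
      if (max(abs(M - M0)) < tol) break
    }
    objTrace <- c(objTrace,
                  matchingObjective(w, M[seq_len(n1), seq_len(n2)]))
    beta <- beta * betaGrowth
  }
  new("SoftAssignment", m = M[seq_len(n1), seq_len(n2), drop = FALSE],
      beta = beta / betaGrowth, objective = objTrace)
}

#' Extract hard correspondences from a soft assignment
#'
#' Greedy mutual-maximum rule: a pair (i, i') is accepted iff
#' \code{M[i, i']} is the maximum of both its row and its column and exceeds
#' \code{acceptThreshold}; the output is one-to-one by construction.
#'
#' @param assignment a \linkS4class{SoftAssignment} (or plain matrix)
#' @param acceptThreshold minimum accepted match variable; defaults to
#'   \code{1 / (min(n1, n2) + 1)}
#' @param ids1,ids2 node ids to report (defaults: row/column indices)
#' @return a \linkS4class{CorrespondenceSet}
#' @export
discretizeAssignment <- function(assignment, acceptThreshold = NULL,
                                 ids1 = NULL, ids2 = NULL) {
  m <- if (is(assignment, "SoftAssignment")) assignment@m else assignment
  if (is.null(acceptThreshold))
    acceptThreshold <- 1 / (min(dim(m)) + 1)
  if (is.null(ids1)) ids1 <- seq_len(nrow(m))
  if (is.null(ids2)) ids2 <- seq_len(ncol(m))
  rowMax <- apply(m, 1, max)
  colMax <- apply(m, 2, max)
  hit <- which(m == rowMax[row(m)] & m == colMax[col(m)] &
                 m > acceptThreshold, arr.ind = TRUE)
  if (nrow(hit) > 0) {                    # guard against tied duplicates
    hit <- hit[!duplicated(hit[, 1]) & !duplicated(hit[, 2]), , drop = FALSE]
  }
  new("CorrespondenceSet",
      pairs = data.frame(g1 = ids1[hit[, 1]], g2 = ids2[hit[, 2]],
                         confidence = m[hit]),
      method = "graduated-assignment")
}

#' Match two vascular graphs end to end
#'
#' Compatibility computation, bistochastic normalization, graduated
#' assignment and discretization in one call.
#'
#' @param g1,g2 \linkS4class{VascularGraph} objects
#' @param omega1,omega2 attribute weights
#' @param normalize apply bistochastic normalization to the edge
#'   similarity matrix before matching
#' @param ... passed to \code{\link{graduatedAssignment}}
#' @return a \linkS4class{CorrespondenceSet} whose pairs reference node ids
#' @export
matchGraphs <- function(g1, g2, omega1 = 0.5, omega2 = 0.5,
                        normalize = FALSE, ...) {
  w <- computeCompatibility(g1, g2, omega1, omega2)
  if (normalize) w <- bistochasticNormalize(w)
  sa <- graduatedAssignment(w, ...)
  discretizeAssignment(sa, ids1 = g1@nodes$id, ids2 = g2@nodes$id)
}
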