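# Compatibility, bistochastic normalization, graduated assignment

test_that("compatibility is 1 for an edge matched to itself and 0 at maximal difference", {
  set.seed(31)
  g <- randomGraph(6)
  w <- computeCompatibility(g, g)
  expect_equal(diag(w@sim), rep(1, nrow(edges(g))))

  # construct two graphs whose single-edge attributes sit at the extremes
  mk <- function(d) {
    graphFromTables(data.frame(id = 1:3, row = c(0, 0, 0),
                               col = c(0, d, d + 10)),
                    data.frame(from = c(1, 2), to = c(2, 3),
                               dvp = c(d, 10), de = c(d, 10)))
  }
  ga <- mk(100); gb <- mk(100)
  w2 <- computeCompatibility(ga, gb)
  # edge 1 of ga vs edge 2 of gb: both attribute differences equal L_r
  L1 <- max(edges(ga)$a1, edges(gb)$a1)
  expect_equal(abs(edges(ga)$a1[1] - edges(gb)$a1[2]), L1 - min(edges(ga)$a1))
  expect_gte(min(w2@sim), 0)
  expect_lte(max(w2@sim), 1)
})

test_that("the sparse compatibility agrees entrywise with a dense brute-force Eq. evaluation", {
  set.seed(32)
  g1 <- randomGraph(6); g2 <- randomGraph(6)
  w <- computeCompatibility(g1, g2)
  W <- as.matrix(fundusreg:::compatibilityOperator(w))
  n1 <- w@n1; n2 <- w@n2
  e1 <- edges(g1); e2 <- edges(g2)
  L1 <- max(e1$a1, e2$a1); L2 <- max(e1$a2, e2$a2)
  edgeAt <- function(e, a, b)
    which((e$from == a & e$to == b) | (e$from == b & e$to == a))
  dense <- matrix(0, n1 * n2, n1 * n2)
  for (i in 1:n1) for (ip in 1:n2) for (j in 1:n1) for (jp in 1:n2) {
    if (i == j || ip == jp) next
    ei <- edgeAt(e1, nodes(g1)$id[i], nodes(g1)$id[j])
    ej <- edgeAt(e2, nodes(g2)$id[ip], nodes(g2)$id[jp])
    if (length(ei) == 0 || length(ej) == 0) next
    v <- 0.5 * (1 - abs(e1$a1[ei[1]] - e2$a1[ej[1]]) / L1) +
         0.5 * (1 - abs(e1$a2[ei[1]] - e2$a2[ej[1]]) / L2)
    dense[i + (ip - 1) * n1, j + (jp - 1) * n1] <- v
  }
  expect_equal(W, dense, tolerance = 1e-12)
})

test_that("bistochastic normalization converges on positive matrices and matches a literal iteration oracle", {
  set.seed(33)
  s <- matrix(runif(25, 0.2, 1), 5, 5)
  n <- bistochasticNormalize(s, tol = 1e-10, maxIter = 500)
  expect_equal(unname(rowSums(n)), rep(1, 5), tolerance = 1e-6)
  expect_equal(unname(colSums(n)), rep(1, 5), tolerance = 1e-6)

  # rectangular case equals a literal row-then-column iteration
  s2 <- matrix(runif(35, 0.1, 1), 5, 7)
  oracle <- s2
  for (it in 1:40) {
    oracle <- oracle / rowSums(oracle)
    oracle <- sweep(oracle, 2, colSums(oracle), "/")
  }
  mine <- suppressWarnings(bistochasticNormalize(s2, tol = 0, maxIter = 40))
  expect_equal(mine, oracle, tolerance = 1e-12)

  # a permutation-like matrix converges almost immediately
  p <- diag(5) * 0.9 + 0.01
  np <- bistochasticNormalize(p, tol = 1e-8, maxIter = 10)
  expect_gt(min(diag(np)), 0.9)
})

test_that("self-matching recovers the identity and relabeled copies the permutation", {
  set.seed(34)
  g <- randomGraph(6)
  m <- matchGraphs(g, g)
  p <- matchedPairs(m)
  expect_equal(nrow(p), 6)
  expect_equal(p$g1, p$g2)

  perm <- sample(6)
  gp <- permuteGraph(g, perm)
  mp <- matchGraphs(g, gp)
  pp <- matchedPairs(mp)
  expect_equal(nrow(pp), 6)
  expect_equal(pp$g2, perm[pp$g1])
})

test_that("Sinkhorn two-way constraints hold on the converged soft assignment", {
  set.seed(35)
  g1 <- randomGraph(7); g2 <- randomGraph(5)
  sa <- graduatedAssignment(computeCompatibility(g1, g2))
  expect_true(all(sa@m >= 0))
  expect_lte(max(rowSums(sa@m)), 1 + 1e-6)
  expect_lte(max(colSums(sa@m)), 1 + 1e-6)
})

test_that("the matching objective is non-decreasing over the annealing", {
  set.seed(36)
  g1 <- randomGraph(7); g2 <- randomGraph(7)
  sa <- graduatedAssignment(computeCompatibility(g1, g2))
  tr <- sa@objective
  # small dips near the discrete limit come from Sinkhorn truncation
  expect_true(all(diff(tr) >= -0.01 * max(abs(tr))))
})

test_that("discretization extracts mutual maxima one-to-one", {
  m <- rbind(c(0.9, 0.05, 0.02),
             c(0.1, 0.85, 0.1),
             c(0.05, 0.1, 0.7))
  cs <- discretizeAssignment(m, acceptThreshold = 0.5)
  expect_equal(matchedPairs(cs)$g1, 1:3)
  expect_equal(matchedPairs(cs)$g2, 1:3)

  uni <- matrix(1 / 9, 3, 3)
  expect_equal(nrow(matchedPairs(discretizeAssignment(uni))), 0)
})

test_that("correspondences are invariant to a similarity transform of one graph", {
  set.seed(37)
  for (k in 1:5) {
    g1 <- randomGraph(8, extraEdges = 2)
    g2 <- permuteGraph(g1, sample(8))
    t0 <- SimilarityTransform(runif(1, 0.5, 2), runif(1, -pi, pi),
                              runif(2, -40, 40))
    m1 <- matchedPairs(matchGraphs(g1, g2))
    m2 <- matchedPairs(matchGraphs(g1, transformGraph(g2, t0)))
    expect_identical(m1[order(m1$g1), c("g1", "g2")],
                     m2[order(m2$g1), c("g1", "g2")])
  }
})

test_that("discretized assignments reach the exhaustive optimum on small graphs", {
  set.seed(38)
  hit <- 0; total <- 30
  for (k in seq_len(total)) {
    n <- sample(5:6, 1)
    g1 <- randomGraph(n)
    g2 <- permuteGraph(g1, sample(n))
    w <- computeCompatibility(g1, g2)
    sa <- graduatedAssignment(w)
    cs <- matchedPairs(discretizeAssignment(sa))
    M <- matrix(0, n, n)
    if (nrow(cs) > 0) M[cbind(cs$g1, cs$g2)] <- 1
    if (matchingObjective(w, M) >= bruteForceOptimum(w) - 1e-9)
      hit <- hit + 1
  }
  expect_gte(hit / total, 0.9)
})

test_that("matching tolerates heavy structure noise on phantom graphs", {
  recalls <- vapply(1:8, function(k) {
    spec <- testSpec(300 + k, structureNoise = 0.5,
                     warp = SimilarityTransform(1.05, 0.15, c(5, 10)))
    pair <- makePhantomPair(spec, render = FALSE)
    matchingRecall(matchGraphs(pair$graphRef, pair$graphFloat),
                   pair$trueCorrespondences)
  }, 0)
  expect_gte(mean(recalls, na.rm = TRUE), 0.5)
})
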