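# Similarity and quadratic transforms: application, inversion, estimation

test_that("similarity estimation recovers an exact transform to machine precision", {
  set.seed(21)
  src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  t0 <- SimilarityTransform(1.2, 20 * pi / 180, c(5, -3))
  dst <- applyTransform(t0, src)
  est <- estimateSimilarity(src, dst)
  expect_equal(est@scale, 1.2, tolerance = 1e-9)
  expect_equal(est@rotation, 20 * pi / 180, tolerance = 1e-9)
  expect_equal(est@translation, c(5, -3), tolerance = 1e-9)

  # two points determine the similarity exactly
  est2 <- estimateSimilarity(src[1:2, ], dst[1:2, ])
  expect_equal(applyTransform(est2, src[1:2, ]), dst[1:2, ],
               tolerance = 1e-9)
  expect_error(estimateSimilarity(matrix(1, 3, 2), dst[1:3, ]),
               class = "fundusregDegenerate")
})

test_that("similarity estimation under jitter agrees with vegan's Procrustes", {
  skip_if_not_installed("vegan")
  set.seed(22)
  src <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  t0 <- SimilarityTransform(0.9, -0.3, c(10, 4))
  dst <- applyTransform(t0, src) + matrix(rnorm(20, 0, 0.5), 10, 2)
  est <- estimateSimilarity(src, dst)
  pr <- vegan::procrustes(dst, src)         # rotates src onto dst
  expect_equal(est@scale, pr$scale, tolerance = 1e-6)
  fit <- applyTransform(est, src)
  expect_equal(unname(fit), unname(fitted(pr, truemean = TRUE)),
               tolerance = 1e-6)
})

test_that("similarity inversion composes to the identity", {
  t0 <- SimilarityTransform(1.4, 0.7, c(12, -8))
  p <- cbind(c(0, 10, 55), c(3, -2, 40))
  expect_equal(applyTransform(invertTransform(t0), applyTransform(t0, p)),
               p, tolerance = 1e-12)
})

test_that("quadratic application matches direct polynomial evaluation", {
  set.seed(23)
  co <- matrix(rnorm(12, 0, 0.01), 2, 6)
  q <- QuadraticTransform(co)
  p <- cbind(runif(5, -5, 5), runif(5, -5, 5))
  direct <- t(apply(p, 1, function(x)
    c(sum(co[1, ] * c(x[1]^2, x[2]^2, x[1] * x[2], x[1], x[2], 1)),
      sum(co[2, ] * c(x[1]^2, x[2]^2, x[1] * x[2], x[1], x[2], 1)))))
  expect_equal(applyTransform(q, p), direct, tolerance = 1e-12)

  expect_equal(applyTransform(identityQuadratic(), p), p)
  shift <- QuadraticTransform(rbind(c(0, 0, 0, 1, 0, 4),
                                    c(0, 0, 0, 0, 1, -2)))
  expect_equal(applyTransform(shift, p), p + rep(c(4, -2), each = 5))
})

test_that("an embedded similarity equals the original map", {
  t0 <- SimilarityTransform(1.1, 0.3, c(2, 7))
  q <- similarityToQuadratic(t0)
  p <- cbind(runif(6, 0, 50), runif(6, 0, 50))
  expect_equal(applyTransform(q, p), applyTransform(t0, p),
               tolerance = 1e-12)
})

test_that("quadratic fitting recovers exact coefficients and annihilates the quadratic block for affine data", {
  set.seed(24)
  p <- cbind(runif(20, 0, 300), runif(20, 0, 300))
  co <- rbind(c(2e-4, -1e-4, 5e-5, 1.05, 0.1, 4),
              c(-5e-5, 2e-4, -1e-4, -0.1, 0.95, -2))
  q <- QuadraticTransform(co)
  fit <- fitQuadratic(p, applyTransform(q, p))
  expect_equal(fit@coeffs, co, tolerance = 1e-8)

  aff <- SimilarityTransform(1.1, 0.2, c(3, -1))
  fitA <- fitQuadratic(p, applyTransform(aff, p))
  expect_lt(max(abs(fitA@coeffs[, 1:3])), 1e-8)

  expect_error(fitQuadratic(p[, c(1, 1)], p), class = "fundusregDegenerate")
})

test_that("noisy quadratic fits equal an explicit normal-equations oracle", {
  set.seed(25)
  p <- cbind(runif(40, 0, 200), runif(40, 0, 200))
  co <- rbind(c(1e-4, 0, -5e-5, 1, 0.05, 2),
              c(0, -1e-4, 5e-5, -0.05, 1, -3))
  d <- applyTransform(QuadraticTransform(co), p) +
    matrix(rnorm(80, 0, 0.3), 40, 2)
  w <- runif(40, 0.5, 1)
  fit <- fitQuadratic(p, d, w)
  X <- cbind(p[, 1]^2, p[, 2]^2, p[, 1] * p[, 2], p[, 1], p[, 2], 1)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * d))   # oracle
  expect_equal(fit@coeffs, t(beta), tolerance = 1e-6)
})

test_that("the numeric quadratic inverse matches the forward map", {
  co <- rbind(c(1e-4, -4e-5, 2e-5, 1.08, 0.06, 5),
              c(3e-5, 8e-5, -2e-5, -0.06, 1.02, -4))
  q <- QuadraticTransform(co)
  p <- cbind(runif(30, 0, 400), runif(30, 0, 400))
  inv <- invertTransform(q)
  expect_equal(unname(inv(applyTransform(q, p))), unname(p),
               tolerance = 1e-6)
})
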