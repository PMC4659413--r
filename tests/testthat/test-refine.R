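# Scale estimation, GGMRF energy, total energy and ICM refinement.

# tiny helper: a graph over an H x W image with given edges and beta
.tinyGraph <- function(H, W, edges, beta, k = NA_real_,
                       betaScaled = numeric(0)) {
  new("DistanceGraph", edges = edges, beta = beta,
      betaScaled = betaScaled, k = k, dim = c(as.integer(H), as.integer(W)), nS = 3L,
      nCnx = 0L)
}

test_that("scale estimation solves the least-squares stretch on the
          0.005 grid", {
  # two edges, beta = {10, 20}, ||du|| = {1, 3}:
  # k = (10*1 + 20*3) / (100 + 400) = 0.14, already on-grid
  u <- array(0, dim = c(1, 3, 3))
  u[1, 2, 1] <- 1          # pixel 2 at L = 1
  u[1, 3, 1] <- 4          # pixel 3 at L = 4 (3 away from pixel 2)
  g <- .tinyGraph(1, 3, cbind(c(1L, 2L), c(2L, 3L)), c(10, 20))
  g <- estimateScale(g, u)
  expect_equal(scaleFactor(g), 0.14)
  expect_equal(edgeBetaScaled(g), c(1.4, 2.8))

  # perfect embedding: k = 1 (boundary of the admissible range)
  gPerf <- .tinyGraph(1, 3, cbind(c(1L, 2L), c(2L, 3L)), c(1, 3))
  expect_equal(scaleFactor(estimateScale(gPerf, u)), 1)

  # off-grid least squares snaps to the nearest 0.005 multiple
  gOff <- .tinyGraph(1, 3, cbind(c(1L, 2L), c(2L, 3L)), c(10, 20))
  uOff <- u; uOff[1, 3, 1] <- 1 + 2.04
  k <- scaleFactor(estimateScale(gOff, uOff))
  expect_equal(k %% 0.005, 0, tolerance = 1e-12)

  # all-zero beta: k = 0 by convention
  gZero <- .tinyGraph(1, 3, cbind(c(1L, 2L), c(2L, 3L)), c(0, 0))
  expect_equal(scaleFactor(estimateScale(gZero, u)), 0)
})

test_that("GGMRF energy applies the documented clique weights", {
  expect_equal(gaitmapDefaults()$gammaStraight, 1 / (2 * sqrt(2) + 4))
  expect_equal(gaitmapDefaults()$gammaDiagonal, 1 / (4 + 4 * sqrt(2)))

  # constant image
  expect_equal(ggmrfEnergy(array(3, dim = c(4, 4, 3)), q = 1), 0)

  # 1 x 2 image, du = (3, 0, 0), q = 2: one horizontal clique
  u <- array(0, dim = c(1, 2, 3)); u[1, 2, 1] <- 3
  expect_equal(ggmrfEnergy(u, q = 2), 9 / (2 * sqrt(2) + 4))
  # q = 1 uses |.|: 3 instead of 9
  expect_equal(ggmrfEnergy(u, q = 1), 3 / (2 * sqrt(2) + 4))

  # 2 x 2 image with one nonzero pixel: 2 straight + 1 diagonal clique
  u2 <- array(0, dim = c(2, 2, 3)); u2[1, 1, 1] <- 2
  expect_equal(ggmrfEnergy(u2, q = 1),
               2 * 2 / (2 * sqrt(2) + 4) + 2 / (4 + 4 * sqrt(2)))

  expect_error(ggmrfEnergy(u, q = 0.5), "\\[1, 2\\]")
})

test_that("total energy is fit plus eta times the prior", {
  u <- array(0, dim = c(1, 2, 3)); u[1, 2, 1] <- 3
  g <- .tinyGraph(1, 2, cbind(1L, 2L), beta = 10,
                  betaScaled = 4, k = 0.4)
  # fit: (4 - 3)^2 = 1; prior: 3 * gammaStraight
  expect_equal(totalEnergy(u, g, eta = 0, q = 1), 1)
  expect_equal(totalEnergy(u, g, eta = 0.025, q = 1),
               1 + 0.025 * 3 / (2 * sqrt(2) + 4))
  # perfect embedding at eta = 0
  gP <- .tinyGraph(1, 2, cbind(1L, 2L), beta = 10, betaScaled = 3,
                   k = 0.3)
  expect_equal(totalEnergy(u, gP, eta = 0), 0)
})

test_that("a perfect embedding is an ICM fixed point at eta = 0", {
  u <- array(0, dim = c(1, 2, 3)); u[1, 2, 1] <- 3
  g <- .tinyGraph(1, 2, cbind(1L, 2L), beta = 10, betaScaled = 3,
                  k = 0.3)
  out <- icmRefine(u, g, eta = 0, radius = 0.5, sweeps = 5)
  expect_equal(mapValues(out), u)
  expect_equal(provenance(out)$moves[1], 0L)
})

test_that("the two-pixel instance converges to the scaled distance
          within half the exploration radius", {
  u <- array(0, dim = c(1, 2, 3))
  u[1, 2, 1] <- 1                        # start far from beta_scaled
  g <- .tinyGraph(1, 2, cbind(1L, 2L), beta = 10, betaScaled = 7.3,
                  k = 0.73)
  out <- icmRefine(u, g, eta = 0, radius = 1, sweeps = 50)
  gap <- sqrt(sum((mapValues(out)[1, 1, ] - mapValues(out)[1, 2, ])^2))
  expect_lte(abs(gap - 7.3), 0.5)
  tr <- provenance(out)$energyTrace
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("ICM never increases the energy on a random instance", {
  set.seed(15)
  H <- 6L; W <- 7L
  g <- buildGraph(c(H, W), nS = 5L, nCnx = 4L)
  g@beta <- runif(nrow(graphEdges(g)), 0, 10)
  u0 <- array(rnorm(H * W * 3, sd = 3), dim = c(H, W, 3))
  g <- estimateScale(g, u0)
  out <- icmRefine(u0, g, eta = 0.025, q = 1, radius = 0.5,
                   sweeps = 6)
  tr <- provenance(out)$energyTrace
  expect_true(all(diff(tr) <= 1e-9))
  expect_lt(tr[length(tr)], tr[1])
  # the trace matches independently recomputed energies
  expect_equal(tr[length(tr)],
               totalEnergy(out, g, eta = 0.025, q = 1))
})

test_that("correlation score matches the textbook Pearson formula", {
  set.seed(16)
  g <- .tinyGraph(1, 4, cbind(c(1L, 1L, 2L, 3L), c(2L, 3L, 4L, 4L)),
                  beta = c(2, 4, 6, 8))
  u <- array(rnorm(12), dim = c(1, 4, 3))
  U <- matrix(u, 4, 3)
  d <- apply(graphEdges(g), 1,
             function(e) sqrt(sum((U[e[1], ] - U[e[2], ])^2)))
  b <- edgeBeta(g)
  rho <- sum((b - mean(b)) * (d - mean(d))) /
    sqrt(sum((b - mean(b))^2) * sum((d - mean(d))^2))
  expect_equal(correlationScore(g, u), rho, tolerance = 1e-12)

  # perfect chain embedding: rho = 1
  gc <- .tinyGraph(1, 4, cbind(1:3, 2:4), beta = c(2, 4, 6))
  uP <- array(0, dim = c(1, 4, 3))
  uP[1, , 1] <- c(0, 2, 6, 12)           # edge distances 2, 4, 6
  expect_equal(correlationScore(gc, uP), 1)

  # anti-ordered distances: negative correlation
  uN <- array(0, dim = c(1, 4, 3))
  uN[1, , 1] <- c(0, 6, 10, 12)          # edge distances 6, 4, 2
  expect_lt(correlationScore(gc, uN), 0)

  gFlat <- .tinyGraph(1, 4, cbind(c(1L, 2L), c(2L, 3L)), c(3, 3))
  expect_error(correlationScore(gFlat, u), "equal")
})
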