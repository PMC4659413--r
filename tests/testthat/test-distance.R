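# Shift-invariant distance family and the pixel-pair graph.

test_that("all distance kinds vanish on identical signals", {
  set.seed(2)
  s <- round(rnorm(60, 2500, 100))
  for (kind in c("L2", "L1", "Linf", "Lmod", "Lrad", "Lmoy"))
    expect_equal(shiftDistance(s, s, shiftDistanceSpec(kind = kind)), 0)
})

test_that("a circular shift on the search grid is invisible", {
  set.seed(4)
  s <- round(rnorm(120, 2500, 120))
  spec <- shiftDistanceSpec()   # {0, 6, ..., 66}
  for (tau in seq(0, 66, by = 6)) {
    shifted <- s[((seq_along(s) - 1 + tau) %% length(s)) + 1]
    expect_equal(shiftDistance(s, shifted, spec), 0)
    expect_equal(shiftDistance(shifted, s, spec), 0)  # symmetrised
  }
  expect_equal(shiftDistance(s, shifted,
                             shiftDistanceSpec(kind = "Lmod")), 0)
})

test_that("shifted norms equal the exhaustive brute-force minimum", {
  set.seed(5)
  spec <- shiftDistanceSpec(tauMax = 11L, tauStep = 1L)
  for (rep in 1:25) {
    s1 <- round(rnorm(12, 0, 50)); s2 <- round(rnorm(12, 0, 50))
    for (kind in c("L2", "L1", "Linf")) {
      sp <- shiftDistanceSpec(kind = kind, tauMax = 11L, tauStep = 1L)
      expect_equal(shiftDistance(s1, s2, sp),
                   bruteShiftDist(s1, s2, 0:11, kind))
    }
  }
})

test_that("the mean distance is blind to mean-preserving asymmetry", {
  s1 <- c(rep(0, 30), rep(100, 30))
  s2 <- rep(50, 60)          # same mean, different movement
  expect_equal(shiftDistance(s1, s2,
                             shiftDistanceSpec(kind = "Lmoy")), 0)
  expect_gt(shiftDistance(s1, s2, shiftDistanceSpec()), 0)
})

test_that("shift distance is symmetric and invariant to a common
          on-grid shift", {
  set.seed(6)
  spec <- shiftDistanceSpec(tauMax = 12L, tauStep = 3L)
  for (rep in 1:10) {
    s1 <- round(rnorm(24, 0, 40)); s2 <- round(rnorm(24, 0, 40))
    d12 <- shiftDistance(s1, s2, spec)
    expect_gte(d12, 0)
    expect_equal(d12, shiftDistance(s2, s1, spec))
    rot <- function(s, tau) s[((seq_along(s) - 1 + tau) %% 24) + 1]
    expect_equal(shiftDistance(rot(s1, 6), rot(s2, 6), spec), d12)
  }
  expect_error(shiftDistance(1:5, 1:6), "equal length")
})

test_that("graph construction follows the documented placement rule", {
  # 1 x 2 image, no long-range links: exactly one edge
  g <- buildGraph(c(1, 2), nS = 3L, nCnx = 0L)
  expect_equal(nrow(graphEdges(g)), 1L)
  expect_equal(unname(graphEdges(g)[1, ]), c(1L, 2L))

  # full rule against an independent reconstruction on a 5 x 5 image
  g5 <- buildGraph(c(5, 5), nS = 5L, nCnx = 6L)
  e <- graphEdges(g5)
  e <- e[order(e[, 1], e[, 2]), ]
  expect_equal(unname(e), unname(bruteGraphEdges(5, 5, 5, 6)))

  # default parameters: an interior pixel of a large image reaches its
  # 4 neighbours plus 11 long-range links
  g13 <- buildGraph(c(31, 31), nS = 13L, nCnx = 11L)
  ctr <- (16L - 1L) * 31L + 16L
  deg <- sum(graphEdges(g13) == ctr)
  expect_gte(deg, 15L)

  expect_error(buildGraph(c(5, 5), nS = 4L), "odd")
})

test_that("graph edges are canonical, unique, and include all
          4-neighbour links", {
  g <- buildGraph(c(6, 7), nS = 5L, nCnx = 3L)
  e <- graphEdges(g)
  expect_true(all(e[, 1] < e[, 2]))
  expect_false(any(duplicated(e)))
  H <- 6
  for (r in 1:5) for (cc in 1:7) {
    i <- (cc - 1) * H + r; j <- (cc - 1) * H + r + 1
    expect_true(any(e[, 1] == i & e[, 2] == j))  # vertical neighbour
  }
})

test_that("batched edge distances agree with the pairwise function", {
  spec0 <- walkerSpec(width = 24L, height = 32L, nFrames = 40L,
                      period = 20L, noiseSd = 5, seed = 8L)
  sil <- extractSilhouette(generateWalker(spec0), walkerScene(spec0),
                           walkerCamera(spec0))
  g <- buildGraph(frameSize(sil), nS = 5L, nCnx = 4L)
  S <- signalMatrix(sil)
  set.seed(9)
  for (kind in c("L2", "L1", "Linf", "Lmod", "Lrad", "Lmoy")) {
    sp <- shiftDistanceSpec(kind = kind, tauMax = 12L, tauStep = 4L)
    gd <- computeDistances(sil, g, sp)
    expect_true(all(edgeBeta(gd) >= 0))
    pick <- sample(nrow(graphEdges(gd)), 12)
    for (i in pick) {
      e <- graphEdges(gd)[i, ]
      expect_equal(edgeBeta(gd)[i],
                   shiftDistance(S[e[1], ], S[e[2], ], sp),
                   tolerance = 1e-9)
    }
  }
})

test_that("constant sequences give all-zero graph distances", {
  fr <- array(1234L, dim = c(4, 5, 6))
  sil <- new("SilhouetteSequence", frames = fr, fps = 30,
             mask = array(TRUE, dim(fr)), clipValue = 1234,
             bounds = c(uMin = 0, uMax = 4, vMin = 0, vMax = 3,
                        zMin = 1, zMax = 5000))
  g <- computeDistances(sil, buildGraph(c(4, 5), nS = 3L, nCnx = 2L))
  expect_true(all(edgeBeta(g) == 0))
})
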