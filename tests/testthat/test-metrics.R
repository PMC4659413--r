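# Longitudinal axis, ASI curve/index, paired comparisons.

test_that("the axis of a mirror-symmetric silhouette is its midline", {
  mask <- matrix(FALSE, 20, 15)
  mask[3:18, 5:11] <- TRUE          # symmetric about column 8
  mask[10:18, 7:9] <- TRUE
  expect_equal(estimateAxis(mask), 8L)
})

test_that("an off-centre silhouette is recovered by the median
          mismatch, matching the brute-force search", {
  mask <- matrix(FALSE, 24, 21)
  mask[3:20, 8:16] <- TRUE          # symmetric about column 12
  mask[12:20, c(9, 15)] <- TRUE     # extra symmetric detail
  mask[5, 8:10] <- TRUE             # small asymmetric blemish
  ax <- estimateAxis(mask, searchHalfwidth = 10L)
  # independent exhaustive evaluation over the +-10 window
  rows <- which(rowSums(mask) > 0)
  l <- sapply(rows, function(r) which(mask[r, ])[1])
  r <- sapply(rows, function(rr) max(which(mask[rr, ])))
  cand <- 1:21
  mm <- sapply(cand, function(cc) median(abs((cc - l) - (r - cc))))
  expect_equal(ax, cand[which.min(mm)])
  expect_equal(ax, 12L)
  expect_error(estimateAxis(matrix(FALSE, 3, 3)), "contour")
})

test_that("the ASI curve records the largest mirrored colour
          difference per row", {
  # single differing pair: left (50,10,0) vs right (50,-10,0) -> 20
  v <- array(0, dim = c(1, 5, 3))
  v[1, 2, ] <- c(50, 10, 0)
  v[1, 4, ] <- c(50, -10, 0)
  expect_equal(unname(asiCurve(v, axis = 3L)), 20)

  # mirror-symmetric map: all-zero curve
  set.seed(19)
  vs <- array(rnorm(4 * 7 * 3), dim = c(4, 7, 3))
  vs[, 5:7, ] <- vs[, 3:1, ]
  expect_true(all(asiCurve(vs, axis = 4L) == 0))

  # toy 3-row map against exhaustive search over offsets
  v3 <- array(rnorm(3 * 7 * 3), dim = c(3, 7, 3))
  got <- asiCurve(v3, axis = 4L)
  for (k in 1:3) {
    best <- max(sapply(1:3, function(i)
      sqrt(sum((v3[k, 4 - i, ] - v3[k, 4 + i, ])^2))))
    expect_equal(unname(got[k]), best)
  }
  expect_error(asiCurve(v3, axis = 1L), "half-width")
})

test_that("the ASI index is the curve mean and scales with the map", {
  expect_equal(asiIndex(c(10, 20, 30)), 20)
  expect_equal(asiIndex(rep(0, 5)), 0)
  expect_error(asiIndex(numeric(0)), "empty")

  set.seed(20)
  v <- array(rnorm(4 * 9 * 3), dim = c(4, 9, 3))
  mask <- matrix(TRUE, 4, 9)
  a1 <- computeAsi(v, mask, searchHalfwidth = 2L)
  v2 <- v; v2[, , 2:3] <- 2 * v2[, , 2:3]; v2[, , 1] <- 0
  vAB <- v; vAB[, , 1] <- 0
  a2 <- computeAsi(vAB, mask, searchHalfwidth = 2L)
  a3 <- computeAsi(v2, mask, searchHalfwidth = 2L)
  # doubling A and B doubles the index (homogeneity of the norm)
  expect_equal(asiIndex(a3), 2 * asiIndex(a2), tolerance = 1e-9)
  expect_s4_class(a1, "AsiResult")
  expect_equal(a1@index, mean(a1@curve))
})

test_that("the ASI is invariant under mirroring the map about the
          estimated axis", {
  spec <- walkerSpec(noiseSd = 5, seed = 21L, lldOffset = 50,
                     lldSide = "left")
  res <- gaitAsymmetry(generateWalker(spec), walkerScene(spec),
                       walkerCamera(spec), refine = FALSE)
  ax <- asiAxis(res$asi)
  v <- mapValues(res$map)
  m <- res$asi@m
  vm <- v
  vm[, ax + (-m:m), ] <- v[, ax + (m:-m), ]
  mirrored <- asiCurve(vm, ax, silhouetteMask(res$silhouette))
  expect_equal(unname(mirrored), res$asi@curve, tolerance = 1e-9)
})

test_that("rows without silhouette content are excluded from the
          curve", {
  v <- array(0, dim = c(6, 5, 3))
  v[2, 2, 1] <- 30                      # asymmetric row 2
  mask <- matrix(FALSE, 6, 5)
  mask[2:4, 2:4] <- TRUE
  cur <- asiCurve(v, 3L, mask)
  expect_equal(as.integer(names(cur)), 2:4)
  expect_equal(length(cur), 3L)
})

test_that("paired comparisons match the closed-form t statistic", {
  a <- c(16.1, 19.4, 22.0)
  b <- c(21.2, 24.8, 23.9)
  got <- pairedComparison(a, b)
  ref <- brutePairedT(a, b)
  expect_equal(got$t, ref$t, tolerance = 1e-12)
  expect_equal(got$p.value, ref$p, tolerance = 1e-12)
  expect_equal(got$confidence, 1 - ref$p, tolerance = 1e-12)
  expect_equal(got$df, 2)

  # identical groups: t = 0, degenerate
  same <- pairedComparison(a, a)
  expect_equal(same$t, 0)
  expect_true(same$degenerate)

  # constant nonzero differences: infinite t, flagged
  expect_warning(inf <- pairedComparison(a, a + 2), "infinite")
  expect_equal(inf$t, Inf)
  expect_true(inf$degenerate)

  expect_error(pairedComparison(1:3, 1:4), "equal length")
  expect_error(pairedComparison(1, 2), "2 pairs")
})
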