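# Silhouette extraction: bounds, background, treadmill, clipping,
# median filtering.

test_that("computeBounds matches per-corner projection", {
  cam <- CameraModel()
  # degenerate box: a single repeated corner on the optical axis
  box1 <- matrix(rep(c(0, 0, 1000), each = 8), 8, 3)
  b <- computeBounds(box1, cam, frame = c(480, 640))
  expect_equal(unname(b[c("uMin", "uMax")]), c(240, 240))
  expect_equal(unname(b[c("zMin", "zMax")]), c(1000, 1000))

  # unit box spanning Z in {1500, 2500}: brute force over the corners
  corn <- as.matrix(expand.grid(X = c(-300, 300), Y = c(-400, 500),
                                Z = c(1500, 2500)))
  b2 <- computeBounds(corn, cam, frame = c(480, 640))
  uv <- projectTo2d(corn[, 1], corn[, 2], corn[, 3], cam)
  expect_equal(unname(b2["uMin"]), floor(min(uv[, "u"])))
  expect_equal(unname(b2["uMax"]), ceiling(max(uv[, "u"])))
  expect_equal(unname(b2["vMin"]), floor(min(uv[, "v"])))
  expect_equal(unname(b2["vMax"]), ceiling(max(uv[, "v"])))
  expect_equal(unname(b2[c("zMin", "zMax")]), c(1500, 2500))

  # symmetric box about the optical axis gives bounds symmetric in u
  expect_equal(unname(b2["uMax"] - cam@cu), unname(cam@cu - b2["uMin"]))
  expect_error(computeBounds(cbind(corn[, 1:2], 0), cam, c(480, 640)),
               "Z > 0")
})

test_that("background removal masks by window and depth range", {
  fr <- array(3000L, dim = c(6, 6, 4))
  fr[3, 3, ] <- 1500L          # subject pixel
  fr[4, 4, ] <- 500L           # too close
  fr[2, 2, ] <- 0L             # invalid
  seq <- DepthSequence(fr)
  b <- c(uMin = 1, uMax = 4, vMin = 1, vMax = 4, zMin = 1000,
         zMax = 2000)
  sil <- removeBackground(seq, b)
  expect_equal(dim(sil@frames), c(4, 4, 4))
  expect_true(all(sil@mask[2, 2, ]))         # (3,3) in crop coords
  expect_false(any(sil@mask[3, 3, ]))        # out-of-range depth
  expect_false(any(sil@mask[1, 1, ]))        # invalid 0 depth
  expect_false(any(sil@mask[4, 4, ]))        # background at 3000
})

test_that("treadmill threshold row follows the per-pixel depth rule", {
  cam <- CameraModel()          # f = 575.82, c_v = 240
  # at depth 2000 and T_y = 500: keep rows v < 383.955
  fr <- array(2000L, dim = c(480, 4, 3))
  seq <- DepthSequence(fr)
  b <- c(uMin = 0, uMax = 3, vMin = 0, vMax = 479, zMin = 1,
         zMax = 5000)
  sil <- removeBackground(seq, b)
  out <- removeTreadmill(sil, tY = 500, cam)
  kept <- which(out@mask[, 1, 1])
  expect_equal(max(kept) - 1, 383)    # 0-based rows 0..383 kept
  expect_equal(575.82 * 500 / 2000 + 240, 383.955)

  # monotone in T_y: a larger threshold keeps a superset
  out2 <- removeTreadmill(sil, tY = 600, cam)
  expect_true(all(out2@mask[out@mask]))
  expect_gt(sum(out2@mask), sum(out@mask))

  # d -> infinity limit: threshold row approaches c_v
  frFar <- array(60000L, dim = c(480, 2, 3))
  silFar <- removeBackground(DepthSequence(frFar),
                             c(uMin = 0, uMax = 1, vMin = 0,
                               vMax = 479, zMin = 1, zMax = 65535))
  outFar <- removeTreadmill(silFar, tY = 500, cam)
  expect_lt(max(which(outFar@mask[, 1, 1])) - 1, 246)
})

test_that("smart clipping uses the whole-sequence subject mean", {
  fr <- array(0L, dim = c(2, 2, 2))
  fr[1, 1, ] <- c(900L, 1100L)
  fr[2, 1, ] <- c(1100L, 900L)
  mask <- array(FALSE, dim = dim(fr))
  mask[1, 1, ] <- TRUE; mask[2, 1, ] <- TRUE
  sil <- new("SilhouetteSequence", frames = fr, fps = 30, mask = mask,
             clipValue = NA_real_,
             bounds = c(uMin = 0, uMax = 1, vMin = 0, vMax = 1,
                        zMin = 1, zMax = 5000))
  out <- smartClip(sil)
  expect_equal(clipValue(out), 1000)
  expect_true(all(out@frames[!out@mask] == 1000))
  # subject pixels untouched: same multiset of depths
  expect_identical(sort(out@frames[out@mask]), sort(fr[mask]))

  sil@mask[] <- FALSE
  expect_error(smartClip(sil), "empty silhouette")
})

test_that("smart clipping keeps the depth histogram unimodal where
          naive zero-clipping splits it", {
  spec <- walkerSpec()
  sil <- extractSilhouette(generateWalker(spec), walkerScene(spec),
                           walkerCamera(spec), medianFilter = FALSE)
  smart <- sil@frames
  naive <- sil@frames; naive[!sil@mask] <- 0L
  # naive clipping: two clusters separated by a huge empty gap
  expect_gt(diff(range(naive)), 2000)
  expect_equal(sum(naive > 0 & naive < 2000), 0)
  # smart clipping: all values live inside the subject's own range
  expect_lte(diff(range(smart)), diff(range(smart[sil@mask])))
})

test_that("3-D median filter equals the brute-force 27-element median", {
  set.seed(11)
  a <- array(sample.int(100, 125, replace = TRUE), dim = c(5, 5, 5))
  expect_identical(medianFilter3d(a), bruteMedian3d(a))

  const <- array(7L, dim = c(4, 4, 4))
  expect_identical(medianFilter3d(const), const)

  imp <- const; imp[2, 2, 2] <- 99L
  expect_identical(medianFilter3d(imp), const)

  expect_error(medianFilter3d(array(1L, dim = c(3, 3, 2))),
               "at least 3 frames")
})

test_that("full preprocessing keeps the subject and drops the
          treadmill on the synthetic walker", {
  spec <- walkerSpec()
  seq <- generateWalker(spec)
  sil <- extractSilhouette(seq, walkerScene(spec), walkerCamera(spec))
  tr <- walkerTruth(spec)
  b <- sil@bounds
  rows <- (b["vMin"]:b["vMax"]) + 1
  cols <- (b["uMin"]:b["uMax"]) + 1
  agg <- silhouetteMask(sil)
  subj <- tr$subject[rows, cols]
  tread <- tr$treadmill[rows, cols]
  expect_gte(mean(agg[subj]), 0.99)
  expect_equal(sum(agg[tread]), 0)
  # feet rows survive at their lowest point
  feetRow <- max(tr$legRows) - b["vMin"]
  expect_true(any(agg[feetRow, ]))
})
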