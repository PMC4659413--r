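# Silhouette extraction: bounding-box clipping, treadmill removal,
# background clipping to the subject mean, 3x3x3 median filtering.

#' Derive 2-D/depth clip limits from a 3-D bounding box
#'
#' The eight corners of the box are projected into the image with
#' [projectTo2d()]; the pixel window is the min/max of the projections
#' (floored/ceiled, clamped to the frame) and the depth limits are the
#' min/max corner depths. This is the only place 3-D geometry is needed:
#' afterwards all masking runs directly in image space.
#'
#' @param box Numeric matrix (8, 3) of corner coordinates (X, Y, Z) in mm;
#'   all Z > 0.
#' @param cam A [CameraModel-class].
#' @param frame Frame size c(H, W) in pixels used for clamping.
#' @return Named numeric: uMin, uMax, vMin, vMax (0-based pixels),
#'   zMin, zMax (mm).
#' @export
computeBounds <- function(box, cam, frame) {
  box <- as.matrix(box)
  if (nrow(box) != 8L || ncol(box) != 3L)
    stop("'box' must be an 8 x 3 matrix of corner coordinates")
  if (any(box[, 3] <= 0)) stop("all box corners must have Z > 0")
  uv <- projectTo2d(box[, 1], box[, 2], box[, 3], cam)
  H <- frame[1]; W <- frame[2]
  c(uMin = max(0, floor(min(uv[, "u"]))),
    uMax = min(W - 1, ceiling(max(uv[, "u"]))),
    vMin = max(0, floor(min(uv[, "v"]))),
    vMax = min(H - 1, ceiling(max(uv[, "v"]))),
    zMin = min(box[, 3]), zMax = max(box[, 3]))
}

#' Remove the background by bounding-box clipping
#'
#' Crops the sequence to the pixel window of the scene and marks as
#' non-subject every pixel whose depth falls outside
#' \code{[zMin, zMax]} (invalid 0-depth pixels included).
#'
#' @param seq A [DepthSequence-class].
#' @param scene A [SceneConfig-class] (or the named bounds vector from
#'   [computeBounds()]).
#' @return A [SilhouetteSequence-class] with the mask set and
#'   \code{clipValue} still \code{NA}.
#' @export
removeBackground <- function(seq, scene) {
  stopifnot(is(seq, "DepthSequence"))
  b <- if (is(scene, "SceneConfig"))
    c(uMin = scene@uMin, uMax = scene@uMax, vMin = scene@vMin,
      vMax = scene@vMax, zMin = scene@zMin, zMax = scene@zMax)
  else scene
  d <- dim(seq@frames)
  rows <- (b["vMin"]:b["vMax"]) + 1   # 0-based bounds -> 1-based rows
  cols <- (b["uMin"]:b["uMax"]) + 1
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 ||
      max(cols) > d[2])
    stop("scene bounds fall outside the frame")
  fr <- seq@frames[rows, cols, , drop = FALSE]
  mask <- fr >= b["zMin"] & fr <= b["zMax"] & fr > 0
  new("SilhouetteSequence", frames = fr, fps = seq@fps, mask = mask,
      clipValue = NA_real_, bounds = b[c("uMin", "uMax", "vMin", "vMax",
                                         "zMin", "zMax")])
}

#' Remove the treadmill by a height threshold in image space
#'
#' The treadmill lies below the subject in the world (Y axis pointing
#' down), so a pixel at row \eqn{v} (0-based, absolute) with depth
#' \eqn{d} is kept only if \eqn{v < f T_y / d + c_v} -- the image-space
#' form of the world-space constraint \eqn{Y < T_y}, valid since
#' \eqn{d > 0}. The threshold row thus depends on each pixel's own depth;
#' no reprojection into 3-D is needed.
#'
#' @param sil A [SilhouetteSequence-class] (from [removeBackground()]).
#' @param tY Treadmill height threshold in mm.
#' @param cam A [CameraModel-class].
#' @return The [SilhouetteSequence-class] with treadmill pixels removed
#'   from the mask.
#' @export
removeTreadmill <- function(sil, tY, cam) {
  stopifnot(is(sil, "SilhouetteSequence"), is(cam, "CameraModel"))
  d <- dim(sil@frames)
  vAbs <- sil@bounds["vMin"] + (seq_len(d[1]) - 1)  # 0-based abs rows
  v <- array(vAbs, dim = d)                          # recycles down rows
  keep <- sil@frames > 0 & v < cam@f * tY / sil@frames + cam@cv
  sil@mask <- sil@mask & keep
  sil
}

#' Clip non-subject pixels to the subject's mean depth
#'
#' Every non-subject pixel in every frame is set to the rounded mean of
#' all subject-pixel depths over the whole sequence. A background equal
#' to the subject mean creates no large artificial pairwise distances, so
#' the informative distances are not squeezed in the embedding, and makes
#' the image's depth histogram unimodal, which yields a well-contrasted
#' final map.
#'
#' @param sil A [SilhouetteSequence-class] with its mask set.
#' @return The [SilhouetteSequence-class] with \code{clipValue} recorded
#'   and background replaced. Subject pixels are untouched.
#' @export
smartClip <- function(sil) {
  stopifnot(is(sil, "SilhouetteSequence"))
  if (!any(sil@mask)) stop("empty silhouette: no subject pixels")
  clip <- round(mean(sil@frames[sil@mask]))
  sil@frames[!sil@mask] <- as.integer(clip)
  sil@clipValue <- clip
  sil
}

#' 3-D (3 x 3 x 3) spatio-temporal median filter
#'
#' Each voxel of the depth cube is replaced by the median of its
#' 3 x 3 x 3 spatio-temporal neighbourhood, removing aberrations on the
#' silhouette contours. Spatial borders are handled by nearest-edge
#' replication (no artificial background values); the temporal border
#' wraps circularly, consistent with the periodicity the shift-invariant
#' distance already assumes -- replicating end frames instead would
#' distort the signals at the window ends and read as spurious motion
#' asymmetry. Depths are integers, so the filter works by a vectorised
#' binary search on the value range and is exact (the 14th order
#' statistic of 27 values).
#'
#' @param x A [DepthSequence-class] (or subclass), or a 3-D integer array;
#'   at least 3 frames.
#' @return Same type as the input, filtered.
#' @export
medianFilter3d <- function(x) {
  if (is(x, "DepthSequence")) {
    x@frames <- medianFilter3d(x@frames)
    return(x)
  }
  a <- x
  d <- dim(a)
  if (length(d) != 3L) stop("need a 3-D array")
  if (d[3] < 3L) stop("need at least 3 frames for a 3-D median")
  storage.mode(a) <- "integer"
  clampIdx <- function(i, n) pmin(pmax(i, 1L), n)
  V <- prod(d)
  M <- matrix(0L, V, 27L)
  k <- 0L
  for (dt in -1:1) for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    M[, k] <- a[clampIdx(seq_len(d[1]) + dr, d[1]),
                clampIdx(seq_len(d[2]) + dc, d[2]),
                (seq_len(d[3]) - 1L + dt) %% d[3] + 1L]
  }
  lo <- M[, 1L]; hi <- M[, 1L]
  for (k in 2:27) { lo <- pmin(lo, M[, k]); hi <- pmax(hi, M[, k]) }
  while (any(open <- lo < hi)) {
    mid <- (lo + hi) %/% 2L
    cnt <- rowSums(M[open, , drop = FALSE] <= mid[open])
    below <- cnt >= 14L            # median is <= mid
    idx <- which(open)
    hi[idx[below]] <- mid[idx[below]]
    lo[idx[!below]] <- mid[idx[!below]] + 1L
  }
  array(lo, dim = d)
}

#' Extract the subject silhouette from a raw depth sequence
#'
#' The full pre-processing stage: select the frame window, clip to the
#' scene bounding box, remove the treadmill, clip the background to the
#' subject mean depth and median-filter the cube (in that order).
#'
#' @param seq A [DepthSequence-class].
#' @param scene A [SceneConfig-class].
#' @param cam A [CameraModel-class].
#' @param medianFilter Apply the 3 x 3 x 3 median filter (default TRUE).
#' @return A [SilhouetteSequence-class].
#' @examples
#' spec <- walkerSpec()
#' sil <- extractSilhouette(generateWalker(spec), walkerScene(spec),
#'                          walkerCamera(spec))
#' sil
#' @export
extractSilhouette <- function(seq, scene, cam, medianFilter = TRUE) {
  stopifnot(is(seq, "DepthSequence"), is(scene, "SceneConfig"))
  n <- nFrames(seq)
  first <- scene@offset + 1L
  last <- if (is.na(scene@n)) n else scene@offset + scene@n
  if (last > n)
    stop(sprintf("scene asks for frames %d..%d but only %d available",
                 first, last, n))
  seq@frames <- seq@frames[, , first:last, drop = FALSE]
  sil <- removeBackground(seq, scene)
  if (!is.na(scene@tY)) sil <- removeTreadmill(sil, scene@tY, cam)
  sil <- smartClip(sil)
  if (medianFilter) sil <- medianFilter3d(sil)
  sil
}
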