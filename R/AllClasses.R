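#' @import methods
NULL

# ---------------------------------------------------------------------------
# CameraModel
# ---------------------------------------------------------------------------

#' Pinhole camera intrinsics of the depth sensor
#'
#' Holds the focal length and principal point of the depth sensor, modelled
#' as a pinhole camera with intrinsic matrix
#' \eqn{K = [[f, 0, c_u], [0, f, c_v], [0, 0, 1]]}.
#' Pixel coordinates are 0-based, \code{u} along columns and \code{v} along
#' rows, origin at the top-left corner, with the Y axis of the world frame
#' pointing down (towards the floor).
#'
#' @slot f numeric(1). Focal length in pixels; must be positive.
#' @slot cu,cv numeric(1). Principal point in pixels.
#'
#' @seealso [CameraModel()], [projectTo3d()], [projectTo2d()]
#' @export
setClass("CameraModel",
  slots = c(f = "numeric", cu = "numeric", cv = "numeric"))

setValidity("CameraModel", function(object) {
  if (length(object@f) != 1L || !is.finite(object@f) || object@f <= 0)
    return("'f' must be a single positive finite number")
  if (length(object@cu) != 1L || length(object@cv) != 1L ||
      !is.finite(object@cu) || !is.finite(object@cv))
    return("'cu' and 'cv' must be single finite numbers")
  TRUE
})

#' Construct a CameraModel
#'
#' The defaults are the manufacturer intrinsics of the Kinect v1 depth
#' sensor used throughout the package documentation
#' (\eqn{f = 575.82}, \eqn{c_u = c_v = 240} for a 640x480 image).
#' The defaults are kept verbatim from the sensor data sheet; supply your
#' own calibration when the sensor or resolution differs.
#'
#' @param f Focal length in pixels.
#' @param cu,cv Principal point in pixels (0-based image coordinates).
#' @return A [CameraModel-class] object.
#' @examples
#' cam <- CameraModel()
#' projectTo3d(240, 240, 1000, cam)   # principal point -> optical axis
#' @export
CameraModel <- function(f = 575.82, cu = 240, cv = 240) {
  new("CameraModel", f = as.numeric(f), cu = as.numeric(cu),
      cv = as.numeric(cv))
}

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: f = %g px, principal point = (%g, %g) px\n",
              object@f, object@cu, object@cv))
})

# ---------------------------------------------------------------------------
# SceneConfig
# ---------------------------------------------------------------------------

#' Scene geometry: bounding box limits and treadmill threshold
#'
#' Describes where the subject is in the image and in depth: the 2-D/depth
#' clip window derived from an enclosing 3-D bounding box, the treadmill
#' height threshold, and which frames of the recording to use.
#'
#' @slot uMin,uMax,vMin,vMax numeric(1). Pixel clip window (0-based,
#'   inclusive), usually obtained with [computeBounds()].
#' @slot zMin,zMax numeric(1). Depth clip limits in mm.
#' @slot tY numeric(1). Treadmill height threshold in mm on the world Y
#'   axis (Y points down); pixels whose world Y is at or below the
#'   treadmill top are discarded by [removeTreadmill()]. \code{NA} disables
#'   treadmill removal.
#' @slot offset integer(1). Frames skipped at the start of the recording
#'   (acclimatisation to the treadmill).
#' @slot n integer(1). Number of frames used after the offset; \code{NA}
#'   means all remaining frames.
#'
#' @seealso [SceneConfig()], [computeBounds()], [extractSilhouette()]
#' @export
setClass("SceneConfig",
  slots = c(uMin = "numeric", uMax = "numeric",
            vMin = "numeric", vMax = "numeric",
            zMin = "numeric", zMax = "numeric",
            tY = "numeric", offset = "integer", n = "integer"))

setValidity("SceneConfig", function(object) {
  one <- function(x) length(x) == 1L
  if (!all(vapply(list(object@uMin, object@uMax, object@vMin, object@vMax,
                       object@zMin, object@zMax, object@tY), one, TRUE)))
    return("all scalar slots must have length 1")
  if (object@uMin > object@uMax) return("uMin must be <= uMax")
  if (object@vMin > object@vMax) return("vMin must be <= vMax")
  if (object@zMin > object@zMax) return("zMin must be <= zMax")
  if (!is.na(object@n) && object@n < 2L) return("n must be >= 2")
  if (object@offset < 0L) return("offset must be >= 0")
  TRUE
})

#' Construct a SceneConfig
#'
#' @param uMin,uMax,vMin,vMax Pixel clip window (0-based, inclusive).
#' @param zMin,zMax Depth clip limits in mm.
#' @param tY Treadmill height threshold in mm (Y down); \code{NA} disables
#'   treadmill removal.
#' @param offset Frames skipped at sequence start.
#' @param n Number of frames used (\code{NA} = all remaining).
#' @return A [SceneConfig-class] object.
#' @export
SceneConfig <- function(uMin, uMax, vMin, vMax, zMin, zMax,
                        tY = NA_real_, offset = 0L, n = NA_integer_) {
  new("SceneConfig",
      uMin = as.numeric(uMin), uMax = as.numeric(uMax),
      vMin = as.numeric(vMin), vMax = as.numeric(vMax),
      zMin = as.numeric(zMin), zMax = as.numeric(zMax),
      tY = as.numeric(tY), offset = as.integer(offset), n = as.integer(n))
}

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig\n")
  cat(sprintf("  u: [%g, %g]  v: [%g, %g]  Z: [%g, %g] mm\n",
              object@uMin, object@uMax, object@vMin, object@vMax,
              object@zMin, object@zMax))
  cat(sprintf("  treadmill T_y: %s mm, frame offset: %d, frames used: %s\n",
              format(object@tY), object@offset,
              ifelse(is.na(object@n), "all", format(object@n))))
})

# ---------------------------------------------------------------------------
# DepthSequence
# ---------------------------------------------------------------------------

#' A depth-video: stack of single-channel depth frames
#'
#' The central data container. Frames are stored as an integer array of
#' dimension \code{(H, W, N)} (rows, columns, frames) with depth in
#' millimetres; 0 encodes an invalid measurement (no sensor return) and is
#' excluded from subject statistics. The time series of one pixel across
#' the N frames is its \emph{depth signal} -- the N-dimensional object that
#' the embedding step maps to a colour.
#'
#' @slot frames integer array (H, W, N), depth in mm, values >= 0.
#' @slot fps numeric(1). Frame rate in frames per second.
#'
#' @seealso [DepthSequence()], [readDepthSequence()], [generateWalker()]
#' @export
setClass("DepthSequence",
  slots = c(frames = "array", fps = "numeric"))

setValidity("DepthSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("'frames' must be a 3-D array (H, W, N)")
  if (any(d < 1L)) return("all of H, W, N must be >= 1")
  if (!is.numeric(object@frames)) return("'frames' must be numeric")
  if (any(object@frames < 0)) return("depth values must be >= 0")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("'fps' must be a single positive number")
  TRUE
})

#' Construct a DepthSequence
#'
#' @param frames Integer array of dimension (H, W, N): depth in mm.
#' @param fps Frame rate (frames per second), default 30 (Kinect).
#' @return A [DepthSequence-class] object.
#' @export
DepthSequence <- function(frames, fps = 30) {
  storage.mode(frames) <- "integer"
  new("DepthSequence", frames = frames, fps = as.numeric(fps))
}

#' @rdname DepthSequence-class
#' @param x A DepthSequence (or subclass).
#' @export
setGeneric("depthFrames", function(x) standardGeneric("depthFrames"))
#' @rdname DepthSequence-class
#' @export
setMethod("depthFrames", "DepthSequence", function(x) x@frames)

#' @rdname DepthSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname DepthSequence-class
#' @export
setMethod("nFrames", "DepthSequence", function(x) dim(x@frames)[3L])

#' @rdname DepthSequence-class
#' @export
setGeneric("frameSize", function(x) standardGeneric("frameSize"))
#' @rdname DepthSequence-class
#' @export
setMethod("frameSize", "DepthSequence",
          function(x) dim(x@frames)[1:2])

#' @rdname DepthSequence-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname DepthSequence-class
#' @export
setMethod("frameRate", "DepthSequence", function(x) x@fps)

setMethod("show", "DepthSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("%s: %d frames of %d x %d px @ %g fps, depth %d..%d mm\n",
              class(object), d[3], d[1], d[2], object@fps,
              min(object@frames), max(object@frames)))
})

# ---------------------------------------------------------------------------
# SilhouetteSequence
# ---------------------------------------------------------------------------

#' A cropped depth sequence with a subject mask
#'
#' Result of the silhouette-extraction stage: frames cropped to the scene
#' clip window, a per-frame logical subject mask, and (after
#' [smartClip()]) every non-subject pixel replaced by the rounded mean
#' depth of all subject pixels in the whole sequence. The absolute pixel
#' offsets of the crop are kept so image-space geometry (e.g. the
#' treadmill row threshold) can still be evaluated.
#'
#' @slot mask logical array, same dimension as \code{frames}; TRUE marks
#'   subject pixels.
#' @slot clipValue numeric(1). Depth (mm) assigned to non-subject pixels;
#'   \code{NA} until [smartClip()] has run.
#' @slot bounds named numeric(6): uMin, uMax, vMin, vMax (0-based absolute
#'   pixel window of the crop), zMin, zMax.
#'
#' @seealso [extractSilhouette()], [smartClip()]
#' @export
setClass("SilhouetteSequence", contains = "DepthSequence",
  slots = c(mask = "array", clipValue = "numeric", bounds = "numeric"))

setValidity("SilhouetteSequence", function(object) {
  if (!identical(dim(object@mask), dim(object@frames)))
    return("'mask' must have the same dimension as 'frames'")
  if (!is.logical(object@mask)) return("'mask' must be logical")
  if (length(object@clipValue) != 1L)
    return("'clipValue' must have length 1")
  need <- c("uMin", "uMax", "vMin", "vMax", "zMin", "zMax")
  if (!all(need %in% names(object@bounds)))
    return("'bounds' must be named with uMin..zMax")
  # Right after smartClip() every non-subject pixel equals the clip
  # value; the subsequent 3-D median filter may legitimately rework
  # pixels near the silhouette contour, so equality is asserted by the
  # clipping step itself, not here.
  TRUE
})

#' @rdname SilhouetteSequence-class
#' @param x A SilhouetteSequence.
#' @export
setGeneric("subjectMask", function(x) standardGeneric("subjectMask"))
#' @rdname SilhouetteSequence-class
#' @export
setMethod("subjectMask", "SilhouetteSequence", function(x) x@mask)

#' @rdname SilhouetteSequence-class
#' @export
setGeneric("clipValue", function(x) standardGeneric("clipValue"))
#' @rdname SilhouetteSequence-class
#' @export
setMethod("clipValue", "SilhouetteSequence", function(x) x@clipValue)

#' Time-aggregated silhouette mask
#'
#' A pixel belongs to the aggregated silhouette if it is a subject pixel
#' in at least one frame. Used for longitudinal-axis estimation and for
#' restricting the ASI curve to body rows.
#'
#' @param x A [SilhouetteSequence-class].
#' @return Logical matrix (H, W).
#' @export
setGeneric("silhouetteMask", function(x) standardGeneric("silhouetteMask"))
#' @rdname silhouetteMask
#' @export
setMethod("silhouetteMask", "SilhouetteSequence", function(x) {
  d <- dim(x@mask)
  m <- x@mask
  dim(m) <- c(d[1] * d[2], d[3])
  out <- matrix(rowSums(m) > 0, d[1], d[2])
  out
})

setMethod("show", "SilhouetteSequence", function(object) {
  callNextMethod()
  cat(sprintf("  subject pixels: %.1f%% of voxels, clip value: %s mm\n",
              100 * mean(object@mask), format(object@clipValue)))
})

# ---------------------------------------------------------------------------
# ShiftDistanceSpec
# ---------------------------------------------------------------------------

#' Specification of a shift-invariant depth-signal distance
#'
#' @slot kind character(1). One of \code{"L2"}, \code{"L1"}, \code{"Linf"}
#'   (norms minimised over circular time shifts), \code{"Lmod"} (L2 between
#'   Fourier amplitude spectra), \code{"Lrad"} (L2 between amplitude
#'   histograms on shared bin edges), \code{"Lmoy"} (L1 between means).
#' @slot tauMax integer(1). Largest shift tried, in frames (about one gait
#'   cycle); default 66.
#' @slot tauStep integer(1). Shift grid step in frames; default 6
#'   (about 0.2 s at 30 fps).
#' @slot nBins integer(1). Histogram bins for \code{"Lrad"}.
#'
#' @seealso [shiftDistance()]
#' @export
setClass("ShiftDistanceSpec",
  slots = c(kind = "character", tauMax = "integer", tauStep = "integer",
            nBins = "integer"))

setValidity("ShiftDistanceSpec", function(object) {
  kinds <- c("L2", "L1", "Linf", "Lmod", "Lrad", "Lmoy")
  if (length(object@kind) != 1L || !(object@kind %in% kinds))
    return(paste("kind must be one of", paste(kinds, collapse = ", ")))
  if (object@tauStep < 1L) return("tauStep must be >= 1")
  if (object@tauMax < 0L) return("tauMax must be >= 0")
  if (object@nBins < 2L) return("nBins must be >= 2")
  TRUE
})

#' Construct a ShiftDistanceSpec
#'
#' Defaults follow the method's operating point: shifts
#' \eqn{\tau \in \{0, 6, 12, \dots, 66\}} frames.
#'
#' @param kind Distance kind, see [ShiftDistanceSpec-class].
#' @param tauMax Largest shift (frames).
#' @param tauStep Shift grid step (frames).
#' @param nBins Bins for the amplitude-histogram distance.
#' @return A [ShiftDistanceSpec-class] object.
#' @export
shiftDistanceSpec <- function(kind = "L2", tauMax = 66L, tauStep = 6L,
                              nBins = 16L) {
  new("ShiftDistanceSpec", kind = as.character(kind),
      tauMax = as.integer(tauMax), tauStep = as.integer(tauStep),
      nBins = as.integer(nBins))
}

setMethod("show", "ShiftDistanceSpec", function(object) {
  cat(sprintf("ShiftDistanceSpec: %s, tau in {0, %d, ..., %d} frames\n",
              object@kind, object@tauStep, object@tauMax))
})

# ---------------------------------------------------------------------------
# DistanceGraph
# ---------------------------------------------------------------------------

#' Sparse pixel-pair graph carrying shift-invariant distances
#'
#' Each pixel of the (cropped) silhouette image is linked to its four
#' nearest neighbours plus \code{nCnx} approximately equally spaced pixels
#' inside a centred \code{nS} x \code{nS} window. The graph carries the
#' raw distances \eqn{\beta_{s,t}} between the incident depth signals and,
#' after scale estimation, \eqn{\beta^{scaled}_{s,t} = k\beta_{s,t}}.
#'
#' Pixel indices are 1-based column-major linear indices into the
#' \code{(H, W)} image.
#'
#' @slot edges integer matrix (E, 2); each row one undirected edge,
#'   first index < second index, no duplicates.
#' @slot beta numeric(E). Raw distances, >= 0; empty until
#'   [computeDistances()].
#' @slot betaScaled numeric(E). Scaled distances \eqn{k\beta}; empty until
#'   [estimateScale()].
#' @slot k numeric(1). Stretch factor (NA until estimated).
#' @slot dim integer(2). Image height and width.
#' @slot nS,nCnx integer(1). Window size and number of long-range links.
#'
#' @seealso [buildGraph()], [computeDistances()], [estimateScale()]
#' @export
setClass("DistanceGraph",
  slots = c(edges = "matrix", beta = "numeric", betaScaled = "numeric",
            k = "numeric", dim = "integer", nS = "integer",
            nCnx = "integer"))

setValidity("DistanceGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("'edges' must have two columns")
  if (nrow(e) && any(e[, 1] >= e[, 2]))
    return("edges must be canonical: first index < second (no self-edges)")
  npix <- prod(object@dim)
  if (nrow(e) && (min(e) < 1L || max(e) > npix))
    return("edge indices out of range")
  if (length(object@beta) && length(object@beta) != nrow(e))
    return("'beta' length must match the number of edges")
  if (length(object@beta) && any(object@beta < 0))
    return("'beta' must be non-negative")
  if (length(object@betaScaled) &&
      length(object@betaScaled) != nrow(e))
    return("'betaScaled' length must match the number of edges")
  TRUE
})

#' @rdname DistanceGraph-class
#' @param x A DistanceGraph.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname DistanceGraph-class
#' @export
setMethod("graphEdges", "DistanceGraph", function(x) x@edges)

#' @rdname DistanceGraph-class
#' @export
setGeneric("edgeBeta", function(x) standardGeneric("edgeBeta"))
#' @rdname DistanceGraph-class
#' @export
setMethod("edgeBeta", "DistanceGraph", function(x) x@beta)

#' @rdname DistanceGraph-class
#' @export
setGeneric("edgeBetaScaled", function(x) standardGeneric("edgeBetaScaled"))
#' @rdname DistanceGraph-class
#' @export
setMethod("edgeBetaScaled", "DistanceGraph", function(x) x@betaScaled)

#' @rdname DistanceGraph-class
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))
#' @rdname DistanceGraph-class
#' @export
setMethod("scaleFactor", "DistanceGraph", function(x) x@k)

setMethod("show", "DistanceGraph", function(object) {
  cat(sprintf(
    "DistanceGraph: %d x %d image, %d edges (N_s = %d, N_cnx = %d)\n",
    object@dim[1], object@dim[2], nrow(object@edges), object@nS,
    object@nCnx))
  if (length(object@beta))
    cat(sprintf("  beta: [%.3g, %.3g]%s\n", min(object@beta),
                max(object@beta),
                if (!is.na(object@k)) sprintf(", k = %.3f", object@k)
                else ""))
})

# ---------------------------------------------------------------------------
# AsymmetryMap
# ---------------------------------------------------------------------------

#' Per-pixel three-channel embedding: the asymmetry map
#'
#' The output of the mapping stage: every pixel carries a 3-vector
#' \eqn{u = (L, A, B)} in (stretched) CIELAB space such that the Euclidean
#' colour difference between two pixels approximates the scaled
#' shift-invariant distance between their depth signals. Mirrored body
#' parts with symmetric motion therefore share a colour; asymmetric parts
#' differ perceptually in proportion to the asymmetry magnitude.
#'
#' @slot values numeric array (H, W, 3): the L, A, B planes.
#' @slot provenance list. Scale k, eta, q, energy trace, correlation, ...
#'
#' @seealso [fastMap()], [icmRefine()], [stretchLab()], [labToRgb()]
#' @export
setClass("AsymmetryMap",
  slots = c(values = "array", provenance = "list"))

setValidity("AsymmetryMap", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[3] != 3L)
    return("'values' must be an (H, W, 3) array")
  if (!all(is.finite(object@values)))
    return("'values' must be finite")
  TRUE
})

#' @rdname AsymmetryMap-class
#' @param x An AsymmetryMap.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname AsymmetryMap-class
#' @export
setMethod("mapValues", "AsymmetryMap", function(x) x@values)

#' @rdname AsymmetryMap-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname AsymmetryMap-class
#' @export
setMethod("provenance", "AsymmetryMap", function(x) x@provenance)

setMethod("show", "AsymmetryMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("AsymmetryMap: %d x %d px, channels L in [%.1f, %.1f], ",
              d[1], d[2], min(object@values[, , 1]),
              max(object@values[, , 1])))
  cat(sprintf("A in [%.1f, %.1f], B in [%.1f, %.1f]\n",
              min(object@values[, , 2]), max(object@values[, , 2]),
              min(object@values[, , 3]), max(object@values[, , 3])))
  pv <- object@provenance
  if (!is.null(pv$k))
    cat(sprintf("  k = %.3f%s%s\n", pv$k,
                if (!is.null(pv$correlation))
                  sprintf(", correlation rho = %.3f", pv$correlation)
                else "",
                if (!is.null(pv$energyTrace))
                  sprintf(", %d ICM sweep(s)",
                          length(pv$energyTrace) - 1L)
                else ""))
})

# ---------------------------------------------------------------------------
# AsiResult
# ---------------------------------------------------------------------------

#' Longitudinal axis, ASI curve and ASI index
#'
#' The ASI curve holds, for each silhouette row (top of the head
#' downwards), the largest perceptual colour difference between pixels
#' mirrored about the estimated longitudinal body axis. Its mean is the
#' scalar asymmetry index (ASI). The index is a relative measure: it
#' compares conditions within a subject, not subjects against an absolute
#' threshold.
#'
#' @slot axis integer(1). Estimated axis column (1-based, in the cropped
#'   image).
#' @slot curve numeric. One non-negative value per evaluated row.
#' @slot rows integer. Row indices the curve entries belong to.
#' @slot index numeric(1). Mean of the curve.
#' @slot m integer(1). Mirror half-width in pixels.
#'
#' @seealso [computeAsi()], [asiCurve()], [asiIndex()]
#' @export
setClass("AsiResult",
  slots = c(axis = "integer", curve = "numeric", rows = "integer",
            index = "numeric", m = "integer"))

setValidity("AsiResult", function(object) {
  if (length(object@curve) != length(object@rows))
    return("'curve' and 'rows' must have the same length")
  if (length(object@curve) && any(object@curve < 0))
    return("curve entries must be >= 0")
  if (length(object@curve) &&
      abs(object@index - mean(object@curve)) > 1e-9)
    return("'index' must be the mean of 'curve'")
  TRUE
})

#' @rdname AsiResult-class
#' @param x An AsiResult.
#' @export
setGeneric("asiAxis", function(x) standardGeneric("asiAxis"))
#' @rdname AsiResult-class
#' @export
setMethod("asiAxis", "AsiResult", function(x) x@axis)

setMethod("show", "AsiResult", function(object) {
  cat(sprintf(
    "AsiResult: axis column %d, %d rows, ASI index = %.2f\n",
    object@axis, length(object@curve), object@index))
})
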