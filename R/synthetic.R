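# Synthetic articulated walker: a periodic treadmill-walking silhouette
# with exactly known symmetry properties. Limbs are axis-aligned
# rectangles whose depth oscillates sinusoidally; the method consumes
# per-pixel depth signals, not anatomy, so this is sufficient to exercise
# every stage of the pipeline with a controllable ground truth.

#' Specification of a synthetic walking sequence
#'
#' Describes frame geometry, gait dynamics and the simulated leg-length
#' discrepancy (LLD) of an articulated walker rendered by
#' [generateWalker()]. Left and right legs (and arms) oscillate in depth
#' with period \code{period} frames and exactly half a period of phase
#' offset, the premise of coronal-plane gait symmetry. The right-side
#' waveform is the left-side phase table evaluated at \eqn{t + P/2}, so
#' for \code{lldOffset = 0} and \code{noiseSd = 0} the frame mirrored
#' about the body midline equals the frame time-shifted by half a period,
#' exactly (integer mm).
#'
#' @slot width,height integer(1). Frame size in pixels (W, H).
#' @slot nFrames integer(1). Number of frames N; a whole number of gait
#'   cycles keeps circular time shifts exact.
#' @slot period integer(1). Gait period P in frames; even, >= 4.
#' @slot fps numeric(1). Frame rate.
#' @slot torsoDepth numeric(1). Depth of the torso plane in mm.
#' @slot limbAmplitude numeric(1). Peak leg depth oscillation in mm
#'   (arms use half of it).
#' @slot backgroundDepth numeric(1). Depth of the far background in mm.
#' @slot lldOffset numeric(1). Simulated LLD: constant depth perturbation
#'   (mm) added to one leg's trajectory (a 5 cm sole under one foot
#'   corresponds to 50 mm).
#' @slot lldSide character(1). "none", "left" or "right".
#' @slot lldLengthPx integer(1). Optional leg-length change in pixels on
#'   the affected side (geometry component of an LLD).
#' @slot noiseSd numeric(1). Additive Gaussian depth noise sigma in mm,
#'   rounded to integer mm.
#' @slot seed integer(1). RNG seed for the noise; generation is
#'   deterministic given the spec.
#'
#' @seealso [walkerSpec()], [generateWalker()], [generateCohort()]
#' @export
setClass("WalkerSpec",
  slots = c(width = "integer", height = "integer", nFrames = "integer",
            period = "integer", fps = "numeric",
            torsoDepth = "numeric", limbAmplitude = "numeric",
            backgroundDepth = "numeric",
            lldOffset = "numeric", lldSide = "character",
            lldLengthPx = "integer", noiseSd = "numeric",
            seed = "integer"))

setValidity("WalkerSpec", function(object) {
  if (object@period < 4L) return("period must be >= 4 frames")
  if (object@period %% 2L != 0L)
    return("period must be even (half-period phase offsets are exact)")
  if (object@nFrames < object@period)
    return("nFrames must be >= period")
  if (object@limbAmplitude < 0) return("limbAmplitude must be >= 0")
  if (object@lldOffset < 0) return("lldOffset must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!(object@lldSide %in% c("none", "left", "right")))
    return("lldSide must be 'none', 'left' or 'right'")
  if (object@width < 16L || object@height < 16L)
    return("frame must be at least 16 x 16 px")
  if (object@torsoDepth + object@limbAmplitude + object@lldOffset >=
      object@backgroundDepth)
    return("background must be farther than any subject depth")
  TRUE
})

#' Construct a WalkerSpec
#'
#' Defaults describe the reduced-scale study configuration: a 48 x 64 px
#' frame, 60 frames (2 s) at 30 fps, gait period 20 frames (a 0.67 s
#' cycle -- a brisk treadmill walk, chosen so the shifted-distance
#' search grid resolves the half period exactly within the window; see
#' the methods vignette), torso at 2500 mm (middle of the depth
#' sensor's working range), 100 mm leg depth oscillation and a far
#' background at 4000 mm. For a full-scale sequence use
#' \code{walkerSpec(width = 640, height = 480, nFrames = 300)}.
#'
#' @param width,height,nFrames,period,fps,torsoDepth,limbAmplitude,
#'   backgroundDepth,lldOffset,lldSide,lldLengthPx,noiseSd,seed
#'   See [WalkerSpec-class].
#' @return A [WalkerSpec-class] object.
#' @examples
#' seq <- generateWalker(walkerSpec(noiseSd = 5, seed = 7))
#' seq
#' @export
walkerSpec <- function(width = 48L, height = 64L, nFrames = 60L,
                       period = 20L, fps = 30,
                       torsoDepth = 2500, limbAmplitude = 100,
                       backgroundDepth = 4000,
                       lldOffset = 0, lldSide = "none",
                       lldLengthPx = 0L, noiseSd = 0, seed = 1L) {
  new("WalkerSpec", width = as.integer(width),
      height = as.integer(height), nFrames = as.integer(nFrames),
      period = as.integer(period), fps = as.numeric(fps),
      torsoDepth = as.numeric(torsoDepth),
      limbAmplitude = as.numeric(limbAmplitude),
      backgroundDepth = as.numeric(backgroundDepth),
      lldOffset = as.numeric(lldOffset),
      lldSide = as.character(lldSide),
      lldLengthPx = as.integer(lldLengthPx),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

setMethod("show", "WalkerSpec", function(object) {
  cat(sprintf(
    "WalkerSpec: %d x %d px, %d frames @ %g fps, period %d frames\n",
    object@width, object@height, object@nFrames, object@fps,
    object@period))
  cat(sprintf("  torso %g mm, limb amplitude %g mm, LLD %g mm (%s)%s\n",
              object@torsoDepth, object@limbAmplitude, object@lldOffset,
              object@lldSide,
              if (object@noiseSd > 0)
                sprintf(", noise sd %g mm", object@noiseSd) else ""))
})

# Body-part layout in 1-based pixel coordinates, proportional to the
# frame so the walker scales from 48 x 64 test frames to 640 x 480.
.walkerLayout <- function(spec) {
  H <- spec@height; W <- spec@width
  cAxis <- W %/% 2L                      # midline column (1-based)
  rows <- function(a, b) seq(max(2L, round(a * H)), round(b * H))
  headHw  <- max(1L, round(0.05 * W))
  torsoHw <- max(2L, round(0.11 * W))
  armW    <- max(1L, round(0.04 * W))
  legW    <- max(2L, round(0.06 * W))
  legGap  <- max(1L, round(0.03 * W))
  leftCols <- function(inner, wdt) seq(cAxis - inner - wdt, cAxis - inner - 1L)
  mirrorCols <- function(cols) sort(2L * cAxis - cols)
  legL <- leftCols(legGap, legW)
  armL <- leftCols(torsoHw + 1L, armW)
  list(cAxis = cAxis,
       headRows = rows(0.06, 0.14),
       headCols = seq(cAxis - headHw, cAxis + headHw),
       torsoRows = rows(0.15, 0.45),
       torsoCols = seq(cAxis - torsoHw, cAxis + torsoHw),
       armRows = rows(0.17, 0.42),
       armColsL = armL, armColsR = mirrorCols(armL),
       legRows = rows(0.47, 0.82),
       legColsL = legL, legColsR = mirrorCols(legL),
       treadRows = seq(round(0.90 * H), H))
}

#' Generate a synthetic walking depth sequence
#'
#' Renders the articulated walker described by a [WalkerSpec-class]:
#' constant far background, a treadmill slab across the bottom rows,
#' a static head/torso, and arm/leg rectangles whose depth oscillates
#' sinusoidally with half-period phase opposition between sides. With
#' \code{lldOffset > 0} the chosen leg's depth trajectory is offset (and
#' optionally its length changed), breaking the mirror/half-period
#' symmetry on that side only.
#'
#' @param spec A [WalkerSpec-class].
#' @return A [DepthSequence-class] of dimension (height, width, nFrames).
#' @export
generateWalker <- function(spec) {
  stopifnot(is(spec, "WalkerSpec"))
  validObject(spec)
  H <- spec@height; W <- spec@width; N <- spec@nFrames; P <- spec@period
  lay <- .walkerLayout(spec)
  D0 <- spec@torsoDepth

  # integer waveforms per gait phase; the right side samples the same
  # table at phase + P/2, making the mirror identity exact in integer mm
  ph <- 0:(P - 1L)
  legWave <- as.integer(round(D0 + spec@limbAmplitude *
                                sin(2 * pi * ph / P)))
  armWave <- as.integer(round(D0 + 0.5 * spec@limbAmplitude *
                                sin(2 * pi * ph / P)))
  off <- as.integer(round(spec@lldOffset))
  dL <- if (spec@lldSide == "left") off else 0L
  dR <- if (spec@lldSide == "right") off else 0L
  legRowsL <- legRowsR <- lay$legRows
  if (spec@lldLengthPx != 0L) {
    ext <- function(r) seq(min(r), min(max(r) + spec@lldLengthPx, H))
    if (spec@lldSide == "left") legRowsL <- ext(legRowsL)
    if (spec@lldSide == "right") legRowsR <- ext(legRowsR)
  }

  frames <- array(as.integer(spec@backgroundDepth), dim = c(H, W, N))
  static <- matrix(FALSE, H, W)
  static[lay$headRows, lay$headCols] <- TRUE
  static[lay$torsoRows, lay$torsoCols] <- TRUE
  tread <- matrix(FALSE, H, W)
  tread[lay$treadRows, ] <- TRUE
  for (t in seq_len(N)) {
    pL <- (t - 1L) %% P + 1L            # left-side phase
    pR <- (t - 1L + P %/% 2L) %% P + 1L # right side: half a period later
    f <- frames[, , t]
    f[static] <- as.integer(D0)
    f[tread] <- as.integer(D0)
    f[lay$armRows, lay$armColsL] <- armWave[pL]
    f[lay$armRows, lay$armColsR] <- armWave[pR]
    f[legRowsL, lay$legColsL] <- legWave[pL] + dL
    f[legRowsR, lay$legColsR] <- legWave[pR] + dR
    frames[, , t] <- f
  }

  if (spec@noiseSd > 0) {
    runWithSeed(spec@seed, {
      noise <- as.integer(round(stats::rnorm(length(frames),
                                             sd = spec@noiseSd)))
      frames <- frames + noise
    })
    frames[frames < 0L] <- 0L
    frames[frames > 65535L] <- 65535L
  }
  DepthSequence(frames, fps = spec@fps)
}

#' Ground truth of a synthetic walker
#'
#' Pixel-level labels the generator guarantees, for validating the
#' silhouette-extraction stage: the subject mask (static -- limbs move in
#' depth only), the treadmill slab, the midline column and the leg
#' rectangles.
#'
#' @param spec A [WalkerSpec-class].
#' @return A list with elements \code{subject}, \code{treadmill}
#'   (logical H x W matrices), \code{axisCol}, \code{legColsL},
#'   \code{legColsR}, \code{legRows}, \code{layout}.
#' @export
walkerTruth <- function(spec) {
  lay <- .walkerLayout(spec)
  H <- spec@height; W <- spec@width
  subject <- matrix(FALSE, H, W)
  subject[lay$headRows, lay$headCols] <- TRUE
  subject[lay$torsoRows, lay$torsoCols] <- TRUE
  subject[lay$armRows, lay$armColsL] <- TRUE
  subject[lay$armRows, lay$armColsR] <- TRUE
  subject[lay$legRows, lay$legColsL] <- TRUE
  subject[lay$legRows, lay$legColsR] <- TRUE
  tread <- matrix(FALSE, H, W)
  tread[lay$treadRows, ] <- TRUE
  list(subject = subject, treadmill = tread, axisCol = lay$cAxis,
       legColsL = lay$legColsL, legColsR = lay$legColsR,
       legRows = lay$legRows, layout = lay)
}

#' Camera model matched to a synthetic walker frame
#'
#' Focal length scaled from the 640-px-wide sensor reference, principal
#' point at the frame centre.
#'
#' @param spec A [WalkerSpec-class].
#' @return A [CameraModel-class].
#' @export
walkerCamera <- function(spec) {
  CameraModel(f = 575.82 * spec@width / 640,
              cu = (spec@width - 1) / 2, cv = (spec@height - 1) / 2)
}

#' Scene configuration matched to a synthetic walker
#'
#' Builds the 3-D bounding box enclosing the walker (excluding treadmill
#' and background), projects its eight corners with [computeBounds()] and
#' places the treadmill height threshold between the lowest leg row and
#' the treadmill slab.
#'
#' @param spec A [WalkerSpec-class].
#' @param cam A [CameraModel-class]; defaults to [walkerCamera()].
#' @return A [SceneConfig-class].
#' @export
walkerScene <- function(spec, cam = walkerCamera(spec)) {
  lay <- .walkerLayout(spec)
  D0 <- spec@torsoDepth
  margin <- 4 * spec@noiseSd + 10
  zMin <- D0 - spec@limbAmplitude - margin
  zMax <- D0 + spec@limbAmplitude + spec@lldOffset + margin
  # pixel extent of the subject (0-based, one-pixel margin)
  u0 <- min(lay$armColsL) - 2L; u1 <- max(lay$armColsR)
  v0 <- min(lay$headRows) - 2L
  v1 <- max(lay$legRows) + spec@lldLengthPx
  # world-space corners chosen so that reprojection reproduces u0..v1
  corn <- expand.grid(u = c(u0, u1), v = c(v0, v1), Z = c(zMin, zMax))
  box <- cbind(X = corn$Z * (corn$u - cam@cu) / cam@f,
               Y = corn$Z * (corn$v - cam@cv) / cam@f,
               Z = corn$Z)
  b <- computeBounds(box, cam, frame = c(spec@height, spec@width))
  # treadmill threshold: midway between last leg row and slab top, at D0
  vMid <- (max(lay$legRows) + spec@lldLengthPx +
             min(lay$treadRows)) / 2 - 1   # 0-based
  tY <- (vMid - cam@cv) * D0 / cam@f
  SceneConfig(b["uMin"], b["uMax"], b["vMin"], b["vMax"],
              zMin, zMax, tY = tY, offset = 0L, n = spec@nFrames)
}

#' Generate a cohort of synthetic subjects
#'
#' For each subject, draws individual geometry/dynamics parameters
#' (jittered around \code{base}) and renders three sequences sharing
#' them: a normal walk, a left-LLD walk and a right-LLD walk -- the
#' within-subject A/B/C design of a sole-under-one-foot experiment.
#'
#' @param nSubjects Number of subjects, >= 1.
#' @param base A [WalkerSpec-class] giving the common configuration
#'   (its \code{lldOffset} is the sole height applied in the LLD arms;
#'   default 50 mm, a 5 cm sole).
#' @param jitter Named list of \code{c(min, max)} ranges drawn uniformly
#'   per subject for numeric spec fields (default: torso depth and limb
#'   amplitude).
#' @param seed Cohort seed; everything is reproducible from it.
#' @return A list of length \code{nSubjects}; each element a list with
#'   components \code{spec} (the subject's normal-walk spec),
#'   \code{normal}, \code{left}, \code{right}
#'   ([DepthSequence-class] objects).
#' @export
generateCohort <- function(nSubjects, base = walkerSpec(lldOffset = 50,
                                                        noiseSd = 5),
                           jitter = list(torsoDepth = c(2350, 2650),
                                         limbAmplitude = c(80, 120)),
                           seed = 1L) {
  stopifnot(nSubjects >= 1)
  base <- as(base, "WalkerSpec")
  if (base@lldOffset <= 0)
    stop("'base@lldOffset' must be > 0: it is the simulated sole height")
  runWithSeed(seed, {
    lapply(seq_len(nSubjects), function(i) {
      sp <- base
      for (nm in names(jitter)) {
        rg <- jitter[[nm]]
        slot(sp, nm) <- round(stats::runif(1, rg[1], rg[2]))
      }
      sp@seed <- as.integer(seed * 1000L + i * 10L)
      mk <- function(side, extraSeed) {
        s <- sp
        s@lldSide <- side
        if (side == "none") s@lldOffset <- 0
        s@seed <- sp@seed + extraSeed
        generateWalker(s)
      }
      sp@lldSide <- "none"             # the spec records the subject's
      sp@lldOffset <- base@lldOffset   # geometry; sole height on record
      list(spec = sp,
           normal = mk("none", 1L),
           left = mk("left", 2L),
           right = mk("right", 3L))
    })
  })
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards.
runWithSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
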