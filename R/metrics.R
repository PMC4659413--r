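# Quantifying asymmetry: longitudinal-axis estimation, the ASI curve
# and index, and cohort-level paired comparisons.

#' Estimate the longitudinal body axis
#'
#' The symmetry line of the subject (head to tail) is searched within
#' \code{searchHalfwidth} pixels of the vertical centre line. For each
#' candidate column the silhouette contour -- the outermost subject
#' pixels of each row, located at the strong-gradient body boundary --
#' gives a per-row mismatch |distance-to-left-contour minus
#' distance-to-right-contour|; the candidate with the smallest median
#' mismatch wins. Ties go to the column closest to the centre, then to
#' the smallest index.
#'
#' @param x A [SilhouetteSequence-class] (its aggregated
#'   [silhouetteMask()] is used) or a logical H x W silhouette matrix.
#' @param searchHalfwidth Search half-width in pixels (default 10).
#' @return The axis column (1-based integer).
#' @export
estimateAxis <- function(x, searchHalfwidth = 10L) {
  mask <- if (is(x, "SilhouetteSequence")) silhouetteMask(x) else x
  stopifnot(is.matrix(mask), is.logical(mask))
  W <- ncol(mask)
  rows <- which(rowSums(mask) > 0L)
  if (!length(rows)) stop("no silhouette contour found")
  left <- apply(mask[rows, , drop = FALSE], 1L,
                function(z) which(z)[1L])
  right <- apply(mask[rows, , drop = FALSE], 1L,
                 function(z) max(which(z)))
  centre <- (W + 1) / 2
  cand <- seq(max(1L, floor(centre - searchHalfwidth)),
              min(W, ceiling(centre + searchHalfwidth)))
  mismatch <- vapply(cand, function(cc)
    stats::median(abs((cc - left) - (right - cc))), numeric(1))
  best <- which(mismatch == min(mismatch))
  best <- best[order(abs(cand[best] - centre), cand[best])][1L]
  as.integer(cand[best])
}

#' ASI curve: largest mirrored colour difference per row
#'
#' For each image row, the largest Euclidean colour difference (in
#' stretched LAB) between the pixel i columns left of the longitudinal
#' axis and the pixel i columns right of it, over offsets
#' \eqn{i \in [1, m]} with \eqn{m} the mirror half-width. A symmetric
#' gait yields mirrored pixels with (near-)identical colours and a flat
#' curve near zero; an asymmetric movement shows up as a bump at the
#' rows of the implicated body part.
#'
#' @param umap A (stretched) [AsymmetryMap-class] or (H, W, 3) array.
#' @param axis Axis column from [estimateAxis()].
#' @param mask Optional logical H x W silhouette matrix; rows without
#'   any silhouette content are excluded (the clipped background would
#'   contribute zero rows and dilute the index).
#' @return Numeric vector of per-row maxima; names are the row indices
#'   (vertical distance from the top of the image).
#' @export
asiCurve <- function(umap, axis, mask = NULL) {
  v <- if (is(umap, "AsymmetryMap")) umap@values else umap
  d <- dim(v)
  H <- d[1]; W <- d[2]
  if (axis < 1L || axis > W) stop("axis outside the image")
  m <- min(axis - 1L, W - axis)
  if (m < 1L) stop("mirror half-width is empty at this axis")
  off <- seq_len(m)
  leftB <- v[, axis - off, , drop = FALSE]
  rightB <- v[, axis + off, , drop = FALSE]
  D2 <- (leftB - rightB)^2
  D2 <- D2[, , 1L] + D2[, , 2L] + D2[, , 3L]
  D2 <- matrix(D2, H, m)
  curve <- sqrt(apply(D2, 1L, max))
  rows <- seq_len(H)
  if (!is.null(mask)) rows <- rows[rowSums(mask) > 0L]
  if (!length(rows)) stop("no rows left after silhouette exclusion")
  stats::setNames(curve[rows], rows)
}

#' ASI index
#'
#' The mean of the ASI curve elements: a single number summarising the
#' gait asymmetry of a sequence. A relative measure -- meaningful for
#' within-subject comparisons (conditions, progression, treatment), not
#' as an absolute normal/abnormal threshold.
#'
#' @param x A numeric ASI curve, or an [AsiResult-class].
#' @return Scalar index.
#' @export
setGeneric("asiIndex", function(x) standardGeneric("asiIndex"))

#' @rdname asiIndex
#' @export
setMethod("asiIndex", "numeric", function(x) {
  if (!length(x)) stop("empty ASI curve")
  mean(x)
})

#' @rdname asiIndex
#' @export
setMethod("asiIndex", "AsiResult", function(x) x@index)

#' Axis, ASI curve and index of an asymmetry map
#'
#' Two-step procedure: estimate the longitudinal axis from the
#' silhouette, then record the maximal mirrored colour difference per
#' row about that axis.
#'
#' @param umap A (stretched) [AsymmetryMap-class].
#' @param mask Logical H x W silhouette matrix (e.g.
#'   [silhouetteMask()] of the silhouette sequence); also used to
#'   exclude empty rows from the curve.
#' @param searchHalfwidth Axis search half-width (default 10 px).
#' @return An [AsiResult-class].
#' @export
computeAsi <- function(umap, mask, searchHalfwidth = 10L) {
  axis <- estimateAxis(mask, searchHalfwidth)
  curve <- asiCurve(umap, axis, mask)
  W <- dim(if (is(umap, "AsymmetryMap")) umap@values else umap)[2]
  new("AsiResult", axis = axis, curve = as.numeric(curve),
      rows = as.integer(names(curve)), index = mean(curve),
      m = as.integer(min(axis - 1L, W - axis)))
}

#' Paired comparison of ASI values between two conditions
#'
#' Paired two-sided t test on per-subject ASI values (condition B minus
#' condition A), reporting the t statistic on n - 1 degrees of freedom
#' and the confidence value 1 - p. Used to ask whether, e.g., a
#' simulated leg-length discrepancy raises the ASI over the normal walk
#' of the same subjects.
#'
#' @param asiA,asiB Equal-length numeric vectors of per-subject ASI
#'   values under the two conditions (n >= 2 pairs).
#' @return List with \code{t}, \code{df}, \code{p.value},
#'   \code{confidence} (= 1 - p) and \code{degenerate} (TRUE when all
#'   differences are identical and nonzero, giving an infinite t).
#' @export
pairedComparison <- function(asiA, asiB) {
  if (length(asiA) != length(asiB))
    stop("paired samples must have equal length")
  n <- length(asiA)
  if (n < 2L) stop("need at least 2 pairs")
  d <- asiB - asiA
  if (stats::sd(d) == 0) {
    # degenerate cases: identical groups give t = 0 (no evidence of a
    # difference); identical nonzero differences give an infinite t
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p.value = 1, confidence = 0,
                  degenerate = TRUE))
    warning("all paired differences identical: infinite t statistic")
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p.value = 0,
                confidence = 1, degenerate = TRUE))
  }
  tt <- stats::t.test(asiB, asiA, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, confidence = 1 - tt$p.value,
       degenerate = FALSE)
}
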