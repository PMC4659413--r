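#' Project a pixel with depth into 3-D world coordinates
#'
#' Applies the inverse pinhole model \eqn{(X, Y, Z)^T = d K^{-1} (u, v, 1)^T},
#' i.e. \eqn{X = d (u - c_u) / f}, \eqn{Y = d (v - c_v) / f}, \eqn{Z = d}.
#' Coordinates are 0-based pixels; the world frame has Y pointing down and
#' units of mm.
#'
#' @param u,v Pixel coordinates (0-based column / row); vectorised.
#' @param d Depth in mm; must be > 0.
#' @param cam A [CameraModel-class].
#' @return Numeric matrix with columns X, Y, Z (mm); a single row is
#'   returned as a named vector.
#' @examples
#' cam <- CameraModel()
#' projectTo3d(815.82, 240, 1000, cam)
#' @export
projectTo3d <- function(u, v, d, cam) {
  stopifnot(is(cam, "CameraModel"))
  if (any(d <= 0)) stop("depth 'd' must be > 0")
  out <- cbind(X = d * (u - cam@cu) / cam@f,
               Y = d * (v - cam@cv) / cam@f,
               Z = d)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Project a 3-D world point into the image
#'
#' The forward pinhole model \eqn{u = f X / Z + c_u},
#' \eqn{v = f Y / Z + c_v}; inverse of [projectTo3d()] for \eqn{Z > 0}.
#'
#' @param X,Y,Z World coordinates in mm; \code{Z} must be > 0; vectorised.
#' @param cam A [CameraModel-class].
#' @return Numeric matrix with columns u, v (0-based pixels); a single row
#'   is returned as a named vector.
#' @export
projectTo2d <- function(X, Y, Z, cam) {
  stopifnot(is(cam, "CameraModel"))
  if (any(Z <= 0)) stop("'Z' must be > 0")
  out <- cbind(u = cam@f * X / Z + cam@cu,
               v = cam@f * Y / Z + cam@cv)
  if (nrow(out) == 1L) out[1L, ] else out
}
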