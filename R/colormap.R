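# Conversion of the refined embedding into a displayable perceptual
# colour image.

#' An 8-bit sRGB rendering of an asymmetry map
#'
#' @slot rgb integer array (H, W, 3), values in [0, 255].
#' @slot clampedFraction numeric(1). Fraction of pixels with at least one
#'   channel clamped during gamut mapping.
#' @slot stretch list. The per-channel affine stretch applied before
#'   conversion, for reproducibility.
#' @export
setClass("RgbImage",
  slots = c(rgb = "array", clampedFraction = "numeric",
            stretch = "list"))

setValidity("RgbImage", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    return("'rgb' must be an (H, W, 3) array")
  if (min(object@rgb) < 0L || max(object@rgb) > 255L)
    return("'rgb' values must lie in [0, 255]")
  TRUE
})

setMethod("show", "RgbImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("RgbImage: %d x %d px, %.2f%% of pixels gamut-clamped\n",
              d[1], d[2], 100 * object@clampedFraction))
})

#' Stretch a map's channels to the displayable LAB range
#'
#' Affine per-channel stretch: L is mapped to [0, 100]; A and B are
#' shifted to zero mean and scaled so their maximal amplitude is 100.
#' This keeps the subsequent sRGB conversion from saturating more than a
#' handful of pixels. Constant channels follow documented conventions:
#' a constant L becomes 50 everywhere, a constant A or B becomes 0.
#' The operation is idempotent.
#'
#' @param umap An [AsymmetryMap-class] or (H, W, 3) array.
#' @return An [AsymmetryMap-class]; \code{provenance(x)$stretch} records
#'   the per-channel offset and scale applied.
#' @export
stretchLab <- function(umap) {
  v <- if (is(umap, "AsymmetryMap")) umap@values else umap
  prov <- if (is(umap, "AsymmetryMap")) umap@provenance else list()
  L <- v[, , 1L]; A <- v[, , 2L]; B <- v[, , 3L]
  st <- list()
  rngL <- range(L)
  if (rngL[1] == rngL[2]) {
    L[] <- 50
    st$L <- c(offset = 50 - rngL[1], scale = 1)
  } else {
    sc <- 100 / (rngL[2] - rngL[1])
    L <- (L - rngL[1]) * sc
    st$L <- c(offset = -rngL[1] * sc, scale = sc)
  }
  centreAmp <- function(x) {
    mu <- mean(x)
    x <- x - mu
    mx <- max(abs(x))
    sc <- if (mx > 0) 100 / mx else 1
    list(x = x * sc, par = c(offset = -mu * sc, scale = sc))
  }
  a <- centreAmp(A); b <- centreAmp(B)
  st$A <- a$par; st$B <- b$par
  prov$stretch <- st
  new("AsymmetryMap",
      values = array(c(L, a$x, b$x), dim = dim(v)), provenance = prov)
}

#' Convert a stretched LAB map to an 8-bit sRGB image
#'
#' Standard CIE 1976 L*a*b* to sRGB conversion: Lab to XYZ under the
#' D65 reference white (0.95047, 1, 1.08883), the IEC 61966-2-1 linear
#' transform, then sRGB companding. Out-of-gamut values are clamped to
#' the channel range and the fraction of affected pixels is reported --
#' after [stretchLab()] it should be small.
#'
#' @param umap A (stretched) [AsymmetryMap-class] or (H, W, 3) array.
#' @return An [RgbImage-class].
#' @export
labToRgb <- function(umap) {
  v <- if (is(umap, "AsymmetryMap")) umap@values else umap
  prov <- if (is(umap, "AsymmetryMap")) umap@provenance else list()
  d <- dim(v)
  lab <- matrix(v, prod(d[1:2]), 3L)
  srgb <- .labToSrgb(lab)
  tol <- 1e-9
  clamped <- rowSums(srgb < -tol | srgb > 1 + tol) > 0L
  srgb[srgb < 0] <- 0
  srgb[srgb > 1] <- 1
  out <- array(as.integer(round(srgb * 255)), dim = d)
  new("RgbImage", rgb = out, clampedFraction = mean(clamped),
      stretch = if (is.null(prov$stretch)) list() else prov$stretch)
}

# CIE L*a*b* (D65) -> sRGB, IEC 61966-2-1 constants; rows of `lab` are
# pixels. Returns uncompanded-then-companded values, NOT clamped.
.labToSrgb <- function(lab) {
  fy <- (lab[, 1L] + 16) / 116
  fx <- fy + lab[, 2L] / 500
  fz <- fy - lab[, 3L] / 200
  finv <- function(t) ifelse(t^3 > 216 / 24389, t^3,
                             (116 * t - 16) * 27 / 24389)
  xyz <- cbind(0.95047 * finv(fx), finv(fy), 1.08883 * finv(fz))
  M <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                -0.9692660, 1.8760108, 0.0415560,
                0.0556434, -0.2040259, 1.0572252), 3L, 3L,
              byrow = TRUE)
  lin <- xyz %*% t(M)
  ifelse(lin <= 0.0031308, 12.92 * lin,
         1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
}

#' Write an RGB asymmetry image as PNG
#'
#' @param img An [RgbImage-class].
#' @param path Output PNG file.
#' @return Invisibly, \code{path}.
#' @export
writeAsymmetryPng <- function(img, path) {
  stopifnot(is(img, "RgbImage"))
  png::writePNG(img@rgb / 255, path)
  invisible(path)
}
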