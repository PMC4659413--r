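#' Read a depth sequence from disk
#'
#' Two storage dialects are supported, both lossless for 16-bit depth:
#' \describe{
#'   \item{raw stack}{a directory holding \code{frames.bin} (little-endian
#'     unsigned 16-bit, column-major \code{(H, W, N)} order) plus a
#'     \code{manifest.yaml} describing dtype, shape and frame rate --
#'     the format written by [writeDepthSequence()];}
#'   \item{PNG frames}{a directory of lexicographically ordered 16-bit
#'     single-channel PNG files (one per frame).}
#' }
#'
#' @param path Directory holding the sequence.
#' @param manifest Optional list overriding/supplying manifest entries
#'   (e.g. \code{list(fps = 30)} for a PNG directory without one).
#' @return A [DepthSequence-class]; depth values are preserved bit-exactly.
#' @seealso [writeDepthSequence()]
#' @export
readDepthSequence <- function(path, manifest = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  mf <- file.path(path, "manifest.yaml")
  man <- if (file.exists(mf)) yaml::read_yaml(mf) else list()
  man[names(manifest)] <- manifest
  if (identical(man$container, "raw") ||
      file.exists(file.path(path, "frames.bin"))) {
    .readRawStack(path, man)
  } else {
    .readPngStack(path, man)
  }
}

.readRawStack <- function(path, man) {
  need <- c("dtype", "height", "width", "nFrames")
  if (!all(need %in% names(man)))
    stop("manifest is missing entries: ",
         paste(setdiff(need, names(man)), collapse = ", "))
  if (!identical(man$dtype, "uint16"))
    stop("unsupported dtype in manifest: ", man$dtype)
  h <- as.integer(man$height); w <- as.integer(man$width)
  n <- as.integer(man$nFrames)
  f <- file.path(path, "frames.bin")
  if (!file.exists(f)) stop("missing frames.bin in ", path)
  nv <- h * w * n
  con <- file(f, "rb"); on.exit(close(con))
  x <- readBin(con, "integer", n = nv, size = 2L, signed = FALSE,
               endian = "little")
  if (length(x) != nv)
    stop(sprintf("frames.bin holds %d values, manifest promises %d",
                 length(x), nv))
  DepthSequence(array(x, dim = c(h, w, n)),
                fps = if (is.null(man$fps)) 30 else as.numeric(man$fps))
}

.readPngStack <- function(path, man) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", path)
  frames <- vector("list", length(files))
  dim0 <- NULL
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i], info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 16L)
      stop(sprintf("frame %d (%s): unsupported bit depth %d (need 16)",
                   i, basename(files[i]), info$bit.depth))
    if (length(dim(img)) != 2L)
      stop(sprintf("frame %d (%s): expected a single channel, got %d",
                   i, basename(files[i]), dim(img)[3]))
    if (is.null(dim0)) dim0 <- dim(img)
    else if (!identical(dim(img), dim0))
      stop(sprintf("frame %d (%s): shape %dx%d differs from %dx%d",
                   i, basename(files[i]), dim(img)[1], dim(img)[2],
                   dim0[1], dim0[2]))
    # readPNG rescales 16-bit samples to [0, 1] by 65535
    frames[[i]] <- as.integer(round(img * 65535))
  }
  arr <- array(unlist(frames), dim = c(dim0, length(files)))
  DepthSequence(arr,
                fps = if (is.null(man$fps)) 30 else as.numeric(man$fps))
}

#' Write a depth sequence to disk
#'
#' Writes the raw-stack dialect: \code{frames.bin} (little-endian uint16,
#' column-major) plus \code{manifest.yaml}. The output re-reads bit-exactly
#' with [readDepthSequence()].
#'
#' @param seq A [DepthSequence-class].
#' @param path Output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
writeDepthSequence <- function(seq, path) {
  stopifnot(is(seq, "DepthSequence"))
  validObject(seq)
  if (max(seq@frames) > 65535L)
    stop("depth values exceed the 16-bit container (max 65535 mm)")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  d <- dim(seq@frames)
  man <- list(container = "raw", dtype = "uint16",
              height = d[1], width = d[2], nFrames = d[3],
              fps = seq@fps,
              order = "column-major (H, W, N)", file = "frames.bin")
  con <- file(file.path(path, "frames.bin"), "wb")
  writeBin(as.integer(seq@frames), con, size = 2L, endian = "little")
  close(con)
  yaml::write_yaml(man, file.path(path, "manifest.yaml"))
  invisible(man)
}
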