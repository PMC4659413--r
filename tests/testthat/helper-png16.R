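# Minimal 16-bit grayscale PNG emitter, used only to build test
# fixtures for the PNG-reading dialect (the installed PNG binding writes
# 8-bit files only). Validated against png::readPNG in the tests.

.crcTable <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))   # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(.crcTable[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  bitwXor(crc, -1L)
}

.beInt <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                               endian = "big")

.pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.beInt(length(data)), body, .beInt(.crc32(body)))
}

# mat: integer matrix (H, W) with values in 0..65535
writePng16Gray <- function(mat, path) {
  H <- nrow(mat); W <- ncol(mat)
  scan <- raw(0)
  for (r in seq_len(H)) {
    row <- as.integer(mat[r, ])
    bytes <- as.raw(rbind(row %/% 256L, row %% 256L))
    scan <- c(scan, as.raw(0L), bytes)
  }
  # memCompress(type = "gzip") emits a zlib stream (0x78 header +
  # adler32 trailer), which is exactly what IDAT holds
  zlib <- memCompress(scan, "gzip")
  ihdr <- c(.beInt(W), .beInt(H),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit grayscale
  png <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           .pngChunk("IHDR", ihdr),
           .pngChunk("IDAT", zlib),
           .pngChunk("IEND", raw(0)))
  writeBin(png, path)
  invisible(path)
}
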