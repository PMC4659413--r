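# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementations.

# Exhaustive shifted distance: min over the given circular shifts of the
# chosen norm (plain loops).
bruteShiftDist <- function(s1, s2, taus, kind = "L2") {
  N <- length(s1)
  best <- Inf
  for (tau in taus) {
    x <- numeric(N)
    for (t in seq_len(N)) x[t] <- s1[(t - 1 + tau) %% N + 1] - s2[t]
    v <- switch(kind, L2 = sum(x^2), L1 = sum(abs(x)),
                Linf = max(abs(x)))
    best <- min(best, v)
  }
  if (kind == "L2") sqrt(best) else best
}

# Brute-force 3x3x3 median with the package's border convention:
# nearest-edge replication in space, circular wrap in time.
bruteMedian3d <- function(a) {
  d <- dim(a)
  out <- array(0L, d)
  for (r in seq_len(d[1])) for (cc in seq_len(d[2]))
    for (t in seq_len(d[3])) {
      vals <- integer(0)
      for (dr in -1:1) for (dc in -1:1) for (dt in -1:1) {
        rr <- min(max(r + dr, 1), d[1])
        c2 <- min(max(cc + dc, 1), d[2])
        tt <- (t - 1 + dt) %% d[3] + 1
        vals <- c(vals, a[rr, c2, tt])
      }
      out[r, cc, t] <- median(vals)
    }
  out
}

# Independent reconstruction of the neighbourhood graph's edge set
# following the documented placement rule: 4-neighbours plus nCnx
# equally spaced cells of the nS x nS window in column-major order
# (centre excluded), truncated at borders, undirected, deduplicated.
bruteGraphEdges <- function(H, W, nS, nCnx) {
  h <- (nS - 1) / 2
  cells <- list()
  for (dc in -h:h) for (dr in -h:h)
    if (abs(dr) + abs(dc) > 1) cells[[length(cells) + 1]] <- c(dr, dc)
  sel <- unique(round(seq(1, length(cells), length.out = nCnx)))
  offs <- c(list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
            if (nCnx > 0) cells[sel])
  seen <- character(0)
  edges <- list()
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    i <- (c0 - 1) * H + r0
    for (o in offs) {
      r1 <- r0 + o[1]; c1 <- c0 + o[2]
      if (r1 < 1 || r1 > H || c1 < 1 || c1 > W) next
      j <- (c1 - 1) * H + r1
      key <- paste(min(i, j), max(i, j))
      if (key %in% seen) next
      seen <- c(seen, key)
      edges[[length(edges) + 1]] <- c(min(i, j), max(i, j))
    }
  }
  m <- do.call(rbind, edges)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Textbook CIE L*a*b* (D65) -> sRGB conversion, written directly from
# the standard formulas.
labToRgbRef <- function(lab) {
  L <- lab[1]; A <- lab[2]; B <- lab[3]
  fy <- (L + 16) / 116
  fx <- fy + A / 500
  fz <- fy - B / 200
  finv <- function(t) ifelse(t^3 > 216 / 24389, t^3,
                             (116 * t - 16) * 27 / 24389)
  # D65 reference white
  X <- 0.95047 * finv(fx)
  Y <- 1.00000 * finv(fy)
  Z <- 1.08883 * finv(fz)
  M <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                -0.9692660, 1.8760108, 0.0415560,
                0.0556434, -0.2040259, 1.0572252),
              3, 3, byrow = TRUE)
  rgbLin <- as.vector(M %*% c(X, Y, Z))
  gamma <- function(u) ifelse(u <= 0.0031308, 12.92 * u,
                              1.055 * u^(1 / 2.4) - 0.055)
  out <- pmin(pmax(gamma(rgbLin), 0), 1)
  attr(out, "linear") <- rgbLin
  out
}

# Paired t statistic from the closed formula.
brutePairedT <- function(a, b) {
  d <- b - a
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, p = p)
}
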