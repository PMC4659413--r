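# Temporally shift-invariant distances between per-pixel depth signals,
# and the sparse pixel-pair graph they are evaluated on.

# Circular shift index sets for a signal of length N: the forward grid
# {0, tauStep, ..., tauMax} and its negatives (symmetrisation), reduced
# mod N and deduplicated.
.shiftSet <- function(N, spec) {
  tau <- seq(0L, spec@tauMax, by = spec@tauStep)
  sort(unique(c(tau %% N, (-tau) %% N)))
}

.shiftIndex <- function(N, tau) ((seq_len(N) - 1L + tau) %% N) + 1L

#' Shift-invariant distance between two depth signals
#'
#' The core dissimilarity of the method: for the shifted kinds
#' (\code{"L2"}, \code{"L1"}, \code{"Linf"}) the chosen norm of
#' \eqn{s_1(t + \tau) - s_2(t)} is minimised over the circular shift grid
#' \eqn{\tau \in \{0, \pm\tau_{step}, \dots, \pm\tau_{max}\}} (the
#' negative shifts symmetrise the distance), so two signals describing
#' the same movement half a gait period apart -- the two legs of a
#' symmetric walk -- are at distance (near) zero. \code{"L2"} returns the
#' square root of the minimal sum of squared per-frame differences, i.e.
#' a Euclidean distance commensurate with colour differences.
#'
#' Three shift-free alternatives are provided for comparison:
#' \code{"Lmod"} (L2 between Fourier amplitude spectra, inherently
#' shift-invariant), \code{"Lrad"} (L2 between amplitude histograms on
#' bin edges shared by the pair) and \code{"Lmoy"} (L1 between the two
#' signal means). The latter two cannot see asymmetries that preserve
#' the value distribution or the mean.
#'
#' @param s1,s2 Numeric vectors of equal length N >= 2.
#' @param spec A [ShiftDistanceSpec-class].
#' @return A non-negative scalar; zero for identical signals.
#' @examples
#' s <- sin(2 * pi * (0:59) / 30) * 100 + 2500
#' shiftDistance(s, s[c(16:60, 1:15)], shiftDistanceSpec(tauStep = 15))
#' @export
shiftDistance <- function(s1, s2, spec = shiftDistanceSpec()) {
  stopifnot(is(spec, "ShiftDistanceSpec"))
  if (length(s1) != length(s2))
    stop("signals must have equal length")
  N <- length(s1)
  if (N < 2L) stop("signals must have length >= 2")
  switch(spec@kind,
    L2 = , L1 = , Linf = {
      best <- Inf
      for (tau in .shiftSet(N, spec)) {
        x <- s1[.shiftIndex(N, tau)] - s2
        v <- switch(spec@kind, L2 = sum(x * x), L1 = sum(abs(x)),
                    Linf = max(abs(x)))
        if (v < best) best <- v
      }
      if (spec@kind == "L2") sqrt(best) else best
    },
    Lmod = {
      a1 <- Mod(stats::fft(s1)); a2 <- Mod(stats::fft(s2))
      sqrt(sum((a1 - a2)^2))
    },
    Lrad = {
      h <- .amplitudeHist(rbind(s1, s2), spec@nBins)
      sqrt(sum((h[1, ] - h[2, ])^2))
    },
    Lmoy = abs(mean(s1) - mean(s2)))
}

# Histogram counts per row of a signal matrix on bin edges shared by all
# rows supplied (the pair, or the whole image).
.amplitudeHist <- function(S, nBins) {
  rng <- range(S)
  if (rng[1] == rng[2])
    return(matrix(c(ncol(S), rep(0L, nBins - 1L)), nrow(S), nBins,
                  byrow = TRUE))
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- findInterval(S, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  dim(bin) <- dim(S)
  t(apply(bin, 1L, tabulate, nbins = nBins))
}

#' Build the sparse pixel-pair graph
#'
#' Links every pixel of an (H, W) image to its four nearest neighbours
#' plus \code{nCnx} approximately equally spaced pixels inside a centred
#' \code{nS} x \code{nS} window (long-range links let the embedding see
#' beyond local texture without the quadratic cost of all pairs). The
#' long-range offsets are chosen deterministically: the window cells in
#' column-major order, excluding the centre, sampled at \code{nCnx}
#' equally spaced positions. Links falling outside the image are
#' truncated; the edge set is undirected and deduplicated.
#'
#' @param shape Image size c(H, W).
#' @param nS Window size in pixels; odd. Default 13.
#' @param nCnx Long-range links per pixel. Default 11.
#' @return A [DistanceGraph-class] with edges only (no distances yet).
#' @export
buildGraph <- function(shape, nS = 13L, nCnx = 11L) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  nS <- as.integer(nS); nCnx <- as.integer(nCnx)
  if (nS %% 2L != 1L) stop("'nS' must be odd")
  if (nCnx < 0L) stop("'nCnx' must be >= 0")
  offs <- .graphOffsets(nS, nCnx)
  npix <- H * W
  from <- to <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    dr <- offs[i, 1L]; dc <- offs[i, 2L]
    r <- seq_len(H); c <- seq_len(W)
    rOk <- r[r + dr >= 1L & r + dr <= H]
    cOk <- c[c + dc >= 1L & c + dc <= W]
    if (!length(rOk) || !length(cOk)) next
    a <- outer(rOk, (cOk - 1L) * H, "+")
    b <- outer(rOk + dr, (cOk + dc - 1L) * H, "+")
    from[[i]] <- as.vector(a); to[[i]] <- as.vector(b)
  }
  a <- unlist(from); b <- unlist(to)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated((lo - 1) * as.double(npix) + hi) & lo != hi
  new("DistanceGraph",
      edges = cbind(lo[keep], hi[keep]),
      beta = numeric(0), betaScaled = numeric(0), k = NA_real_,
      dim = c(H, W), nS = nS, nCnx = nCnx)
}

# Neighbourhood offsets: 4-connected plus nCnx equally spaced cells of
# the nS x nS window (column-major order; the centre and the four
# nearest neighbours are not candidates -- the long-range links are
# "other" pixels).
.graphOffsets <- function(nS, nCnx) {
  h <- (nS - 1L) %/% 2L
  four <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  if (nCnx == 0L) return(four)
  g <- as.matrix(expand.grid(dr = -h:h, dc = -h:h))
  g <- g[abs(g[, 1L]) + abs(g[, 2L]) > 1L, , drop = FALSE]
  sel <- unique(round(seq(1L, nrow(g), length.out = nCnx)))
  rbind(four, g[sel, , drop = FALSE])
}

#' Fill the graph with shift-invariant distances
#'
#' Evaluates [shiftDistance()] between the depth signals at the two ends
#' of every graph edge, in a vectorised batch over the shift grid.
#' Deterministic; distances are symmetric by construction.
#'
#' @param sil A [SilhouetteSequence-class] (its frames supply the
#'   signals) or a pixels-by-frames signal matrix matching the graph.
#' @param graph A [DistanceGraph-class] from [buildGraph()].
#' @param spec A [ShiftDistanceSpec-class].
#' @return The graph with \code{beta} filled.
#' @export
computeDistances <- function(sil, graph, spec = shiftDistanceSpec()) {
  stopifnot(is(graph, "DistanceGraph"), is(spec, "ShiftDistanceSpec"))
  S <- signalMatrix(sil)
  if (nrow(S) != prod(graph@dim))
    stop("signal matrix does not match the graph image size")
  e1 <- graph@edges[, 1L]; e2 <- graph@edges[, 2L]
  N <- ncol(S)
  graph@beta <- switch(spec@kind,
    L2 = {
      sq <- rowSums(S * S)
      best <- rep(Inf, length(e1))
      A2 <- S[e2, , drop = FALSE]
      for (tau in .shiftSet(N, spec)) {
        cross <- rowSums(S[e1, .shiftIndex(N, tau), drop = FALSE] * A2)
        best <- pmin(best, sq[e1] + sq[e2] - 2 * cross)
      }
      sqrt(pmax(best, 0))
    },
    L1 = , Linf = {
      best <- rep(Inf, length(e1))
      A2 <- S[e2, , drop = FALSE]
      for (tau in .shiftSet(N, spec)) {
        X <- abs(S[e1, .shiftIndex(N, tau), drop = FALSE] - A2)
        v <- if (spec@kind == "L1") rowSums(X)
             else do.call(pmax, lapply(seq_len(ncol(X)),
                                       function(j) X[, j]))
        best <- pmin(best, v)
      }
      best
    },
    Lmod = {
      A <- t(Mod(stats::mvfft(t(S))))
      sqrt(rowSums((A[e1, , drop = FALSE] - A[e2, , drop = FALSE])^2))
    },
    Lrad = {
      vapply(seq_along(e1), function(i) {
        h <- .amplitudeHist(S[c(e1[i], e2[i]), , drop = FALSE],
                            spec@nBins)
        sqrt(sum((h[1, ] - h[2, ])^2))
      }, numeric(1))
    },
    Lmoy = {
      m <- rowMeans(S)
      abs(m[e1] - m[e2])
    })
  graph
}

#' Per-pixel depth-signal matrix
#'
#' Reshapes the (H, W, N) depth cube into a (H*W, N) matrix whose rows
#' are the depth signals, in column-major pixel order (the order used by
#' [DistanceGraph-class] indices).
#'
#' @param x A [DepthSequence-class] (or subclass) or a 3-D array; a
#'   matrix passes through.
#' @return Numeric matrix (pixels, frames).
#' @export
signalMatrix <- function(x) {
  if (is(x, "DepthSequence")) x <- x@frames
  if (is.matrix(x)) return(x)
  d <- dim(x)
  stopifnot(length(d) == 3L)
  dim(x) <- c(d[1] * d[2], d[3])
  storage.mode(x) <- "double"
  x
}
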