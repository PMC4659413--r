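# FastMap: linear-time multidimensional scaling. Axes of the target
# space are built one by one from a distant pivot pair; every point is
# projected onto the pivot line by the cosine law and the construction
# recurses on the residual distances.

#' FastMap embedding of objects given by a distance oracle
#'
#' Maps n objects to p coordinates so that pairwise distances are
#' preserved as well as possible, at O(pn) distance evaluations -- the
#' full distance matrix is never formed. Per axis, a distant pivot pair
#' (a, b) is found by farthest-point hops (5 hops, deterministic, ties
#' broken towards the lowest index), each point is projected by
#' \deqn{x_i = (d_{ai}^2 + d_{ab}^2 - d_{bi}^2) / (2 d_{ab}),}
#' and the next axis works on the residual distances
#' \eqn{d'^2 = d^2 - (x_i - x_j)^2} (floored at zero). Distances exactly
#' realisable in p Euclidean dimensions are reproduced exactly; if all
#' residual distances vanish the remaining axes are zero.
#'
#' @param x The objects: a numeric matrix of depth signals (one row per
#'   pixel, distances from \code{spec}), a \code{stats::dist} object, or
#'   a full symmetric distance matrix.
#' @param p Number of output dimensions (3 for an L, A, B map).
#' @param spec A [ShiftDistanceSpec-class]; used only when \code{x} holds
#'   signals.
#' @return Numeric matrix (n, p) of coordinates.
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' X <- fastMap(dist(pts), p = 3)
#' max(abs(dist(X) - dist(pts)))   # ~ 0: 3-D distances are 3-embeddable
#' @export
fastMap <- function(x, p = 3L, spec = shiftDistanceSpec()) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
    distFn <- function(i) D[i, ]
    n <- nrow(D)
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             isSymmetric(unname(x)) && all(diag(x) == 0)) {
    # a full symmetric distance matrix with zero diagonal
    distFn <- function(i) x[i, ]
    n <- nrow(x)
  } else if (is.matrix(x)) {
    distFn <- .signalDistFn(x, spec)
    n <- nrow(x)
  } else stop("'x' must be a signal matrix or a dist object")
  .fastMapCore(distFn, n, as.integer(p))
}

.fastMapCore <- function(distFn, n, p) {
  X <- matrix(0, n, p)
  eps <- 1e-12
  resDist <- function(i, ax) {
    d2 <- distFn(i)^2
    if (ax > 1L) {
      prev <- X[, seq_len(ax - 1L), drop = FALSE]
      d2 <- d2 - rowSums((prev - matrix(prev[i, ], n, ax - 1L,
                                        byrow = TRUE))^2)
    }
    sqrt(pmax(d2, 0))
  }
  for (ax in seq_len(p)) {
    # farthest-point pivot hops
    a <- 1L
    da <- resDist(a, ax)
    b <- which.max(da)
    for (hop in seq_len(4L)) {
      db <- resDist(b, ax)
      a2 <- which.max(db)
      a <- b; da <- db; b <- a2
    }
    db <- resDist(b, ax)
    dab <- da[b]
    if (dab <= eps) next       # all residual distances zero: axis stays 0
    X[, ax] <- (da^2 + dab^2 - db^2) / (2 * dab)
    X[b, ax] <- dab            # exact endpoints (guards rounding)
    X[a, ax] <- 0
  }
  X
}

# Distance-to-all oracle for a signal matrix under a ShiftDistanceSpec.
# For the shifted L2 kind the scan is a single matrix product per query
# (||s_j - shift(s_i)||^2 expanded into dot products, exact for integer
# depth signals); other kinds fall back to direct evaluation.
.signalDistFn <- function(S, spec) {
  n <- nrow(S); N <- ncol(S)
  switch(spec@kind,
    L2 = {
      sq <- rowSums(S * S)
      idx <- lapply(.shiftSet(N, spec), .shiftIndex, N = N)
      function(i) {
        V <- vapply(idx, function(ix) S[i, ix], numeric(N))
        cross <- S %*% V                       # n x nTau
        d2 <- (sq + sq[i]) - 2 * cross
        sqrt(pmax(do.call(pmin, asplit(d2, 2L)), 0))
      }
    },
    Lmod = {
      A <- t(Mod(stats::mvfft(t(S))))
      function(i)
        sqrt(rowSums((A - matrix(A[i, ], n, ncol(A), byrow = TRUE))^2))
    },
    Lmoy = {
      m <- rowMeans(S)
      function(i) abs(m - m[i])
    },
    {
      function(i)
        vapply(seq_len(n), function(j)
          shiftDistance(S[i, ], S[j, ], spec), numeric(1))
    })
}
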