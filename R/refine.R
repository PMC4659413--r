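# Scale estimation, GGMRF prior and ICM local-search refinement of the
# FastMap embedding.

# Clique weights of the second-order (8-connected) neighbourhood system:
# horizontal/vertical cliques and diagonal cliques. They normalise the
# contribution of the two clique orientations.
.gammaStraight <- 1 / (2 * sqrt(2) + 4)
.gammaDiagonal <- 1 / (4 + 4 * sqrt(2))

#' Operating-point defaults of the mapping method
#'
#' A single place collecting the method's numeric constants: the
#' regularisation weight eta, the GGMRF exponent q and clique weights,
#' the shift grid, the neighbourhood-graph parameters, the k search grid
#' and the axis search half-width.
#'
#' @return A named list.
#' @export
gaitmapDefaults <- function() {
  list(eta = 0.025, q = 1,
       gammaStraight = .gammaStraight, gammaDiagonal = .gammaDiagonal,
       tauMax = 66L, tauStep = 6L, nS = 13L, nCnx = 11L,
       kGridStep = 0.005, icmRadius = 1, icmSweeps = 2L,
       searchHalfwidth = 10L)
}

#' Estimate the linear stretch between graph distances and the embedding
#'
#' Finds the factor \eqn{k} minimising
#' \eqn{\sum_{(s,t)} (k\beta_{s,t} - ||u_s - u_t||_2)^2} over the graph
#' edges: the least-squares solution
#' \eqn{k = \sum \beta d / \sum \beta^2}, snapped to the search grid
#' \eqn{k \in [0, 1]} with step 0.005. The scaled distances
#' \eqn{\beta^{scaled} = k \beta} become the observed data of the
#' refinement energy. If every \eqn{\beta} is zero, \eqn{k = 0} by
#' convention.
#'
#' @param graph A [DistanceGraph-class] with \code{beta} filled.
#' @param umap An [AsymmetryMap-class] (or an (H, W, 3) array) on the
#'   scale the embedding is refined on.
#' @param gridStep Snap grid for k (default 0.005).
#' @return The graph with \code{k} and \code{betaScaled} set
#'   (\code{\link{scaleFactor}} retrieves k).
#' @export
estimateScale <- function(graph, umap, gridStep = 0.005) {
  stopifnot(is(graph, "DistanceGraph"))
  if (!length(graph@beta)) stop("graph has no distances yet")
  d <- .edgeMapDist(graph, umap)
  sb2 <- sum(graph@beta^2)
  k <- if (sb2 == 0) 0 else sum(graph@beta * d) / sb2
  k <- min(max(round(k / gridStep) * gridStep, 0), 1)
  graph@k <- k
  graph@betaScaled <- k * graph@beta
  graph
}

# Euclidean LAB distance across each graph edge.
.edgeMapDist <- function(graph, umap) {
  U <- .mapMatrix(umap, graph@dim)
  e <- graph@edges
  sqrt(rowSums((U[e[, 1L], , drop = FALSE] -
                  U[e[, 2L], , drop = FALSE])^2))
}

.mapMatrix <- function(umap, shape = NULL) {
  v <- if (is(umap, "AsymmetryMap")) umap@values else umap
  stopifnot(length(dim(v)) == 3L, dim(v)[3L] == 3L)
  if (!is.null(shape) && !identical(dim(v)[1:2], as.integer(shape)))
    stop("map shape does not match the graph")
  matrix(v, prod(dim(v)[1:2]), 3L)
}

#' GGMRF regularisation energy
#'
#' The edge-preserving smoothness prior
#' \eqn{\Omega(u) = \sum_{<s,t>} \gamma_{st} |u_s - u_t|^q} over the
#' second-order (8-connected) clique system, with
#' \eqn{\gamma_{st} = (2\sqrt{2}+4)^{-1}} for horizontal/vertical and
#' \eqn{(4+4\sqrt{2})^{-1}} for diagonal cliques. \eqn{|.|^q} is applied
#' per channel and summed; \eqn{q = 2} is a Gaussian MRF, \eqn{q = 1}
#' the edge-preserving absolute-value potential.
#'
#' @param umap An [AsymmetryMap-class] or (H, W, 3) array.
#' @param q Shape exponent, in [1, 2].
#' @return Non-negative scalar.
#' @export
ggmrfEnergy <- function(umap, q = 1) {
  if (q < 1 || q > 2) stop("'q' must lie in [1, 2]")
  v <- if (is(umap, "AsymmetryMap")) umap@values else umap
  d <- dim(v)
  H <- d[1]; W <- d[2]
  cl <- function(r1, c1, r2, c2)
    sum(abs(v[r1, c1, , drop = FALSE] - v[r2, c2, , drop = FALSE])^q)
  straight <- diagonal <- 0
  if (H > 1L) straight <- straight + cl(1:(H - 1), 1:W, 2:H, 1:W)
  if (W > 1L) straight <- straight + cl(1:H, 1:(W - 1), 1:H, 2:W)
  if (H > 1L && W > 1L) {
    diagonal <- cl(1:(H - 1), 1:(W - 1), 2:H, 2:W) +
      cl(2:H, 1:(W - 1), 1:(H - 1), 2:W)
  }
  .gammaStraight * straight + .gammaDiagonal * diagonal
}

#' Penalised cost of an asymmetry map
#'
#' The energy minimised by the refinement:
#' \deqn{E(u) = \sum_{(s,t)} (\beta^{scaled}_{s,t} - ||u_s - u_t||_2)^2
#'       + \eta\, \Omega(u),}
#' a goodness-of-fit term (preservation of scaled between-signal
#' distances over the graph edges) plus the GGMRF prior
#' ([ggmrfEnergy()]) weighted by \code{eta}.
#'
#' @param umap An [AsymmetryMap-class] or (H, W, 3) array.
#' @param graph A [DistanceGraph-class] with \code{betaScaled} set.
#' @param eta Regularisation weight (default 0.025).
#' @param q GGMRF exponent (default 1).
#' @return Scalar energy.
#' @export
totalEnergy <- function(umap, graph, eta = 0.025, q = 1) {
  stopifnot(is(graph, "DistanceGraph"))
  if (!length(graph@betaScaled))
    stop("graph has no scaled distances: run estimateScale() first")
  d <- .edgeMapDist(graph, umap)
  sum((graph@betaScaled - d)^2) + eta * ggmrfEnergy(umap, q)
}

#' ICM local-search refinement of the embedding
#'
#' Iterated conditional modes on the penalised cost ([totalEnergy()]):
#' Gauss--Seidel sweeps over the pixels in raster order; at each pixel
#' the 27 candidates \eqn{u_s + \{-r, 0, +r\}^3} are scored on the local
#' contribution (incident graph edges plus incident prior cliques) and
#' the best is kept. Each accepted move strictly lowers the global
#' energy, so the energy trace is non-increasing by construction; the
#' sweep loop stops early when a whole sweep accepts no move.
#'
#' @param umap0 Starting [AsymmetryMap-class] (or (H, W, 3) array),
#'   normally the LAB-scaled FastMap embedding.
#' @param graph A [DistanceGraph-class] with \code{betaScaled} set.
#' @param eta,q Energy parameters, see [totalEnergy()].
#' @param radius Exploration radius r in LAB units (default 1).
#' @param sweeps Maximum number of full sweeps (default 2).
#' @param shuffle Visit pixels in a random order instead of raster order
#'   (default FALSE; raster order is deterministic).
#' @param seed Seed for \code{shuffle}.
#' @return An [AsymmetryMap-class]; \code{provenance(x)$energyTrace}
#'   holds the energy before refinement and after each sweep, and
#'   \code{provenance(x)$moves} the accepted moves per sweep.
#' @export
icmRefine <- function(umap0, graph, eta = 0.025, q = 1, radius = 1,
                      sweeps = 2L, shuffle = FALSE, seed = 1L) {
  stopifnot(is(graph, "DistanceGraph"), radius > 0)
  if (!length(graph@betaScaled))
    stop("graph has no scaled distances: run estimateScale() first")
  v0 <- if (is(umap0, "AsymmetryMap")) umap0@values else umap0
  prov <- if (is(umap0, "AsymmetryMap")) umap0@provenance else list()
  d <- dim(v0)
  if (!identical(as.integer(d[1:2]), graph@dim))
    stop("map shape does not match the graph")
  npix <- prod(d[1:2])
  U <- matrix(v0, npix, 3L)

  adj <- .adjacency(graph@edges, graph@betaScaled, npix)
  pri <- .priorCliques(d[1], d[2])
  cand <- as.matrix(expand.grid(c(-radius, 0, radius),
                                c(-radius, 0, radius),
                                c(-radius, 0, radius)))
  centre <- which(rowSums(cand != 0) == 0L)

  energy <- totalEnergy(array(U, dim = d), graph, eta, q)
  trace <- energy
  movesPerSweep <- integer(0)
  for (sw in seq_len(sweeps)) {
    ord <- if (shuffle) runWithSeed(seed + sw, sample.int(npix))
           else seq_len(npix)
    moves <- 0L
    for (i in ord) {
      nb <- adj$nbr[[i]]; bt <- adj$beta[[i]]
      pn <- pri$nbr[[i]]; pw <- pri$w[[i]]
      C <- cand + matrix(U[i, ], nrow(cand), 3L, byrow = TRUE)
      local <- numeric(nrow(cand))
      if (length(nb)) {
        Un <- U[nb, , drop = FALSE]
        D2 <- matrix(rowSums(C * C), nrow(C), length(nb)) +
          matrix(rowSums(Un * Un), nrow(C), length(nb), byrow = TRUE) -
          2 * C %*% t(Un)
        fit <- (matrix(bt, nrow(C), length(nb), byrow = TRUE) -
                  sqrt(pmax(D2, 0)))^2
        local <- local + rowSums(fit)
      }
      if (eta > 0 && length(pn)) {
        Up <- U[pn, , drop = FALSE]
        pe <- abs(outer(C[, 1L], Up[, 1L], "-"))^q +
          abs(outer(C[, 2L], Up[, 2L], "-"))^q +
          abs(outer(C[, 3L], Up[, 3L], "-"))^q
        local <- local + eta * as.vector(pe %*% pw)
      }
      j <- which.min(local)
      if (j != centre && local[j] < local[centre] - 1e-12) {
        U[i, ] <- C[j, ]
        moves <- moves + 1L
      }
    }
    energy <- totalEnergy(array(U, dim = d), graph, eta, q)
    trace <- c(trace, energy)
    movesPerSweep <- c(movesPerSweep, moves)
    if (moves == 0L) break
  }
  prov$energyTrace <- trace
  prov$moves <- movesPerSweep
  prov$eta <- eta; prov$q <- q; prov$radius <- radius
  prov$k <- graph@k
  new("AsymmetryMap", values = array(U, dim = d), provenance = prov)
}

# Per-pixel incident graph edges (both directions).
.adjacency <- function(edges, beta, npix) {
  from <- c(edges[, 1L], edges[, 2L])
  to <- c(edges[, 2L], edges[, 1L])
  b <- c(beta, beta)
  o <- order(from)
  f <- factor(from[o], levels = seq_len(npix))
  list(nbr = split(to[o], f), beta = split(b[o], f))
}

# Per-pixel incident prior cliques of the 8-neighbourhood, with their
# gamma weights.
.priorCliques <- function(H, W) {
  npix <- H * W
  lin <- function(r, c) (c - 1L) * H + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  add <- function(dr, dc, wt) {
    r <- seq_len(H); c <- seq_len(W)
    rOk <- r[r + dr >= 1L & r + dr <= H]
    cOk <- c[c + dc >= 1L & c + dc <= W]
    if (!length(rOk) || !length(cOk)) return()
    a <- as.vector(outer(rOk, (cOk - 1L) * H, "+"))
    b <- as.vector(outer(rOk + dr, (cOk + dc - 1L) * H, "+"))
    from <<- c(from, a, b); to <<- c(to, b, a)
    w <<- c(w, rep(wt, 2L * length(a)))
  }
  add(1L, 0L, .gammaStraight); add(0L, 1L, .gammaStraight)
  add(1L, 1L, .gammaDiagonal); add(1L, -1L, .gammaDiagonal)
  o <- order(from)
  f <- factor(from[o], levels = seq_len(npix))
  list(nbr = split(to[o], f), w = split(w[o], f))
}

#' Correlation between graph distances and map colour differences
#'
#' Pearson correlation over the graph edges between the shift-invariant
#' signal distances and the Euclidean LAB differences of the map: the
#' quality score of the mapping (1 = distances perfectly preserved up to
#' scale).
#'
#' @param graph A [DistanceGraph-class] with \code{beta} filled.
#' @param umap An [AsymmetryMap-class] or (H, W, 3) array.
#' @return Correlation rho in [-1, 1].
#' @export
correlationScore <- function(graph, umap) {
  stopifnot(is(graph, "DistanceGraph"))
  if (length(graph@beta) < 2L)
    stop("need at least 2 edges with distances")
  if (stats::sd(graph@beta) == 0)
    stop("correlation undefined: all graph distances are equal")
  stats::cor(graph@beta, .edgeMapDist(graph, umap))
}
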