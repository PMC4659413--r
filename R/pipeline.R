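# End-to-end pipeline: silhouette -> embedding -> refined map -> colour
# image and ASI.

#' Compute the asymmetry map of a silhouette sequence
#'
#' The mapping stage: build the pixel-pair graph, evaluate the
#' shift-invariant distances on its edges, embed every pixel's depth
#' signal into three dimensions with FastMap, bring the embedding onto
#' the LAB scale, estimate the linear stretch factor k between graph
#' distances and colour differences, and (optionally) refine the map by
#' ICM under the GGMRF prior.
#'
#' The LAB scaling before refinement is isotropic (one common factor,
#' chosen so the first axis spans [0, 100], with the second and third
#' axes centred): it preserves all distance ratios, so the correlation
#' score is unaffected, while putting k and the ICM exploration radius
#' on the LAB scale where their defaults are meaningful. The
#' channel-wise display stretch ([stretchLab()]) is applied afterwards
#' by [gaitAsymmetry()] / [labToRgb()].
#'
#' @param sil A [SilhouetteSequence-class].
#' @param spec A [ShiftDistanceSpec-class] (default shifted L2).
#' @param nS,nCnx Neighbourhood-graph parameters (defaults 13, 11).
#' @param eta,q Refinement energy parameters (defaults 0.025, 1).
#' @param refine Run the ICM refinement (default TRUE).
#' @param radius,sweeps ICM exploration radius and sweep count.
#' @return A list with \code{map} (the [AsymmetryMap-class], on the
#'   isotropic LAB scale) and \code{graph} (the [DistanceGraph-class]
#'   with beta and k). \code{provenance(map)} records k, the correlation
#'   score and, when refined, the energy trace.
#' @export
computeAsymmetryMap <- function(sil, spec = shiftDistanceSpec(),
                                nS = 13L, nCnx = 11L,
                                eta = 0.025, q = 1, refine = TRUE,
                                radius = 1, sweeps = 2L) {
  stopifnot(is(sil, "SilhouetteSequence"))
  shape <- frameSize(sil)
  graph <- buildGraph(shape, nS = nS, nCnx = nCnx)
  graph <- computeDistances(sil, graph, spec)
  X <- fastMap(signalMatrix(sil), p = 3L, spec = spec)
  umap <- .isotropicLab(array(X, dim = c(shape, 3L)))
  umap@provenance$distance <- spec@kind
  graph <- estimateScale(graph, umap)
  umap@provenance$k <- graph@k
  if (refine)
    umap <- icmRefine(umap, graph, eta = eta, q = q, radius = radius,
                      sweeps = sweeps)
  umap@provenance$correlation <- correlationScore(graph, umap)
  list(map = umap, graph = graph)
}

# One common scale for the three FastMap axes: first axis to [0, 100],
# axes 2 and 3 centred; ratios between coordinate differences (hence the
# correlation with beta) are untouched.
.isotropicLab <- function(v) {
  prov <- list()
  rng <- range(v[, , 1L])
  sc <- if (rng[2] > rng[1]) 100 / (rng[2] - rng[1]) else 1
  L <- (v[, , 1L] - rng[1]) * sc
  if (rng[2] == rng[1]) L[] <- 50
  A <- (v[, , 2L] - mean(v[, , 2L])) * sc
  B <- (v[, , 3L] - mean(v[, , 3L])) * sc
  prov$labScale <- sc
  new("AsymmetryMap", values = array(c(L, A, B), dim = dim(v)),
      provenance = prov)
}

#' Full gait-asymmetry analysis of a depth sequence
#'
#' Runs the four stages end to end: silhouette extraction
#' ([extractSilhouette()]), asymmetry-map estimation
#' ([computeAsymmetryMap()]), colour conversion ([stretchLab()] +
#' [labToRgb()]) and ASI quantification ([computeAsi()]).
#'
#' The ASI is computed on the isotropic LAB-scale map -- the scale on
#' which the colour difference between two pixels is the linear image
#' \eqn{k\beta} of their motion asymmetry, which is the contract the
#' index quantifies. The channel-wise display stretch exists to fill the
#' sRGB gamut for visualisation; on data whose residual embedding axes
#' are nearly degenerate it would amplify noise to full amplitude and
#' the index would measure the stretch, not the gait.
#'
#' @param seq A [DepthSequence-class].
#' @param scene A [SceneConfig-class].
#' @param cam A [CameraModel-class].
#' @param spec A [ShiftDistanceSpec-class].
#' @param refine Run the ICM refinement (default TRUE).
#' @param eta,q,radius,sweeps Refinement parameters.
#' @param searchHalfwidth Longitudinal-axis search half-width (px).
#' @param medianFilter Apply the 3x3x3 median filter during silhouette
#'   extraction.
#' @return A list with components \code{silhouette}
#'   ([SilhouetteSequence-class]), \code{map} (the
#'   [AsymmetryMap-class] on the isotropic LAB scale), \code{display}
#'   (the channel-stretched map used for rendering), \code{graph}
#'   ([DistanceGraph-class]), \code{rgb} ([RgbImage-class]), \code{asi}
#'   ([AsiResult-class]), \code{correlation} (the mapping score rho).
#' @examples
#' spec <- walkerSpec(lldOffset = 50, lldSide = "left", noiseSd = 5)
#' res <- gaitAsymmetry(generateWalker(spec), walkerScene(spec),
#'                      walkerCamera(spec))
#' res$asi
#' @export
gaitAsymmetry <- function(seq, scene, cam, spec = shiftDistanceSpec(),
                          refine = TRUE, eta = 0.025, q = 1,
                          radius = 1, sweeps = 2L,
                          searchHalfwidth = 10L, medianFilter = TRUE) {
  sil <- extractSilhouette(seq, scene, cam, medianFilter = medianFilter)
  emb <- computeAsymmetryMap(sil, spec = spec, eta = eta, q = q,
                             refine = refine, radius = radius,
                             sweeps = sweeps)
  stretched <- stretchLab(emb$map)
  rgb <- labToRgb(stretched)
  asi <- computeAsi(emb$map, silhouetteMask(sil),
                    searchHalfwidth = searchHalfwidth)
  list(silhouette = sil, map = emb$map, display = stretched,
       graph = emb$graph, rgb = rgb, asi = asi,
       correlation = provenance(emb$map)$correlation)
}
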