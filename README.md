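# gaitmap

Perceptual asymmetry maps for depth-video gait analysis.

Healthy gait is left–right symmetric in the coronal plane *up to half a
gait period*; losing that symmetry is an early, observable marker of
many orthopedic, muscular and neurological conditions. `gaitmap` turns
a depth-video of a subject walking on a treadmill — a stack of 16-bit
depth frames from a consumer structured-light sensor — into a single
colour image in which the perceptual colour difference between mirrored
body parts is linearly related to their motion asymmetry, and distils
it into a scalar **asymmetry index (ASI)** for clinicians and gait
researchers who want a fast, marker-less, quantitative overview of
*where* and *how much* a gait is asymmetric.

## The method in brief

Each pixel of the video is an N-frame depth signal $s(t)$. The
asymmetry between two pixels is a temporally shift-invariant Euclidean
distance

$$\beta_{s_1,s_2} = \min_{\tau \in \{0,\pm6,\dots,\pm66\}}
\Big(\sum_t (s_1(t+\tau)-s_2(t))^2\Big)^{1/2},$$

so limbs moving identically in phase opposition are at distance zero.
After silhouette extraction (3-D bounding-box clipping, image-space
treadmill removal $v < fT_y/d + c_v$, background clipping to the
subject mean, 3×3×3 median filtering), every pixel is embedded into
CIELAB 3-space with FastMap so that
$\lVert u_s - u_t\rVert_2 \approx k\,\beta_{s,t}$, the stretch $k$ is
estimated by least squares on a sparse pixel graph (4-neighbours + 11
long-range links in a 13×13 window), and the map is refined by ICM
under a generalized Gaussian MRF prior
($\Omega(u)=\sum\gamma_{st}|u_s-u_t|^q$, $\eta = 0.025$, $q = 1$).
The ASI curve is the largest mirrored colour difference per row about
the estimated longitudinal body axis; the ASI index is its mean.

A synthetic articulated-walker generator (`generateWalker()`,
`generateCohort()`) reproduces the study conditions — including a
simulated leg-length discrepancy (LLD) via a 5 cm sole — with exact,
provable symmetry properties, so the whole pipeline is testable
without recorded data.

## Worked example

```r
library(gaitmap)

## a 2 s walk at reduced scale, with a 5 cm sole under the left foot
spec <- walkerSpec(lldOffset = 50, lldSide = "left", noiseSd = 5,
                   seed = 7)
seq <- generateWalker(spec)
seq
#> DepthSequence: 60 frames of 64 x 48 px @ 30 fps, depth 2385..4020 mm

res <- gaitAsymmetry(seq, walkerScene(spec), walkerCamera(spec))
res$silhouette
#> SilhouetteSequence: 60 frames of 51 x 19 px @ 30 fps, depth 2398..2651 mm
#>   subject pixels: 47.1% of voxels, clip value: 2508 mm
res$map
#> AsymmetryMap: 51 x 19 px, channels L in [-0.6, 98.5], A in [-7.3, 47.6], B in [-3.8, 15.4]
#>   k = 0.145, correlation rho = 1.000, 2 ICM sweep(s)
res$asi
#> AsiResult: axis column 10, 49 rows, ASI index = 27.01

writeAsymmetryPng(res$rgb, "asymmetry.png")
```

What the numbers mean: the silhouette stage kept the walker and
replaced everything else by the subject's mean depth (2508 mm); the
embedding preserved the shift-invariant distances essentially
perfectly (correlation rho = 1.000 between beta and colour
differences, scale k = 0.145); and the mirrored colour differences
about the axis column average **27.0** LAB units. The same subject
walking without the sole gives ASI **3.5** — the sole raises the index
by an order of magnitude, and the ASI curve localises the difference
to the leg rows:

```r
spec0 <- walkerSpec(noiseSd = 5, seed = 7)   # no LLD
res0 <- gaitAsymmetry(generateWalker(spec0), walkerScene(spec0),
                      walkerCamera(spec0))
asiIndex(res0$asi)
#> [1] 3.53
```

A perfectly symmetric, noiseless walker maps to an exactly symmetric
image: its ASI curve is identically zero.

## Scope

The ASI is a *relative* measure for within-subject comparisons
(condition A vs B, progression, treatment response); it is not an
absolute normal/abnormal classifier. See the methods vignette
(`vignettes/gait-asymmetry-mapping.Rmd`) for the model, parameter
rationale, numerical choices and limitations.
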