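---
title: "Perceptual asymmetry maps for depth-video gait analysis"
author: "gaitmap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual asymmetry maps for depth-video gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmap)
```

## The problem and the model

Healthy human gait is, to good approximation, symmetric in the coronal
(frontal) plane *up to half a gait period*: the left leg repeats what
the right leg did half a cycle earlier. Many orthopedic, muscular and
neurological disorders break this symmetry, which makes gait asymmetry
a useful, non-invasive clinical marker. `gaitmap` implements a method
that turns a depth-video of a subject walking on a treadmill, recorded
by a consumer depth sensor facing the subject, into a *single colour
image* in which the perceptual colour difference between mirrored body
parts is linearly related to their motion asymmetry, plus a scalar
index (ASI) quantifying it.

The data object is the depth cube: each pixel holds a *depth signal*
$s(t)$, its distance to the camera (mm) over the $N$ frames of the
analysis window. The method has four stages.

**1. Silhouette extraction.** The sensor is a pinhole camera
$u = fX/Z + c_u$, $v = fY/Z + c_v$ (pixels; world Y points down, units
mm). A 3-D box around the subject is projected into the image once
(`computeBounds()`), giving a pixel window and depth limits
$[Z_{min}, Z_{max}]$ outside of which pixels are non-subject. The
treadmill, always *below* the subject in the world, is removed
directly in image space: a pixel at row $v$ with depth $d$ survives
only if $v < f\,T_y/d + c_v$, the image form of $Y < T_y$
(`removeTreadmill()`). Non-subject pixels are then clipped to the
rounded mean depth of all subject pixels over the whole sequence
(`smartClip()`): a background close to the subject's own depth range
creates no large artificial pairwise distances that would squeeze the
informative ones in the embedding, and keeps the image histogram
unimodal. Finally a $3\times3\times3$ spatio-temporal median filter
removes single-voxel aberrations (`medianFilter3d()`).

**2. Shift-invariant distances.** The asymmetry between two pixels is
the temporally shift-invariant Euclidean distance between their
signals,
$$\beta_{s_1,s_2} \;=\; \min_{\tau} \Big(\sum_t
  \big(s_1(t+\tau) - s_2(t)\big)^2\Big)^{1/2},$$
with circular shifts $\tau \in \{0, \pm 6, \dots, \pm 66\}$ frames
(about one gait cycle at 30 fps; step 6 $\approx$ 0.2 s keeps the
search cheap; the negative shifts make $\beta$ symmetric). Two pixels
executing the same movement in phase opposition -- the two legs of a
symmetric walk -- are at distance (near) zero. `shiftDistance()` also
provides the L1 and L$\infty$ shifted norms and three shift-free
alternatives (Fourier amplitude spectra `Lmod`, amplitude histograms
`Lrad`, signal means `Lmoy`) for comparison; the latter two are blind
to asymmetries that preserve the value distribution or the mean, which
is why the shifted L2 is the default.

**3. Embedding.** Every pixel is mapped to a 3-vector
$u = (L, A, B)$ in CIELAB space -- approximately perceptually uniform,
so equal colour differences read as equal asymmetries -- such that
$\|u_s - u_t\| \approx k\,\beta_{s,t}$. Distances are preserved with
FastMap (`fastMap()`): axes are built one at a time from a distant
pivot pair found by farthest-point hops, each point is projected by
the cosine law, and the construction recurses on residual distances;
cost is $O(pN)$ distance evaluations instead of the $O(N^3)$ of
classical MDS. The scale factor $k$ minimising
$\sum (k\beta - \|u_s-u_t\|)^2$ over a sparse pixel graph is found in
closed form and snapped to the grid $k \in [0,1]$, step 0.005
(`estimateScale()`). The embedding is then refined by iterated
conditional modes (`icmRefine()`) on the penalised cost
$$E(u) = \sum_{(s,t)} \big(\beta^{scaled}_{s,t} -
  \|u_s - u_t\|\big)^2 + \eta \sum_{\langle s,t\rangle}
  \gamma_{st}\,|u_s - u_t|^q ,$$
whose second term is a generalized Gaussian Markov random field prior
over the 8-neighbour cliques ($\gamma = (2\sqrt2+4)^{-1}$ for
horizontal/vertical, $(4+4\sqrt2)^{-1}$ for diagonal cliques;
$q \in [1,2]$, default 1, the edge-preserving absolute-value
potential). The fit term runs over a sparse graph: every pixel linked
to its 4 neighbours plus $N_{cnx} = 11$ equally spaced *other* pixels
in a $13 \times 13$ window -- long-range context at linear cost. ICM
sweeps the pixels in raster order, tries the 27 candidates
$u_s + \{-r, 0, +r\}^3$ and keeps the best; each accepted move
strictly lowers $E$, so the energy trace is non-increasing by
construction.

**4. Colour conversion and ASI.** For display, the channels are
affinely stretched ($L \to [0,100]$; $A, B$ zero-mean, max amplitude
100) and converted to 8-bit sRGB under D65 (`stretchLab()`,
`labToRgb()`; out-of-gamut pixels are clamped and counted). For
quantification, the longitudinal body axis is estimated as the column
(within $\pm 10$ px of the image centre) about which the per-row
silhouette contour distances are most symmetric in the median sense
(`estimateAxis()`); the *ASI curve* records, per row, the largest
colour difference between pixels mirrored about that axis, and the
*ASI index* is the curve mean (`computeAsi()`). Cohort-level questions
("does a simulated leg-length discrepancy raise the ASI?") use paired
two-sided t tests (`pairedComparison()`).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tauMax`, `tauStep` | 66, 6 | frames | shift search grid, about one gait cycle sampled every 0.2 s |
| `nS`, `nCnx` | 13, 11 | px, links | sparse graph: window size and long-range links per pixel |
| `eta` | 0.025 | -- | weight of the GGMRF prior in the refinement energy |
| `q` | 1 | -- | GGMRF exponent; 1 = edge-preserving, 2 = Gaussian smoothing |
| `radius`, `sweeps` | 1, 2 | LAB units, -- | ICM exploration radius and sweep budget |
| `kGridStep` | 0.005 | -- | snap grid for the stretch factor $k \in [0,1]$ |
| `searchHalfwidth` | 10 | px | longitudinal-axis search range about the centre line |

`eta` is the one genuinely free model parameter; it trades distance
fidelity against spatial smoothness and is held fixed across all
analyses. The graph parameters are not sensitive: more links improve
convergence at linear extra cost. All defaults are collected in
`gaitmapDefaults()` and asserted by the test suite.

## Where the embedding lives: one scale, two stretches

The printed operating point only makes sense if the embedding is on
the LAB scale when $k$ and the ICM radius apply: raw depth-signal
distances are $O(10^3)$ mm while LAB spans $O(10^2)$, so
$k \approx 0.05$--$0.2$ (well inside the $[0,1]$ grid) and an
exploration radius of 1 is a meaningful perceptual step. The pipeline
therefore rescales the raw FastMap coordinates *isotropically* (first
axis to $[0, 100]$, the others centred, one common factor) before
estimating $k$ and refining. An isotropic map preserves every distance
ratio, so the correlation between $\beta$ and colour differences is
untouched.

The channel-wise display stretch ($A, B$ to amplitude 100) is applied
only afterwards, for rendering. It is deliberately anisotropic -- it
fills the sRGB gamut -- and on data whose residual embedding axes are
nearly degenerate it amplifies whatever lives there, including noise,
to full amplitude. For that reason the ASI is computed on the
*isotropic* map, where $\|u_s - u_t\| \approx k\beta_{s,t}$ is the
linearity contract the index is meant to quantify. On the synthetic
walker (whose shift-invariant distance structure is genuinely
low-dimensional, see below) this distinction matters a great deal; on
rich real recordings the residual axes carry real variance and the two
choices differ less.

## The synthetic walker

`generateWalker()` renders the study conditions without any recorded
data: a far background (4000 mm), a treadmill slab across the bottom
rows, a static head and torso at 2500 mm, and arm/leg rectangles whose
depth oscillates sinusoidally (legs $\pm$100 mm, arms half that) with
exactly half a period of phase offset between sides. The right-side
waveform is the left-side integer phase table evaluated at
$t + P/2$, so for a noiseless, LLD-free walker the frame mirrored
about the body midline *equals* the frame shifted by half a period,
bit for bit -- the symmetry premise is exact, not approximate. A
leg-length discrepancy is simulated as a constant depth offset on one
leg's trajectory (default 50 mm, the height of the sole used in the
LLD experiments this emulates), optionally with a leg-length change in
pixels. Sensor noise is i.i.d. Gaussian depth noise, rounded to
integer mm (default $\sigma = 5$ mm, a realistic figure for a
structured-light sensor at 2.5 m).

Two generator choices deserve explanation:

* **Gait period 20 frames (0.67 s at 30 fps).** The shift grid is
  fixed at step 6 by the method. If the half period falls maximally
  between grid points (as with $P = 30$: $P/2 = 15$, 3 frames from the
  nearest reachable phase), the best shift misaligns the legs by a
  tenth of a cycle and the map is dominated by *grid aliasing* rather
  than gait asymmetry. Over a long window the grid effectively
  resolves most real cycle lengths; in the short 60-frame test window,
  $P = 20$ (with $30 \bmod 20 = 10 = P/2$ on the grid, and whole
  cycles in the window) reproduces that regime, so the study condition
  probes asymmetry detection, not aliasing. The cadence is a brisk
  treadmill walk.
* **Degenerate residual structure is a feature to know about.** Under
  a shift-invariant distance, all phase-shifted copies of one waveform
  collapse; the walker's signal classes (constant, leg wave, arm wave)
  form an essentially low-dimensional configuration, so FastMap's
  second and third axes carry little genuine variance. Real bodies
  produce richer signal families. Consequences for what the tests can
  and cannot show are listed under limitations.

`generateCohort()` draws per-subject geometry (torso depth 2350--2650
mm, limb amplitude 80--120 mm, uniform) and renders three sequences
per subject -- normal, left-LLD, right-LLD -- sharing that geometry,
reproducing the within-subject A/B/C design of a sole-under-one-foot
experiment.

## Numerical choices

* **Distance exactness.** Depth values are integer mm; squared
  differences and their sums stay below $2^{53}$, so shifted-L2
  distances are computed exactly in double arithmetic (the dot-product
  expansion used for speed is exact for integer operands). This is why
  the mirror-null test can demand *identically zero*.
* **Median filter.** Implemented as a vectorised binary search on the
  integer value range -- exact 14th order statistic of 27 values.
  Spatial borders replicate the nearest edge (no artificial background
  values); the temporal border wraps circularly, consistent with the
  periodicity the shifted distance already assumes. Replicating end
  frames instead measurably distorts the signals at the window ends,
  and the distance then reads that as spurious motion asymmetry.
* **FastMap determinism.** Pivots come from 5 farthest-point hops with
  ties broken towards the lowest pixel index; residual squared
  distances are floored at zero; a zero-distance pivot pair leaves the
  remaining axes at zero (all-equal inputs map to the origin). No
  randomness anywhere in the default pipeline; the optional ICM
  candidate-order shuffle is off by default.
* **ICM.** Candidates are scored on the local energy (incident graph
  edges plus incident prior cliques); a move is accepted only if it
  strictly lowers it, which provably never increases the global
  energy. Two raster sweeps are the default budget -- the starting
  point is already a good embedding, and the refinement's role is
  regularisation, not search. The sweep loop stops early if nothing
  moves.
* **Degenerate inputs.** All-zero $\beta$: $k = 0$ by convention.
  Constant L channel after stretching: set to 50. Constant A or B:
  set to 0. Identical paired groups: $t = 0$, flagged degenerate;
  identical nonzero differences: $t = \pm\infty$, flagged.
* **Axis ties.** Candidates with equal median mismatch resolve to the
  column closest to the centre line, then to the smallest index.

## Problem sizes

The test suite and the acceptance script run the walker at
$48 \times 64$ px and 60 frames (about 800--1200 silhouette pixels,
6000--7000 graph edges), the scale at which the whole pipeline takes
about a second; the cohort analyses use 10 subjects $\times$ 3
conditions. The generator scales to the full $640 \times 480 \times
300$ sensor format with the same code.

## Limitations

* The walker is a flat articulated cartoon: no limb self-occlusion, no
  out-of-plane rotation, no clothing texture, no structured-light
  dropout patterns (invalid-0 pixels are supported by the container
  and the masking, but the generator does not emit them). Passing
  tests show the *method* behaves as specified, not that a clinical
  deployment is validated.
* Because the walker's residual distance structure is low-dimensional,
  the display stretch is exercised in its least favourable regime; the
  rendered PNG of a near-symmetric walker shows amplified residual
  noise even though the quantitative index correctly reads near zero.
* The ASI is a relative measure. It supports within-subject
  comparisons across conditions or time; it is not an absolute
  normal/abnormal classifier, and no threshold for such use is
  provided.
* Sequences are analysed as circularly periodic. Windows holding a
  non-integer number of gait cycles leak a small spurious distance at
  the wrap; with a few cycles per window the effect is minor, and the
  acceptance analyses use whole-cycle windows.
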