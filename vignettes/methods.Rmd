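---
title: "Methods: from vascular images to drug-release maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from vascular images to drug-release maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasq)
```

`vasq` quantifies spatiotemporal drug release in perfusable vascularized
tissue models from two image channels: bright-field (drug absorbance
darkens the vessel lumen) and fluorescence (the drug's emission marks
extravascular spread). This vignette explains the models behind each
stage, the parameters that matter, what the synthetic phantom does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The photometric model

Light crossing a drug-filled vessel of diameter $d$ (the optical path) at
concentration $c$ is attenuated relative to the background grayscale
$G_B$:

$$A \equiv \log_{10}\frac{G_B}{G} = \varepsilon\,\log_{10}(c\,d) + k,$$

an empirical form modified from the Beer–Lambert law: $\varepsilon$ is
the light-attenuation coefficient and $k$ an attenuation-independent
offset (scattering and other losses). `fitCalibration()` estimates both
by ordinary least squares on calibration samples spanning channel sizes
of 50–1000 µm and concentrations of 0.625–20 mg/mL, which is the regime
in which the linear form holds; the default $\varepsilon = 0.249$ is the
experimentally obtained value for doxorubicin. Units matter only through
the product $c\,d$: the calibration and any later use must share them.

For mapping, the model is used in ratio form between a *target* edge and
the *source* edges (the first edges extending from the Root, whose
concentration is taken to equal the injected $c_0$ at time zero):

$$\log_{10}\frac{G_t}{G_s} =
  \varepsilon\left[\log_{10}\frac{c_s}{c_t} +
                   \log_{10}\frac{d_s}{d_t}\right],$$

solved per edge as
$c_t = c_s\,(d_s/d_t)\,(G_s/G_t)^{1/\varepsilon}$. Two consequences
shape the implementation:

* $k$ cancels, so the base of the logarithm is irrelevant here; base 10
  is fixed throughout so that a reported $k$ is well-defined.
* the bracket must multiply *both* logarithmic terms — this is forced by
  deriving the ratio form from the absolute law; any other reading fails
  the round-trip consistency checks in the test suite.

Edge-level quantities enter as means: $G_t$ is the mean grayscale over
the edge's skeleton path, $d_t$ the edge's mean diameter. Near a
junction the centerline of a branch runs *inside the lumen of its wider
neighbour* for up to $r/\sin\theta$ pixels ($r$ the neighbour's radius,
$\theta$ the branching angle), where the darker neighbour would
contaminate the average; such pixels are excluded by a geometric test
against every neighbouring edge's tube before averaging. Without this
exclusion the concentration error on second-generation branches is
several percent; with it, noise-free phantoms round-trip below 0.5%.

Quantification is restricted to levels P1–P2 by default (`maxLevel`):
distal vessels are a few pixels wide and their grayscale is dominated by
partial-volume and noise effects. Values are clipped to
$[0, 2c_0]$ with clip events flagged rather than silently truncated.
For a time series, later frames reuse the time-zero source photometry
(`reference` argument), so residual concentration is expressed relative
to the injected state.

## Segmentation

The primary segmenter is a dual-attention U-Net generator trained
adversarially (DAU-GAN). The architecture follows the conventional
U-Net progression — Conv Blocks of convolution–BatchNorm–ReLU, MaxPool
downsampling, transposed-convolution upsampling, skip connections — with
a dual-attention block on every skip path: a channel branch (global
average pooling, a bottleneck of ratio `attentionReduction`, a sigmoid
gate per channel) and a spatial branch (channel-mean map, a 3×3
convolution, a sigmoid gate per pixel), fused by addition. The output
layer is a 1×1 convolution and sigmoid, so predictions are per-pixel
probabilities and the raster shape is preserved. The discriminator is a
stack of Conv Blocks over the (image, label-map) pair with global
average pooling.

The generator objective is per-pixel binary cross-entropy plus
$\lambda$ times the adversarial loss ($\lambda = 0.1$ by default; at
$\lambda = 0$ training reduces to a plain segmentation network and the
log carries no adversarial column). Channel widths default to
64–128–256–512; the width-doubling convention is enforced. Because no
deep-learning framework is assumed, forward passes, backpropagation
(verified against finite differences in the test suite) and Adam are
implemented directly on im2col/col2im kernels. With batch size one,
BatchNorm uses per-image statistics at training and prediction alike.
Two architectural simplifications are deliberate: convolution biases
inside Conv Blocks are omitted (the following BatchNorm absorbs any
per-channel offset exactly, so their gradient is identically zero), and
so is the transposed-convolution bias.

Augmentation emits horizontal/vertical flips and rotations at every 4°
starting at 4° and stopping short of 360° — 89 distinct angles, the 4°
endpoint read as included — plus contrast/brightness jitter applied to
the image only; masks are resampled nearest-neighbour so they stay
binary, and rotation corners are filled with the background median so
they do not mimic vessels. For desk-scale experiments (reduced widths
8–16–32, 128×128 patches) the learning rate is raised to $10^{-3}$;
small networks on small patch sets tolerate and need the larger steps,
while the full-width default keeps the conventional $10^{-4}$.

The classical fallback — adaptive mean thresholding (window clamped to
the image), morphological opening, hole filling, largest-component
retention — requires no training and anchors comparisons. Hole filling
is load-bearing: a noise pinhole in a mask becomes a skeleton ring and a
graph cycle downstream. On full phantom frames with flat background the
fallback is excellent (DSC ≈ 0.999); on mostly-vessel patches, where the
threshold window lacks background reference, it degrades sharply
(DSC ≈ 0.7–0.9) while the trained network stays above 0.99 — the regime
that motivates learned segmentation on real, unevenly illuminated
images.

## Skeleton and topology

Thinning alternates two directional subiterations (north-west corner /
south-east boundary, then the converse), realized with the standard
two-pass deletion conditions on the 8-neighbourhood. Within a
subiteration, candidates are collected in parallel but deleted
sequentially with conditions re-checked on the updating raster, which
preserves the 8-connected component count (endpoints are never deleted).
Two artefact classes survive the directional rules and are cleaned at
the fixpoint: staircase corner pixels (degree 2 with mutually adjacent
neighbours) are redundant and removed; residual fully-set 2×2 blocks —
which arise when the raster is pinched between adjacent background
holes — lose one non-endpoint member, chosen so the global foreground
component count is unchanged (merging two background holes is
acceptable; splitting foreground is not). The result is idempotent.
Spurs shorter than 5 px (configurable) are pruned before graph building.

Graph construction types skeleton pixels by 8-neighbour count (1 leaf,
≥ 3 bifurcation), merges adjacent bifurcation pixels into one node at
the member pixel nearest the cluster centroid, and traces degree-2
chains into edges carrying their ordered pixel path, pixel-count length,
and mean diameter. Diameter at a skeleton pixel is $2d_{bg} - 1$, twice
the Euclidean distance to the nearest background pixel minus one — exact
for ideal odd-width bands under pixel-center geometry, which is why the
−1 is there. Cycles are rejected with an explicit error (portal trees
are assumed acyclic; anastomoses are out of scope), disconnected
skeletons reduce to the largest component with a warning (optionally,
fragments can be kept and swept into level P5).

The Root — the first main bifurcation, used so that longitudinal frames
of the same specimen classify consistently — is detected among the three
bifurcations with the largest node diameters (max incident edge
diameter) as the one farthest from the image border (Chebyshev
distance), ties broken by diameter then row-major order. One addition
proved necessary: the root-incident edge whose far endpoint is a leaf on
the image border is treated as the *inlet* (the injection vessel
upstream of the Root). It is excluded from the main branches and from
the Eq.-ratio source set — averaging the thick inlet with the thinner
main branches would bias $G_s$ and $d_s$ jointly and breaks the
concentration round trip by ~10% — and is itself assigned level P1.

Level classification peels farthest-leaf paths: from the Root, each main
branch claims the shortest-path-farthest leaf reachable through it
(Dijkstra, weights = pixel-count lengths) and the path becomes P1;
bifurcations on P1 paths seed P2 from their remaining branches, and so
on; everything beyond level 5 is recorded as P5. Distance ties break to
the smaller leaf node id — the phantom's independent truth-level oracle
implements the same tie-break, so agreement is exact, not approximate.

## Extravascular diffusion

Profiles are cast perpendicular to the local vessel direction (principal
axis of skeleton pixels near the anchor; a mask window would be
isotropic inside wide vessels). Sampling is bilinear at quarter-pixel
steps; the wall is the interpolated 0.5-crossing of the mask along the
ray, refined by bisection. The wall-adjacent grayscale $G_0$ is the mean
of the first three samples outside the wall — an averaging window is
needed on noisy data, and at 0.25 px steps it sits ~2.5 µm out, a bias
well under one pixel pitch. $D(n\%)$ is the largest distance at which
the 3-sample-smoothed profile still reaches $n\%$ of $G_0$, linearly
interpolated at the crossing; taking the *largest* crossing makes the
estimate robust to noise dips, and monotonicity in $n$ is structural.
Profiles that never fall below threshold return the ray length flagged
censored. Locations are labelled L1–L4 by local vessel diameter
(800–1000, 600–800, 400–600, 200–400 µm).

Coverage takes background-corrected fluorescence (pre-injection frame
when available, else the modal grayscale), calls every pixel with
corrected grayscale ≥ 1 signal, and splits it by the vessel mask into
intra- and extravascular areas; overlays record the earliest and latest
time point at which each pixel carried signal. The IVIVC is an ordinary
least-squares fit of in vivo concentration ratios $C_n/C_0$ on in vitro
fluorescence ratios $G_n/G_0$ across matched depths and times; in vivo
ratios are user-supplied (they come from clinical explant measurements,
not from images).

## The phantom: what it emulates, and what it does not

`generatePhantom()` grows a branching tree from an inlet stub at the
left border: children leave each bifurcation at physiologic opening
angles (18–32° off the parent axis, alternating sides), per-generation
diameters taper from 900 µm at the trunk through 400, 100, 64 to
55 ± 7 µm at the fifth generation, and branches shorten when they
approach the canvas margin, as vessels do toward the organ boundary. At
the default 10 µm/px pitch a 1024² canvas spans ~1 cm — a
stereomicroscope field in which both the trunk (90 px wide) and the
distal twigs (5–6 px) rasterize. The trunk is long enough (5000 µm) that
the first bifurcation sits interior to the frame, as in a micrograph
framed on the injected lobe; this is also what makes the farthest-from-
border root heuristic identifiable. The two first-generation main
branches are twin-like (400 ± 12 µm): they are anatomical twins, and the
ratio model's arithmetic source averaging assumes near-interchangeable
source edges — with a wide spread the averaging itself, not the
algorithm, caps round-trip accuracy (the error grows as the squared
relative spread, amplified by $1/\varepsilon$).

The bright-field channel renders each tube at the grayscale the forward
attenuation law prescribes (darkest tube wins where lumens overlap at
junctions) plus optional Gaussian noise; concentration decays by a fixed
factor (default 0.8) at each bifurcation downstream of the source edges,
so the source generation carries $c_0$ exactly as the ratio model
assumes at time zero. The fluorescent channel is a plateau inside the
vessel plus an exponential halo $G(x) = G_{wall}\,e^{-x/\lambda}$ in the
*analytic* distance $x$ to the tube surface — chosen because it gives a
closed-form $D(n\%) = \lambda \ln(100/n)$ against which the profiler is
validated to within one pixel pitch. Ground-truth levels are computed by
an independent recursive peeling on the exact generated tree (closed-
form Chebyshev pixel-count lengths, no raster, no Dijkstra), so the
classifier is checked against a second implementation, not against
itself. Pixels are stored as doubles in [0, 255]: quantisation to 8 bits
happens only at file I/O, because rounding an edge's uniform rendered
value by up to 0.5 gray is amplified by $1/\varepsilon \approx 4$ into a
multi-percent concentration error that would mask real defects.

What the phantom does **not** emulate: uneven illumination, the Tyndall
scattering of oil emulsions, anastomoses/loops, flow-driven
advection–diffusion (the halo is a static closed form, not physics),
out-of-plane (3-D) structure, and drug-eluting beads as discrete
objects. Passing tests therefore demonstrate the *algorithms* are
correct against their models, not that the models capture every property
of real microscopy; on real images the manual-correction layer and the
configurable thresholds are expected to earn their keep.

## Problem sizes and determinism

The shipped suite validates at desk scale: 100 random blob masks for
skeleton properties, 25 noise-free phantoms for exact level agreement,
200 random graphs for shortest-path cross-checks, 10 seeds × 3 decay
lengths for diffusion depths, and a reduced-width (8–16–32) network
trained on 16 augmented 128×128 patches for the segmentation
comparison. Every stochastic component draws from an explicit seed;
`runPipeline()` reruns byte-identically at a fixed seed and records
per-file checksums in its manifest. Known limitations: cyclic vasculature
is rejected rather than analysed; ASSD is undefined (an error) for empty
masks; the ratio model saturates outside the calibration range of
$c\,d$; and level classification below P2 on real noisy skeletons
inherits the segmentation's junction errors — which is precisely why
concentration mapping stops at P2.
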