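# vasq: quantitative mapping of intravascular drug release

`vasq` analyses bright-field and fluorescent microscopy images of
drug-containing vascular networks — the kind acquired when a chemoembolic
agent (an oil/doxorubicin emulsion, drug-eluting beads, or a plain drug
solution) is injected into the portal tree of a transparent, perfusable
decellularized-liver model and followed over days. It reconstructs the
injected vascular tree from images, classifies its branches into
hierarchical levels, and converts image grayscale into local drug
concentration, so that spatiotemporal release can be quantified without
destructive sampling.

The pipeline has four computational stages plus two quantification layers:

1. **Segmentation** — a dual-attention U-Net generator trained
   adversarially against a convolutional discriminator (DAU-GAN), written
   from first principles in this package (im2col convolution kernels,
   hand-derived backpropagation, Adam). A classical fallback
   (adaptive threshold + morphological cleanup) runs with no training.
   Accuracy is scored by the Dice similarity coefficient (DSC) and the
   average symmetric surface distance (ASSD).
2. **Skeletonization** — iterative two-subiteration thinning (alternating
   north-west / south-east directional deletion passes) down to a
   connected, single-pixel-wide centerline.
3. **Topology** — the skeleton becomes a graph of root, bifurcation and
   leaf nodes; the Root (first main bifurcation) is detected as the most
   interior of the three thickest bifurcations; branches are classified
   into levels P1–P5 by iterative farthest-leaf path peeling (Dijkstra
   shortest paths, pixel-count edge lengths), with generations beyond the
   fifth folded into P5. Branch counts, accumulated lengths and
   distance-transform diameters are tabulated per level.
4. **Photometry** — a modified Beer–Lambert law calibrated on microfluidic
   channels,

   A = log10(G_B / G) = ε · log10(c·d) + k,

   with attenuation coefficient ε = 0.249, links grayscale G to the
   concentration–diameter product. Its ratio form

   log10(G_t / G_s) = ε · [log10(c_s/c_t) + log10(d_s/d_t)]

   propagates the known source-edge concentration c_s = c0 to every
   target edge (the offset k cancels), yielding per-edge concentration
   maps over the P1–P2 trunk and residual-drug time courses.

On the fluorescent channel, `vasq` quantifies extravascular spread:
radial intensity profiles perpendicular to the vessel wall, the diffusion
depth D(n%) at which intensity falls to n% of the wall-adjacent level,
drug-coverage areas split into intra- and extravascular components, and a
linear in vitro–in vivo correlation (IVIVC) between image-derived and
clinically measured concentration ratios.

Because the underlying microscopy images are not publicly deposited, the
package ships a **synthetic phantom generator** (`generatePhantom`) that
draws branching trees with level-dependent diameters (down to 55 ± 7 µm),
renders both channels through the forward models above, and returns the
complete ground truth (mask, graph, levels, per-edge concentrations).
Every stage is validated against phantom truth.

## Worked example

```r
library(vasq)

spec <- PhantomSpec(seed = 8, noiseSdGray = 0)   # 1024x1024, 10 um/px
bundle <- generatePhantom(spec)

mask <- classicalSegment(bundle@brightField)
dsc(mask, bundle@truthMask)
#> [1] 0.9999448

skel  <- pruneSpurs(skeletonize(mask))
graph <- classifyLevels(buildGraph(skel, mask))
graph
#> VesselGraph: 32 nodes (14 bifurcations, 17 leaves), 31 edges,
#>   levels P1/P2/P3/P4

cmap <- propagateConcentration(graph, bundle@brightField,
                               CalibrationModel(epsilon = 0.249), c0 = 5)
cmap
#> ConcentrationMap: 21 edges (levels <= 2), c0 = 5.00 mg/mL, 0 clipped
head(cmap@map$c_t, 4)
#> [1] 5.135794 5.008770 4.991946 3.909016
```

The phantom injected 5 mg/mL into the trunk with a 0.8 concentration
decay per bifurcation downstream of the main branches; working purely
from the image, the pipeline recovers the truth (5, 5, 5, 4, ... mg/mL)
to within a few percent — the residual error is raster measurement, and
it drops below 1% when the exact ground-truth graph is used (the
acceptance suite checks exactly that). A full run over a
time series — segmentation through coverage, with per-stage outputs and
a checksummed manifest — is one call:

```r
runPipeline(list(seed = 1, phantom = list(seeds = c(1, 2)), c0 = 5),
            "out/")
```

A thin command-line wrapper is installed at `inst/cli/vasq`
(`vasq phantom|segment|skeleton|topology|run`).

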