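---
title: "Methods: quantifying magnetically aligned fiber composites and spheroid outgrowth"
author: "fibermag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying magnetically aligned fiber composites and spheroid outgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system

Electrospun dextran fiber segments carrying superparamagnetic iron oxide
nanoparticles can be aligned inside an amorphous hydrogel by gelling the
composite between two permanent magnets. The resulting materials pose four
quantification problems that this package addresses end to end:

1. **Magnetostatics** — what flux density does a given two-magnet chamber
   deliver at the sample, and how does it fall off with magnet spacing?
2. **Fiber architecture** — how aligned are the fibers in a fluorescence
   image, how long and thick are they, and how much of the material is
   entangled rather than dispersed?
3. **Cell morphometry** — how strongly do embedded cells (tenocytes are the
   canonical example) co-orient with the fiber axis, and what fraction of
   cells survive encapsulation (Hoechst/PI)?
4. **Spheroid migration** — for epithelial spheroids embedded in the
   composite, which outgrowths stay contiguous multicellular strands and
   which detach as clusters or single cells, how far do cells migrate, and
   how is migration oriented relative to the fiber axis?

Because no public microscopy dataset accompanies this problem, every
analysis stage is validated against a synthetic-scene generator that emits
pixel-exact ground truth. The generator is first-class, tested code, not a
fixture.

# Magnetostatics of the gelation chamber

Each magnet is modeled as a uniformly magnetized cylinder (radius $R$,
length $L$, remanence $B_r$), equivalent to a solenoidal surface current
$K = B_r/\mu_0$. On the symmetry axis, at distance $z$ outside the face,

$$B(z) = \frac{B_r}{2}\left[\frac{z+L}{\sqrt{(z+L)^2+R^2}} -
\frac{z}{\sqrt{z^2+R^2}}\right],$$

which inverts at $z=0$ to the calibration rule
$B_r = 2 B_s \sqrt{L^2+R^2}/L$ for a datasheet surface field $B_s$
(`calibrate_remanence()`). The chamber's default geometry is a 1.905 cm x
3.81 cm N52 cylinder pair with $B_s = 661.9$ mT; the literature that
motivated the package also quotes 669.1 mT in one place — we standardize on
661.9 mT and note the inconsistency here. An attracting pair at spacing $d$
superposes to $B(d/2-z)+B(d/2+z)$ on the gap, symmetric about the midpoint
where the field is smallest (`pair_axial_profile()`).

Off axis, `field_slice()` integrates the current-loop field (complete
elliptic integrals $K$, $E$) over each magnet's sheet with Gauss-Legendre
quadrature; the same quadrature restricted to the axis serves as an
independent oracle for the closed form (they agree to better than
$10^{-6}$ relative). Air is treated as $\mu_r = 1$ with open boundaries —
deliberately simpler than a finite-element model in a bounded air sphere.
Finite-domain truncation strongly suppresses midpoint flux, which is why
published bounded-domain midpoint values cannot be matched exactly by any
open-boundary model; our validation therefore checks the spacing trend,
order of magnitude (within a factor of 2.5), the dipole far-field limit
$B \to B_r R^2 L / (2 z_c^3)$ (with $z_c$ from the magnet *center*), exact
superposition, and mirror symmetry instead. SI units (m, T) are used
internally; user-facing helpers print cm/mT.

# Synthetic scenes and their ground truth

All scenes share one rendering model: objects are drawn with analytic edge
anti-aliasing (per-pixel coverage `clamp(d_edge + 0.5, 0, 1)` from the
exact distance to the shape boundary), blended by maximum, then blurred by
a Gaussian PSF and overlaid with additive Gaussian background noise. The
analytic coverage is mathematically the limit of supersample-and-downsample
rendering and much cheaper; because coverage depends only on the recorded
geometry, rasterizing a truth table reproduces the noise-free support
pixel-exactly — a property the test suite asserts. Poisson shot noise is
not simulated: the validation questions are geometric, and none of the
estimators depend on intensity statistics beyond a threshold. The default
pixel size is 0.5 um/px, making a 2 um fiber 4 px wide (resolvable but
realistic for a 20x objective).

**Orientations** are axial (defined modulo 180 degrees) and are sampled by
angle-doubling: $\varphi \sim \mathrm{vonMises}(2\mu, \kappa)$ on the full
circle, $\theta = \varphi/2$ — the standard construction for orientation
data. The von Mises draw uses the Best-Fisher rejection sampler (no
circular-statistics dependency is available); $\kappa = 0$ reduces to the
uniform circle and very large $\kappa$ to a wrapped normal of width
$1/\sqrt{\kappa}$.

**Fiber fields** (`generate_fiber_image()`): capsules of constant ~2 um
width with lengths from one of two models. The *photomasked* model is a
truncated normal around a prescribed mean (60-120 um is the range such
masks produce). The *unmasked* model reflects uncontrolled vortexing of
fiber mats: a lognormal truncated to 100-550 um whose log-mean is
calibrated by root-finding so the truncated mean is exactly 225 um (shape
`sdlog = 0.5`, chosen to spread mass across the whole support — the source
only constrains mean and range). With `overlap = FALSE` fibers are placed
by rejection sampling with a clearance test between capsule centerlines,
so each connected component is exactly one fiber — the condition under
which skeleton-based length recovery is well-posed.

**Tenocyte scenes**: non-overlapping ellipses (default area 500 um^2,
aspect ratio 4 — an elongated, uniaxial morphology) with axial von Mises
orientations. Overlap is excluded by enclosing each ellipse in its capsule
and testing segment-segment clearance, conservative but cheap.

**Viability scenes**: disks of radius 3.5 um spaced at least one diameter
apart; exactly `round(n * dead_fraction)` nuclei carry PI signal, so the
truth count is integer-exact.

**Spheroid scenes** (`generate_spheroid_scene()`): an elliptical body
(semi-axes ~75-90 x 60-72 um, ~50 crowded body nuclei that may overlap in
projection — realistic and deliberately not used for counting) plus
outgrowths of the three phenotypes: *contiguous strands* (capsules of
width 14 um rooted on the body boundary, 80-130 um long, nuclei spaced
at least one diameter along the path, the first placed 12 um out so a
covering body ROI cannot swallow it), *disconnected clusters* (2-5 nuclei
hex-packed, actin disks of 1.6x the nucleus radius, shifted along the
outgrowth direction until the nearest actin edge sits at the declared gap),
and *disconnected single cells* (one elongated cell, one nucleus). Gaps
default to 15-35 um — far larger than the contiguity tolerance plus ROI
inflation, so class labels are unambiguous by construction. Outgrowth
directions follow an axial von Mises distribution about the alignment axis
with a random choice of axial sense, mimicking a field that biases
migration along an axis without distinguishing its two directions.

`random_spheroid_spec()` exposes `min_direction_sep`: recovery benchmarks
keep directions >= 18 degrees apart so components stay distinct (phenotype
accuracy is then a meaningful matching question); the directional-bias
benchmark leaves the distribution untouched (`min_direction_sep = 0`)
because thinning dense directions would bias the rose-plot fraction that
benchmark exists to validate.

# Fiber architecture metrics

`anisotropy_score()` computes gradients by central differences after a
1 px Gaussian presmooth, keeps pixels whose gradient magnitude exceeds 2%
of the region maximum (the one tunable that materially affects scores),
and averages the nematic tensor of the gradient-normal direction weighted
by gradient energy. The result equals the coherency of the ROI-summed
structure tensor: $A = \lambda_1 - \lambda_2$ of the unit-trace mean
tensor, 0 for isotropic texture, 1 for parallel structures, and the mean
orientation is the leading eigenvector. We chose energy weighting over an
unweighted average of per-pixel unit tensors after measuring both: the
unweighted variant saturates near 0.94 even on noise-free parallel fields
(anti-aliasing skirts and end caps vote with full weight) and collapses to
~0.6 on a single noisy fiber, while the energy-weighted score reaches
~0.98 on parallel fields and stays ~0 on isotropic ones. Known
limitation, reproduced on purpose: the score still depends mildly on
object length through the end-cap fraction (about $\pi w / 2L$), so
short-segment fields score slightly lower at equal alignment — the same
behavior practitioners observe with FibrilTool-style scores.

`orientation_map()` is the per-pixel analog (structure tensor smoothed by
a Gaussian window; hue = orientation, saturation = coherency, value =
intensity via `orientation_rgb()`), matching OrientationJ-style color maps.

`measure_fibers()` thresholds at half the robust (99.9th percentile)
foreground intensity — the width-faithful choice; Otsu, which lands well
below half-max on sparse fiber images and inflates widths by ~50%, is
available as an option and is used elsewhere for cell-scale masks — then
labels components, thins each to a skeleton (Zhang-Suen, compiled),
prunes endpoints three times to remove spurs, and reports length as the
longest geodesic path through the skeleton (double-sweep Dijkstra with
$\sqrt 2$ diagonal steps to *find* the path, plus compensation of the
pruned ends). The reported length is the Euclidean length of the path
polyline subsampled every 5 pixels, not the raw 8-connected chain length:
chain length systematically overestimates oblique segments by up to ~8%
(a classic digitization artifact), while the subsampled polyline tracks
both straight and gently curved fibers to well under 1%. Diameter is
twice the mean distance-map value over skeleton pixels. On a clean
150 x 2 um rod this recovers length within ~1% and diameter within a
pixel-quantization error, and across 500-fiber scenes the mean length
lands within ~1% of truth.

`entanglement_fraction()` operationalizes a qualitative notion: a
component is entangled if its area exceeds `k = 3` single-fiber areas or
its solidity drops below 0.2; the fraction is entangled area over total
fiber area.

# Cell orientation and viability

`segment_cells()` is Otsu + size filter + connected components, with
orientation and aspect ratio from second central moments
(equivalent-ellipse fit). Cells with aspect ratio below `a_min = 1.2`
get `NA` orientation: a stellate, near-round cell has no meaningful axis,
and including arbitrary moment angles for such cells would only add noise.

`orientation_histogram()` uses 10-degree axial bins by default (18 bins
over 180 degrees — the granularity at which such histograms are usually
drawn). FWHM is found by locating the modal bin and walking both ways with
wrap-around at +/-90 degrees, linearly interpolating between bin centers
where counts cross half the peak; if no bin falls below half max the
distribution is flat at this resolution and FWHM is 180 by convention.
Degenerate data (all angles equal) yield exactly one bin width. FWHM is
refused below n = 10 angles, where a histogram mode is meaningless.
`angular_stratification()` reports the 0-30/30-60/60-90 degree band
fractions (axial distance to the alignment axis); they sum to 1 exactly.

`viability()` segments Hoechst nuclei (threshold, distance transform,
watershed) and calls a nucleus PI-positive when its mean PI intensity
exceeds the PI background mean by 3 background standard deviations — the
staining protocol fixes concentrations, not a calling rule, so a robust
z-score rule is used. The watershed split tolerance is `max(0.6 px,
0.08 r)`: we measured the pixelated distance-map saddle between two disks
overlapping ~30% by area at ~1 px and single-disk pixelation wiggle at
~0.5 px, so this value splits genuine pairs without shattering single
nuclei. (A tolerance proportional to the radius alone, e.g. 0.3 r, merges
exactly the overlapping pairs the splitter exists for.)

# Spheroid migration pipeline

The pipeline mirrors a standard invasion-assay workflow: maximum-intensity
projection; per-channel Otsu threshold and size filter (20 um^2 nuclei /
50 um^2 actin); body ROI; outgrowth labeling; nucleus splitting; phenotype
calling; metrics.

**Body ROI.** A user-supplied ellipse is honored verbatim (the assay is
traditionally run with a hand-drawn ROI). Automatically, the actin mask is
first opened with a 10 um disc — implemented as two distance transforms,
cheap at any radius — which removes strand-scale protrusions that would
otherwise skew the fit; the largest remaining component is fitted with its
moment-equivalent ellipse and the semi-axes inflated 5% to emulate a
covering hand-drawn ROI. On synthetic scenes the pre-inflation fit is
accurate to a fraction of a percent; the deliberate 5% inflation is the
dominant (and conservative) bias in all distance metrics, shaving ~4% off
depths measured from the boundary.

**Contiguity.** After subtracting the ellipse interior, 8-connected
components are outgrowths; one is contiguous if any pixel lies within
`r_c = 2 px` of the ellipse (bridging hairline segmentation gaps without
merging genuinely detached objects; configurable).

**Nuclei.** The same watershed splitter as viability; centroids inside the
ellipse are body nuclei and never count as migratory. Centroids outside
are assigned to the outgrowth whose mask contains them, falling back to
the nearest mask within 15 um, ambiguity resolved toward the nearer mask.
Detected nuclei always partition exactly into body + per-outgrowth sets
(asserted in tests).

**Phenotypes** follow the contiguity rule: contiguous = strand;
disconnected with one nucleus = single, with several = cluster.

**Metrics.** Per-nucleus migration distance is the Euclidean distance from
the centroid to the nearest point of the body ellipse — the spheroid
periphery, not its centroid — solved by vectorized bisection on the
standard ellipse nearest-point equation (60 iterations, far below pixel
resolution). Maximal invasion depth of an outgrowth is the maximum of that
distance over its mask pixels. Totals are stratified by contiguity.
Euclidean depth from the periphery (rather than a skeleton path length
within the outgrowth) is used for migration distance: it is well-defined
for all three phenotypes and is the quantity a depth-from-boundary
readout measures.

**Population aggregation.** Binarized actin masks are translated (never
rotated — all spheroids share the magnet axis) so body centers coincide,
then summed into an occupancy heatmap; the rose histogram bins the polar
angle of every migratory nucleus about its body center in 10-degree bins
over the full circle. `rose_axial_fraction()` pools the two axial senses
when comparing against the generator's analytic band probability
$\int_{-30°}^{30°} e^{\kappa\cos 2\theta}\,d\theta \big/
\int_{-90°}^{90°} e^{\kappa\cos 2\theta}\,d\theta$.

# Validation design

`benchmark_*()` functions freeze the reference study conditions:

- **Anisotropy ladder**: kappa in {0, 1, 2, 4, 8, 1e6}, five seeded scenes
  each, 500 unmasked-length fibers per 1400^2 px scene (the alignment
  experiments this mirrors used full-length fibers; long fibers also
  minimize the end-cap effect). Mean scores must increase strictly with
  kappa, <= 0.05 at kappa 0 and >= 0.95 at kappa 1e6.
- **Length recovery**: masked means 60/90/120 um and the unmasked model,
  >= 500 non-overlapping fibers each, recovered within 10%.
- **FWHM ladder**: kappa in {0.5, 1, 2, 4, 8}, five 80-cell scenes each
  (1024^2 px), measured through the full segmentation; mean FWHM strictly
  decreasing, and at kappa 4 within one bin of the analytic half-max
  width of the axial von Mises density.
- **Migration recovery**: 25 scenes per condition (a mixed condition with
  3 strands + 2 clusters + 3 singles, and a collective condition with
  4 strands only); migratory-cell counts within 10%, summed migration
  distance within 15%, phenotype agreement >= 90%, mean maximal depth
  within 5%, nucleus partition exact; and the disconnected stratum must
  order the two conditions correctly in >= 95% of paired seeds.
- **Directional bias**: 25 uniform scenes (rose fraction within 3 standard
  errors of 1/3) and 25 kappa = 6 scenes (fraction >= 60% and within 3
  standard errors of the analytic band probability, ~0.98).

What passing these does and does not show: the generator emulates
geometry, blur and background noise, but not optical sectioning,
photobleaching, intensity heterogeneity, cell shape irregularity, or
touching *cells* (as opposed to touching nuclei); accuracy numbers here
are upper bounds on what the same pipeline achieves on real micrographs,
and thresholds (Otsu, the 3-sigma PI rule, the 2% gradient floor) are the
components most sensitive to that gap.

Problem sizes throughout (scene counts, fibers per scene, 1024-1400 px
canvases) were chosen as the smallest at which the statistical criteria
above are well-powered; the full validation suite runs in minutes on one
core.

# Reproducibility and conventions

Images are `[row, col]` matrices, origin top-left; exported coordinates
are 0-based pixels with y downward; angles are degrees from +x toward +y;
distances and areas are um and um^2 (magnetics is SI). Every generator
takes an explicit seed and restores the caller's RNG state; identical
spec + seed is bit-identical output, which the suite asserts. Analysis
outputs carry `#`-comment headers with the seed and a config hash;
`run_config()` writes a JSON manifest (config echo, seed, hash, package
and R versions, timing) beside its outputs. `scripts/acceptance.R`
recomputes the three headline round-trip quantities (calibrated surface
field; mean recovered fiber diameter; mean recovered unmasked fiber
length) from scratch at any seed.

# Known limitations

- 2D only: all analysis operates on projections; depths are in-plane.
- The open-boundary magnet model intentionally does not reproduce
  bounded-domain finite-element midpoint values (trend and order of
  magnitude only).
- `measure_fibers()` assumes segments are mostly resolvable; in heavily
  entangled fields lengths of merged components are reported per
  component (flag them via `entanglement_fraction()`).
- The anisotropy score inherits the object-length dependence discussed
  above; compare scores only between fields of similar fiber length.
- Proliferation, time-lapse speeds and EMT readouts are out of scope.
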