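---
title: "Quantifying nuclear shape and lamina mislocalization: models, parameters and design decisions"
author: "nucmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear shape and lamina mislocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nucmorph` automates a scoring protocol for nuclear abnormalities in
laminopathy models: myogenic cells carrying *LMNA* mutations develop
deformed, blebbed, stringy or abnormally elongated nuclei and mislocalized
lamina proteins, and these phenotypes are classically quantified by hand
from confocal images. This vignette records the models the package
implements, the parameters that matter, what the synthetic phantoms do and
do not establish, and the design decisions taken where the protocol left
the design open.

## The contour ratio and its estimator

The central statistic is the nuclear contour ratio

$$\mathrm{CR} = \frac{4\pi A}{P^2},$$

which is 1 for a perfect circle and decreases as the outline deviates from
circularity. Control (circular/oval) nuclei typically span 1–0.79; that
band is used for reporting and QC only, never as a classification rule —
it describes controls, it does not define them.

The ratio is anchored at "circle = 1", which makes the perimeter estimator
the critical numerical choice. Counting exposed pixel edges overestimates
a disc's perimeter by a factor ~4/π (+27%), biasing CR low by ~38%;
chain-code tracing biases it low by ~5% at typical nucleus sizes. The
package instead traces the 0.5 iso-contour of the Gaussian-smoothed binary
mask (marching squares, smoothing scale σ = 1.5 px) and sums the polygon
length. On rasterized discs and ellipses spanning 50–400 px this estimator
is within 0.1–0.5% of the closed forms (2πr and Ramanujan's approximation),
which is what lets the acceptance anchors — disc = 1 within 1%, 30 × 15 μm
oval ≈ 0.84 — hold without shape-specific calibration. The area is the
pixel count times the pixel area; at nucleus scales (≥ 40 px across) the
two definitions agree with a fully polygon-based oracle to better than 1%,
and CR can exceed 1 by up to ~0.02 on small discs (the documented
discretization allowance).

Masks too thin to support the 0.5 level after smoothing (e.g. a 1-px line)
fall back to exposed-edge length so degenerate inputs stay finite; the
classifier labels such masks `severely_deformed` with a warning rather
than failing.

## Segmentation

The DNA channel is smoothed (σ = 1 px), thresholded by Otsu's method,
hole-filled, and labelled with 4-connectivity (6-connectivity in 3D).
Components larger than `split_min_area_um2` (280 μm², larger than any
single nucleus at the default geometry) are candidates for a
distance-transform watershed split seeded from distance maxima; smaller
components are deliberately left whole, because deeply bitten single
nuclei can present two distance peaks and must not be cut in half. Masks
touching the field border are measured but flagged and excluded from all
statistics: a truncated perimeter corrupts the contour ratio, and the
scoring protocol is silent on such nuclei. The recipe is a policy, not a
contribution — any recipe passing the phantom contract (one mask per
nucleus, Jaccard ≥ 0.95, noise-free) is acceptable.

The 2D major axis is the maximum Feret diameter of the sub-pixel contour.
In 3D it is the extent of the voxel cloud along the leading principal axis
of the coordinate covariance — within ~2% of the true 3D Feret on
ellipsoids and far cheaper; the same 25 μm threshold is applied in 2D and
3D (the 3D analysis explicitly reuses the 2D criteria).

## Shape classification

Five independent labels; the empty set is a normal nucleus, and a nucleus
may carry several labels (tallies may sum past 100% — the double-counting
convention of the field's reports). Only the elongation rule is
quantitative in the original protocol:

* **elongated** — major axis strictly greater than 25 μm.

The other four operators are surrogates for by-eye scoring, calibrated on
the phantom generator and all exposed in `classifier_config()`:

* **Protrusions** (blebs, strings). A morphological opening with a 1.7 μm
  disc separates protrusions from the body. Each removed component is
  described by its width (twice its maximal inscribed-disc radius) and its
  outward extent beyond the body. Width ≥ 1.3 μm and extent ≥ 1.0 μm is a
  bleb; width ≤ 1.2 μm and extent ≥ 3 μm is a string. The extent floor
  rejects the thin slivers an opening sheds at high-curvature tips of
  elongated nuclei; the string width bound carries a one-pixel allowance
  over the 1 μm generative definition because inscribed-disc widths
  quantize at 0.2 μm/px.
* **Concavities** (jellybean, severely deformed). Deep convexity defects —
  connected components of (convex hull minus mask) with depth ≥ 1 μm and
  area ≥ 1.5 μm² — are censused on the mask *minus qualifying protrusions*,
  not on the opened body: opening recedes the boundary around concavities
  and flattens their depth (a 2.3 μm bite measures ~0.8 μm deep after a
  1.9 μm opening), which would blind the classifier. Exactly one defect of
  depth ≥ 1.2 μm is the bend signature of a **jellybean**; two or more
  defects with solidity < 0.95 mark **severely deformed**. The solidity
  bound is looser than a textbook 0.9 because two realistic bites of a
  16 × 11 μm ellipse leave solidity ≈ 0.92.

The threshold-sharpness property — ellipses of 24.9 vs 25.1 μm differ in
the elongated label and nothing else — holds because the contour-based
Feret slightly *under*-measures a rasterized ellipse (tip curvature is
rounded by smoothing), so a true-25.0 μm ellipse never crosses the strict
inequality.

## Localization

All intensity scoring runs on 2D images; nuclei in z-stacks are first
reduced by a mid-nucleus maximum projection. The stated projection
protocol ("a 3.5 μm stack ... 6 slices of 1 μm with 0.7 μm overlap") is
internally inconsistent — six slices at 0.3 μm step span 2.5 μm — so the
package selects exactly six planes centred on the intensity-weighted
mid-plane, whatever the z-step, and records the planes used.

The **peripheral localization ratio** is the mean intensity over a
peripheral ring divided by the mean over the nucleoplasm (the nucleus
eroded by the ring width). The protocol's two descriptions of this ratio
are mutually inconsistent (Methods say nucleoplasm/periphery; Results
interpret values > 1 as peripheral enrichment); the package follows the
interpretation: **periphery ÷ nucleoplasm, > 1 ⇔ peripheral enrichment**.
The ring width defaults to 1.0 μm, about the lateral confocal resolution
envelope; the ratio is exactly invariant to multiplicative intensity
rescaling but not to additive offsets, so background subtraction is the
caller's responsibility. The erosion is computed from the exact Euclidean
distance transform, so the generator (which paints its rim with the same
partition) and the detector agree pixel-for-pixel — a uniform nucleus
yields exactly 1, and injected rim ratios 0.5–3 are recovered within 5%.

**Honeycomb and foci** (Lamin A/C) are patch detectors on intensities
normalized by the regional median (ring and nucleoplasm separately — a
bright rim must not read as a focus). With the robust MAD floored at 5% of
the median, honeycomb requires ≥ 2 interior patches below
1 − 3·MAD, each ≥ 0.5 μm²; foci require ≥ 1 patch above 1 + 3·MAD of
≥ 0.3 μm². Interior bright patches larger than 4 μm² are treated as
nucleoli and excluded. **Capping** (Lamin B1) unwraps the ring into 5°
angular bins; a contiguous arc ≥ 30° whose mean falls below half the
reference level (the brighter of ring and nucleoplasm medians — so a
fully deleted rim still reads as absent) is a cap, and the absent-bin
fraction is reported. **Emerin foci** reuse the foci branch only; the
emerin signal is too weak for a reliable honeycomb call. Channels are
scored independently; co-occurrence is a reporting question, not a
detection rule.

## Myotube context

A nucleus is a myonucleus iff (1) ≥ 80% of its area lies inside one
marker-positive (MyHC/eMyHC/titin) structure, (2) that structure contains
at least two such nuclei, and (3) the mean marker intensity inside the
nucleus is below 0.5× the mean in the surrounding structure shell
(nuclear exclusion). The 80% and 0.5 constants operationalize criteria
originally applied by eye and are configurable. Structures are Otsu
threshold + connected components with interior holes filled (nuclear
exclusion punches holes in the tubes); a marker-negative field yields zero
structures, and a missing marker channel assigns everything non-myotube
with a warning instead of failing downstream.

## Statistics

Inference never runs on nuclei. Per-nucleus tables are averaged per
experimental repeat — fields weighted by the nuclei they contribute, i.e.
a plain mean over the repeat's nuclei — and the repeat means (n = 3 in the
motivating design) enter the ANOVA. One-way designs use Tukey HSD
(studentized range on the model MSE; verified against `TukeyHSD`).
Two-way designs (line × condition) report Tukey contrasts between lines
within each condition and Sidak-adjusted within-line condition contrasts
(`p' = 1 − (1 − p)^m`, family = lines) — the engine of the 2D-monolayer vs
3D-construct comparison. "Repeat-measures" designs add the repeat as an
additive blocking factor. The protocol's legends say "analysis of
co-variance" while describing designs with no covariate; this is
implemented as analysis of variance. No global FDR layer is added beyond
the per-family Tukey/Sidak adjustments, and α = 0.05 throughout
(configurable).

Calibration of the design itself is simulated at the repeat-summary level
(`simulate_repeat_summaries`), not by re-rendering images: type-I error at
α = 0.05 lands in [0.03, 0.07] over 2,000 null simulations, a 0.08
contour-ratio shift at SD 0.02 and n = 3 is detected with power ≥ 0.8, and
with a +35-percentage-point elongation increase injected into two of four
lines (the scale of the observed 2D→3D contrasts, between-repeat SD 8 pp)
the Sidak contrasts flag exactly the affected lines with sensitivity and
specificity ≥ 0.9.

## The phantom generator: what it states, what a green test means

The generator renders what the scoring protocol describes, with defaults
fixed once as the stated world: 0.2 μm/px (63× confocal scale), normal
nuclei as 16 × 11 μm ellipses (jittered ±8%, safely below the 25 μm rule),
elongated nuclei drawn from 27–34 μm, nucleoplasm at 120 counts with a
1 μm rim at `rim_ratio` times that level, Poisson shot noise at gain 1
plus 2% Gaussian read noise (off in oracle tests). Mislocalization is
injected literally: ≥ 2 signal-free interior holes (honeycomb), bright
0.5 μm peripheral foci, a signal-free angular arc of the Lamin B1 rim
(capping, default 60°), emerin foci. Myotubes are multinucleated
marker-positive bands with marker excluded from member nuclei. Placement
is collision-free with bounded retries ("field too crowded" on failure),
largest-first; everything is reproducible bit-for-bit from (spec, seed),
with per-nucleus RNG substreams and an inverse-CDF label sampler that an
independent implementation replays exactly.

Geometry the protocol never defined is parameterized so that each class is
*unambiguous ground truth*: the jellybean is a bent ellipse thinned ×0.6
and lengthened ×1.15 with a 130–170° arc — at milder bends or full
thickness the banana closes into a nearly convex blob with no concavity to
detect, which would make the class untestable; severe deformation is 2–3
boundary bites of 0.4–0.5 minor-semi-axis radius; blebs are attached discs
of 1.7–2.9 μm placed 0.8 radii outside the boundary; strings are 0.6–0.9 μm
× 3.5–6 μm capsules. In 3D, the 2D mask is extruded with a flattened
super-ellipsoidal profile (exponent 4, z semi-axis 3.5 μm): adherent
nuclei are pancake-like with steep walls, and with round ellipsoidal walls
a six-plane projection smears the rim inward and the 2D/3D ratio agreement
breaks by construction.

A green recovery test therefore establishes that the pipeline inverts
*this* generative model — shapes separable by construction, uniform
staining inside compartments, no point-spread blur, no photobleaching, no
out-of-focus light, no overlapping or border-clipped nuclei, no
chromatic shift. It does not establish scoring accuracy on real stains,
where classes grade into each other and the operators' thresholds would
need calibration against expert labels. The quantitative anchors (CR
closed forms, the 25 μm boundary, ratio recovery, the statistical design's
error rates) are generator-independent.

## Numerical choices and degenerate inputs

* Smoothing scale σ = 1.5 px for contours (bias-minimal across 50–400 px
  shapes); σ = 1 px before Otsu.
* Exact Euclidean distance transforms (Felzenszwalb–Huttenlocher, with
  anisotropic spacing in 3D) back all erosions/dilations/ring partitions.
* Watershed floods from distance-maxima markers with FIFO tie-breaking,
  so labellings are deterministic.
* Empty masks error; single-pixel and 1-px-wide masks measure finite
  perimeters via the edge-length fallback; a nucleus too small for the
  ring width raises "nucleus too small" rather than returning a ratio
  from an empty nucleoplasm.
* 16-bit TIFF output clamps to [0, 65535]; the built-in baseline codec
  exists because the execution environment ships no R TIFF reader, and is
  cross-validated against an external reader in the test suite.

## Known limitations

* The shape operators are calibrated on the phantom taxonomy; real-image
  use requires re-calibration of `classifier_config()` against expert
  scores (the elongation rule and CR need none).
* No PSF/optics model; segmentation on real low-contrast stains will need
  its own validation.
* 3D shape scoring reduces to the largest-area slice for everything but
  elongation; genuinely 3D blebs or bends oriented along z are invisible
  to it.
* The repeat-level ANOVA treats repeats as exchangeable and equally
  weighted even when repeats differ in nucleus count, matching the
  protocol's per-repeat averaging; a nucleus-level mixed model is out of
  scope by design.
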