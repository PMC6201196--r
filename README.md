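# nucmorph

Nuclear morphometry and lamina-protein mislocalization scoring for
fluorescence microscopy of cultured myogenic cells.

Skeletal-muscle laminopathies (mutations in *LMNA*, encoding Lamin A/C)
deform the nuclear lamina: nuclei of patient-derived myogenic cells become
jellybean-shaped, severely deformed, blebbed, stringy or abnormally
elongated, and lamina proteins mislocalize (Lamin A/C honeycomb patterns
and bright foci, Lamin B1 "capping", emerin foci). These phenotypes are
usually scored manually, nucleus by nucleus, from confocal images of 2D
monolayers and 3D engineered-muscle constructs. `nucmorph` turns that
scoring protocol into a tested, reusable pipeline:

* **Nuclear contour ratio** `CR = 4πA / P²` — 1 for a perfect circle,
  decreasing with deformity; control nuclei typically span 1–0.79
  (circular/oval band). The perimeter `P` is measured sub-pixel by
  marching squares on the Gaussian-smoothed mask, so a rasterized disc
  measures `CR = 1` within 1% (naive pixel-edge counting is ~27% off).
* **Multi-label shape classification** into jellybean, severely deformed,
  blebs, strings and elongated (major axis strictly > 25 μm); the empty
  label set is a normal nucleus. A nucleus may carry several labels, so
  per-class tallies can exceed 100% — exactly how the field reports them.
* **Peripheral localization ratio** — mean lamin intensity in a 1 μm
  peripheral ring over the mean in the remaining nucleoplasm; > 1 means
  peripheral enrichment. Detectors for honeycomb, foci, Lamin B1 capping
  arcs and emerin foci, with robust (median/MAD) thresholds.
* **Myotube assignment** by the three-criteria rule: nucleus inside a
  myosin-positive structure, structure multinucleated, marker excluded
  from the nucleus.
* **Repeat-level statistics** — per-field tables are averaged per
  experimental repeat (n = repeats, never n = nuclei), compared by one- or
  two-way ANOVA with Tukey HSD between lines and Sidak-adjusted
  within-line contrasts (the 2D-monolayer vs 3D-construct design).
* **Synthetic phantoms** — a generator that renders 2D fields and 3D
  stacks of nucleus phantoms with known shape class, rim ratio,
  mislocalization flags and myotube context, so every stage is testable
  with exact ground truth and no real data.

Images travel as multi-page TIFF (a minimal baseline codec is built in,
readable by Fiji/tifffile), results as per-nucleus CSV plus JSON/SVG
reports; all lengths are in micrometres.

## Worked example

```r
library(nucmorph)

spec <- phantom_spec(
  n_nuclei   = 24, field_size = c(1000, 1000), pixel_size_um = 0.2,
  shape_mix  = c(normal = 0.6, jellybean = 0.1, severely_deformed = 0.1,
                 blebs = 0.1, elongated = 0.1),
  rim_ratio  = 2, misloc_fractions = c(honeycomb = 0.25, capping = 0.25),
  seed = 42)
sim   <- generate_field(spec)
masks <- segment_nuclei_2d(sim$field)
tab   <- classify_nuclei(masks)
loc   <- localize_nuclei(sim$field, masks)

nrow(tab)                     # 24 nuclei segmented
round(mean(tab$contour_ratio), 3)
table(tab$label_set)
round(mean(loc$peripheral_ratio), 2)
```

prints (seed 42):

```
[1] 24
[1] 0.788
            blebs         elongated         jellybean            normal
                1                 8                 2                10
severely_deformed
                3
[1] 2.04
```

All 24 phantoms are segmented and each carries the label it was generated
with (the seeded draw put 8 elongated nuclei in this field). The mean
contour ratio 0.788 sits right at the 0.79 normal-band floor — expected
for a field where only 10/24 nuclei are normal — and the peripheral ratio
recovers the injected rim ratio of 2 to within 2%.

Statistics run on repeat summaries:

```r
s <- summarize_repeat(per_nucleus_table)          # one row per repeat
compare_groups(s, "mean_contour_ratio", design = "one_way")   # Tukey
condition_contrast(s, "prop_elongated")           # Sidak, 2D vs 3D
```

## Command line

```sh
Rscript -e 'nucmorph::nucmorph_main()' simulate --spec spec.json --seed 1 --out sim/
Rscript -e 'nucmorph::nucmorph_main()' classify --image sim/phantom.tif --out nuclei.csv
Rscript -e 'nucmorph::nucmorph_main()' stats --in per_nucleus.csv --out report/
Rscript -e 'nucmorph::nucmorph_main()' run --config pipeline.json
```

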