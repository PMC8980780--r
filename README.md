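# vesselmetrics

Retinal vessel morphometry from artery/vein/optic-disc segmentation masks.

Microvascular geometry visible in fundus photographs — vessel calibers,
branching angles, tortuosity, network hierarchy — carries information about
systemic vascular health. Segmentation networks produce pixel masks of the
arteries, veins and optic disc; this package does the *measurement* step:
it converts those masks into a hierarchical vessel graph and computes the
standard quantitative parameters, per image, with quality control and
agreement statistics. It is aimed at researchers who already have
segmentation maps (from any model or manual annotation) and need
reproducible morphometry with auditable intermediate structures.

## What is computed

**Standard-zone caliber summaries.** The optic disc (center, radius `r`) is
located from its mask; in the annulus 0.5–1.0 disc diameters from the disc
margin (radii `2r`–`3r`), the six largest arteries and six largest veins are
combined into the central retinal artery/vein equivalents by the revised
pairwise formula

    w_pair = c * sqrt(w1^2 + w2^2),   c = 0.88 (arteries), 0.95 (veins)

pairing widest with narrowest, carrying the median on odd counts, iterating
to a single CRAE / CRVE; AVRe = CRAE / CRVE.

**Per-segment parameters.** The union vessel mask is thinned to a skeleton,
split into segments at branch and crossing points (segments under 10 px are
excluded), and each segment gets a caliber profile from the Euclidean
distance transform (`d = 2·EDT − 1`), arc length, chord length,
length–diameter ratio, and tortuosity (arc/chord).

**Bifurcation geometry.** At each degree-3 junction of one vessel class:
trunk and daughter calibers `d0 ≥ d1 ≥ d2`, branching angle BA (and BA_edge
from wall-contour fits), branching coefficient `BC = (d1²+d2²)/d0²`,
asymmetry ratio `AR = (d2/d1)²`, angular asymmetry `AA = |θ1 − θ2|`, and the
junctional exponent deviation from Murray's law
`JED = ((d1³+d2³)^{1/3} − d0)/d0`.

**Topology and texture.** Centrifugal vessel orders and Strahler orders on
the graph rooted at the disc (crossings are resolved into vessel
continuations, not branchings), and a box-counting fractal dimension.

**Quality control.** Images with no detectable disc, fewer than 6 arteries
or 6 veins in the standard zone, or fewer than 2 arteries or 2 veins overall
are excluded; excluded images keep their computable measurements in a
separate output.

**Agreement statistics.** AUC / accuracy / sensitivity / specificity / F1
inside the field of view, ICC(A,1) with confidence bounds and reliability
bands (poor/moderate/good/excellent), and Bland–Altman limits of agreement.

A parameterized synthetic retina (`generate_tree()`) with exhaustive ground
truth backs the whole test suite — no image downloads are needed.

## Worked example

```r
library(vesselmetrics)

# a synthetic eye with known geometry (or load_segmentation_maps() for PNGs)
g   <- generate_tree(synth_tree_spec(seed = 42))
rec <- measure_fundus(g$maps)
rec
#> <fundus_record> synth_42  QC: pass
#>   CRAE 14.41 px | CRVE 21.50 px | AVRe 0.670
#>   91 segments, 38 bifurcations, fractal dim 1.130

glance(rec)[, c("qc_status", "crae", "crve", "avre", "n_arteries_zone")]
#>   qc_status     crae     crve     avre n_arteries_zone
#> 1      pass 14.41306 21.50002 0.670374               9
```

The CRAE/CRVE are the combined calibers (pixels) of the six largest
arteries/veins crossing the standard zone; their ratio 0.67 is in the
normal adult range. `tidy(rec, "segments")` and `tidy(rec, "bifurcations")`
expose the per-segment and per-junction tables:

```r
tidy(rec, "segments")[1:2, c("vessel_class", "vessel_order",
                             "strahler_order", "mean_diameter", "tortuosity")]
#>   vessel_class vessel_order strahler_order mean_diameter tortuosity
#> 1         vein            4              1      5.000000   1.063182
#> 2         vein            4              1      5.059554   1.122558
```

Batch processing a directory of `<id>_artery.png` / `<id>_vein.png` /
`<id>_disc.png` triplets:

```r
run_pipeline("masks/", "out/", vessel_config())
# out/: measurements.csv, excluded.csv, segments.csv, bifurcations.csv,
#       per-image JSON records, run.log
```

A thin command-line wrapper lives in `inst/cli/vesselmetrics.R`
(`run`, `synth`, `eval` subcommands).

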