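# quadstitch

Automated reconstruction of **pseudo whole-mount histological sections
(PWMHS)** from four digitized tissue-quadrant images.

Large specimens — prostate cross-sections in particular — are routinely
quartered so each piece fits a standard slide. Annotating disease across
piece boundaries, or registering pathology to in-vivo MRI, then needs the
four scans reassembled into one section. The fragments defeat ordinary
image stitching: they do not overlap, tissue is missing along the cuts,
and the cut boundaries do not interlock. `quadstitch` reassembles them by
estimating one rigid-body transform (tx, ty, θ) per quadrant — three
moving quadrants relative to a fixed fourth, a 9-degree-of-freedom
search — by minimizing a two-component, domain-inspired cost

    C(T) = w1 · D_tot + w2 · M_tot,      w2 = 1 − w1

* **D** (tissue dissimilarity): corresponding edge pixels across each
  stitch boundary are compared by the L1 distance between b-bin intensity
  histograms of p×p patches (tissue pixels only, normalized to discrete
  probability densities). Non-corresponding pixels contribute the maximum
  dissimilarity φ (2 for histograms, 1 for single pixels at the coarsest
  level):
  `D_pair = (Σ_k ‖V¹(k) − V²(k)‖₁ + m·φ) / (n + m)`.
* **M** (boundary misalignment): distances between the inner and outer
  endpoints of facing edges' Theil–Sen best-fit lines,
  `M_pair = w3·‖C_in¹ − C_in²‖ + w4·‖C_out¹ − C_out²‖`.

Both are averaged over the four adjacent pairs (ul,ur), (ur,lr), (lr,ll),
(ll,ul). Optimization is an elitist genetic algorithm (population 20,
25-generation stall rule) run coarse-to-fine through an image pyramid,
each finer level searching a local window around the previous solution.
Defaults: w1 = 0.989, w3 = 0.4, p = 81 px, b = 16 bins.

A synthetic-data module generates pseudo-histology phantoms (textured
tissue ellipse with gland lumina and zonal banding), quarters them with
wavy cuts, destroys a kerf of tissue, perturbs each quadrant rigidly, and
records the ground truth — so the entire pipeline is testable without any
clinical material. Reconstructions are scored against a reference with
three measures, each absolute (μm) and normalized by the average of the
reference's width and height (%): automatically placed stitch-edge
fiducials (ASF), supplied landmark fiducials (MSF), and the Hausdorff
distance between optimally aligned convex hulls.

## Worked example

```r
library(quadstitch)

# a synthetic section: lossless cuts, ±5 px / ±3° quadrant perturbations
fx <- simulate_fixture("easy", seed = 3)

st <- hierarchical_stitch(fx$quadrants, ga_cfg = ga_config(seed = 42))
st
#> <stitch_result> final cost 0.25869 over 4 levels (8, 4, 2, 1)
#> <transform_set> fixed = ul
#>   ul: tx     0.00  ty     0.00  theta    0.00 deg
#>   ur: tx   203.64  ty    -4.68  theta   -2.90 deg
#>   ll: tx     4.39  ty   175.00  theta   -3.08 deg
#>   lr: tx   207.70  ty   173.03  theta   -1.10 deg

evaluate_reconstruction(fx$ground_truth$transforms, st$transforms,
                        fx$quadrants,
                        msf = landmarks_to_msf(fx$ground_truth$landmarks,
                                               fx$ground_truth$transforms,
                                               st$transforms))
#> <eval_report> ASF 75.1 um (0.24%)  MSF 70.0 um (0.22%)  Hausdorff 96.9 um (0.31%)
```

The transform set places each quadrant in the frame of the fixed
upper-left quadrant (translations in base-resolution pixels, rotations in
degrees about each quadrant's tissue centroid). Against the known ground
truth, the recovered poses leave mean fiducial displacements of ~75 μm
(0.24% of the section size at 80 μm/px) and a hull Hausdorff distance of
~97 μm — i.e. the reassembly is within about one pixel of truth.

To render and save the stitched section:

```r
comp <- composite_section(fx$quadrants, st$transforms)
write_gray_image(comp$image, "stitched.png")
write_transform_set(st$transforms, "transforms.json")
```

## Command line

A thin Rscript wrapper over the same functions is installed with the
package:

```sh
AS=$(Rscript -e 'cat(system.file("cli","autostitch.R",package="quadstitch"))')
Rscript $AS simulate --preset easy --seed 7 --out fix/
Rscript $AS stitch --ul fix/ul.png --ur fix/ur.png --ll fix/ll.png \
                   --lr fix/lr.png --um-per-px 80 --out run/ --seed 7
Rscript $AS evaluate --fixture fix/ --test run/transforms.json \
                     --ref fix/truth_transforms.json --out report
```

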