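# polcoloc

Single-cell polarity and colocalisation quantification for fluorescence
microscopy.

When lymphocytes are activated, intracellular compartments that are spread
uniformly in resting cells — lysosomes (LAMP1⁺ vesicles), internalised
antigen, cytoskeletal networks — collapse towards one pole of the cell.
polcoloc measures this redistribution on single-cell image crops
(multi-page TIFF, one cell per crop) and provides a synthetic-cell
generator with planted ground truth for validating every estimator.

## The statistics

For a channel with intensities $w_i$ at pixel positions $(x_i, y_i)$ and a
cell centre $c$ (pixel size $p$ μm/px):

* **asymmetry** $= p\,\lVert \bar r - c \rVert$, where
  $\bar r = \sum_i w_i r_i / \sum_i w_i$ is the intensity-weighted
  centroid after local background subtraction (2.6 μm disk);
* **cluster count** = number of connected components (8-connectivity,
  min area 4 px) above the Otsu threshold of the 0.13–0.9 μm
  difference-of-Gaussians bandpass;
* **cluster half-width** $= p\,(\sigma_x + \sigma_y)/2$ over cluster
  pixels only, with $\sigma_x, \sigma_y$ intensity-weighted SDs;
* **colocalisation**: Pearson $r$ over the in-cell pixels plus Manders
  $M_1 = \sum_i a_i [b_i > t_b] / \sum_i a_i$ (and symmetrically $M_2$)
  at Costes automatic thresholds — the highest $t_a$ (with
  $t_b = \text{slope}\cdot t_a + \text{intercept}$ from orthogonal
  regression) at which the jointly-below-threshold pixels are
  uncorrelated.

See `vignettes/polcoloc-methods.Rmd` for assumptions, parameter defaults
and numerical choices.

## Worked example

```r
library(polcoloc)

scene <- scene_spec()                       # 3.5 um cell, 0.08 um/px
channels <- list(
  puncta_channel_spec(n_puncta = 30L, polarisation_offset = 2,
                      placement_spread = 1.2, name = "antigen"),
  puncta_channel_spec(n_puncta = 30L, placement_spread = 1.5,
                      name = "lamp1"))
cell <- simulate_cell(scene, channels, noise_spec(seed = 42L),
                      overlap_fraction = 0.6)

geom <- estimate_cell_center(get_channel(cell$image, "nucleus"),
                             scene$pixel_size)
cfg <- run_config(channel_roles = list(nucleus = "nucleus",
                                       compartment_a = "antigen",
                                       compartment_b = "lamp1"))
compute_polarity_metrics(cell$image, "antigen", geom, cfg)
#> <polarity_metrics> channel 'antigen'
#>   clusters: 19   asymmetry: 1.715 um   half-width: 1.204 um
#>   area coverage: 0.077   mean spot intensity: 123.1   mean spot area: 0.1364 um^2

colocalise_cell(cell$image, geom, "antigen", "lamp1", cfg)
#> <coloc_report> antigen vs lamp1 over 6033 px
#>   Pearson r: 0.622 (above-threshold: 0.724)
#>   Costes thresholds: t_a = 28.43, t_b = 28.31
#>   Manders: M1 = 0.389, M2 = 0.376
```

Reading the numbers: the generator planted a 2 μm polarisation offset and
the pipeline recovers 1.7 μm of asymmetry (the 30 overlapping spots merge
into 19 segmented clusters — counts are exact only for well-separated
puncta, see the vignette). The two channels share 60% of their spot
centres, which shows up as an intermediate Pearson r; the Manders values
are deflated by the additive background of 20 counts, which belongs to
neither compartment but contributes to both denominators.

## Command line

```sh
polcoloc simulate --cells 20 --offset 2.0 --seed 7 --out sim/   # TIFFs + ground_truth.csv
polcoloc polarity sim/cell_0001.tif --out pol.csv
polcoloc coloc sim/cell_0001.tif --chan-a antigen --chan-b lamp1
polcoloc batch sim/ --out results/
polcoloc validate-config                                        # prints resolved defaults
```

(The `polcoloc` script is installed under `inst/bin/`; equivalently call
`polcoloc::polcoloc_cli(c("simulate", ...))` from R.)

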