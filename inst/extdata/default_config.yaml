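# Default polcoloc pipeline configuration (schema v1).
# Values marked [standard constant] are the published analysis constants;
# the rest are artifact choices (see the methods vignette).
schema_version: 1
pixel_size: 0.08            # um/px; stand-in for typical 63x/1.4NA sampling
band:
  low_scale: 0.13           # um [standard constant]
  high_scale: 0.9           # um [standard constant]
background_radius: 2.6      # um [standard constant]
centroid_background: median # unbiased level estimate under noise
centroid_clip_weights: no   # signed residuals cancel instead of pulling inward
otsu_bins: 256
min_cluster_area: 4         # px; suppresses single-pixel noise
connectivity: 8
sigma_rule: half            # DoG sigma = scale / 2 (alternative: fwhm)
half_width_on: raw          # weight half-width with raw intensities
background_before_segmentation: no   # subtraction belongs to the centroid
normalise_asymmetry: no     # report raw um, not radius fractions
use_cell_mask: yes
cell_mask_scale: 1.25       # cytoplasmic allowance around a nucleus-derived circle
channel_roles:
  nucleus: nucleus
  compartment_a: puncta
  compartment_b: ~
coloc_mask: cell_circle
coloc_regression: tls       # orthogonal regression, as in the original method
coloc_max_candidates: 512
crop_padding: 0.2           # um
seed: 1
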