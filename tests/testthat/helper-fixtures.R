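# Small shared simulation configs used across test files.

# single-nucleus noiseless field with optional voids and markers
tiny_nucleus_cfg <- function(seed = 1, radius = 55, voids = 0,
                             void_radius = 8, noise = 0, markers = list(),
                             size = c(200, 200), hole_prevalence = 0,
                             hole_radius = 12) {
  image_sim_config(
    field_size_px = size, n_nuclei = 1,
    nucleus_radius_px = c(mean = radius, sd = 0),
    shape_irregularity = 0,
    camera_noise_sd = noise,
    nucleoli_per_nucleus = dist_spec("point", value = voids),
    nucleolus_radius_px = dist_spec("point", value = void_radius),
    hole_prevalence = hole_prevalence,
    hole_radius_px = dist_spec("point", value = hole_radius),
    marker_specs = markers, seed = seed)
}

# brute-force region masks from a ground-truth nucleus mask, independent of
# derive_rois: direct Euclidean distances from pixel centers to mask pixels
brute_regions <- function(mask, band = 20, inner = 5, outer = 20, ne = 5) {
  din <- nucquant:::as_mat(EBImage::distmap(mask + 0))
  dout <- nucquant:::as_mat(EBImage::distmap(1 - (mask + 0)))
  list(nucleus = which(mask > 0),
       band = which(mask > 0 & din <= band),
       ring = which(mask == 0 & dout > inner & dout <= outer),
       toroid = which((mask > 0 & din <= ne) | (mask == 0 & dout <= ne)))
}

# rasterized centered disk mask
disk_mask <- function(size, r, cx = size[1] / 2, cy = size[2] / 2) {
  xs <- matrix(seq_len(size[1]), size[1], size[2])
  ys <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}
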