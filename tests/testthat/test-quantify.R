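# a one-nucleus RoiSet on ground-truth labels plus a constant-value field
uniform_marker_field <- function(value, labels) {
  image_field(list(
    chromatin = matrix(0.8, nrow(labels), ncol(labels)),
    m = matrix(value, nrow(labels), ncol(labels))))
}

test_that("uniform markers give zero intensity and unit ratios", {
  sim <- generate_cell_field(tiny_nucleus_cfg())
  labels <- sim$truth$nucleus_labels
  rois <- derive_rois(labels)
  mi <- marker_intensities(uniform_marker_field(0.37, labels), rois)
  expect_equal(mi$nuclear_intensity, 0)
  expect_equal(mi$ne_intensity, 0)
  expect_equal(mi$radial_distribution, 1)
  expect_equal(mi$peripheral_distribution, 1)
})

test_that("marker v inside the nucleus and 0 outside measures v", {
  sim <- generate_cell_field(tiny_nucleus_cfg())
  labels <- sim$truth$nucleus_labels
  rois <- derive_rois(labels)
  m <- matrix(0, nrow(labels), ncol(labels))
  m[labels == 1] <- 0.62
  fld <- image_field(list(chromatin = get_channel(sim$field, "chromatin"),
                          m = m))
  mi <- marker_intensities(fld, rois)
  expect_equal(mi$nuclear_intensity, 0.62)
})

test_that("radial distribution equals the brute-force band/nucleus ratio", {
  cfg <- tiny_nucleus_cfg(markers = list(
    marker_spec("m", nuclear_mean = 0.4, cytoplasm_mean = 0.05,
                periphery_enrichment = 2)))
  sim <- generate_cell_field(cfg)
  labels <- sim$truth$nucleus_labels
  rois <- derive_rois(labels)
  mi <- marker_intensities(sim$field, rois)
  m <- get_channel(sim$field, "m")
  reg <- brute_regions(labels == 1)
  expect_equal(mi$radial_distribution,
               mean(m[reg$band]) / mean(m[reg$nucleus]))
})

test_that("intensities are affine-invariant, ratios scale-invariant", {
  cfg <- tiny_nucleus_cfg(markers = list(
    marker_spec("m", 0.4, 0.1, periphery_enrichment = 1.5)), noise = 0.03)
  sim <- generate_cell_field(cfg)
  labels <- sim$truth$nucleus_labels
  rois <- derive_rois(labels)
  base <- marker_intensities(sim$field, rois)
  m <- get_channel(sim$field, "m")
  chrom <- get_channel(sim$field, "chromatin")
  shifted_field <- function(c_add, c_mul = 1) image_field(list(
    chromatin = chrom, m = m * c_mul + c_add))
  prev_ratio <- Inf
  for (c_add in c(0.5, 2, 10)) {
    mi <- marker_intensities(shifted_field(c_add), rois)
    expect_equal(mi$nuclear_intensity, base$nuclear_intensity)
    expect_equal(mi$ne_intensity, base$ne_intensity)
    # ratio of (marker + c) decreases monotonically toward 1
    expect_lt(abs(mi$radial_distribution - 1),
              abs(prev_ratio - 1))
    prev_ratio <- mi$radial_distribution
  }
  for (c_mul in c(0.5, 7)) {
    mi <- marker_intensities(shifted_field(0, c_mul), rois)
    expect_equal(mi$nuclear_intensity, c_mul * base$nuclear_intensity)
    expect_equal(mi$radial_distribution, base$radial_distribution)
  }
})

test_that("measured nuclear intensity tracks ground truth within 2% RMS", {
  errs <- c()
  for (f in 1:8) {
    cfg <- image_sim_config(
      field_size_px = c(760, 760), n_nuclei = 25,
      nucleus_radius_px = c(mean = 28, sd = 2), shape_irregularity = 0.05,
      marker_specs = list(marker_spec("m", 0.5, 0.1)), seed = f)
    sim <- generate_cell_field(cfg)
    rois <- derive_rois(sim$truth$nucleus_labels)
    mi <- marker_intensities(sim$field, rois)
    errs <- c(errs, (mi$nuclear_intensity - 0.4) / 0.4)
  }
  expect_equal(length(errs), 200)
  expect_lt(sqrt(mean(errs^2)), 0.02)
})

test_that("cross-sectional areas match rasterized disks and scale with units", {
  size <- c(140, 140)
  lab <- matrix(0L, size[1], size[2])
  lab[disk_mask(size, 50, 70, 70)] <- 1L
  a <- cross_sectional_area(lab)
  expect_lt(abs(a$area - pi * 2500) / (pi * 2500), 0.02)
  a2 <- cross_sectional_area(lab, pixel_size = 0.5)
  expect_equal(a2$area, a$area * 0.25)
  expect_equal(nrow(cross_sectional_area(matrix(0L, 10, 10))), 0)
})

test_that("H2A.Z-style intensity reflects depletion and known levels", {
  # depletion mimic: marker absent from nuclei and cytoplasm
  cfg0 <- tiny_nucleus_cfg(markers = list(
    marker_spec("H2A.Z", nuclear_mean = 0, cytoplasm_mean = 0,
                nucleolar_factor = 0)))
  sim0 <- generate_cell_field(cfg0)
  rois0 <- derive_rois(sim0$truth$nucleus_labels)
  expect_equal(haz_intensity(sim0$field, rois0)$nuclear_intensity, 0)

  # uniform nuclear level v over zero background, zero noise -> exactly v
  cfg1 <- tiny_nucleus_cfg(markers = list(
    marker_spec("H2A.Z", nuclear_mean = 0.45, cytoplasm_mean = 0)))
  sim1 <- generate_cell_field(cfg1)
  rois1 <- derive_rois(sim1$truth$nucleus_labels)
  expect_equal(haz_intensity(sim1$field, rois1)$nuclear_intensity, 0.45)

  # noisy field: within 2% of the configured region-mean difference
  cfg2 <- tiny_nucleus_cfg(markers = list(
    marker_spec("H2A.Z", nuclear_mean = 0.45, cytoplasm_mean = 0.1)),
    noise = 0.05, seed = 8)
  sim2 <- generate_cell_field(cfg2)
  rois2 <- derive_rois(sim2$truth$nucleus_labels)
  got <- haz_intensity(sim2$field, rois2)$nuclear_intensity
  expect_lt(abs(got - 0.35) / 0.35, 0.02)
})

test_that("empty background rings and zero nuclear means are flagged", {
  size <- c(60, 60)
  lab <- matrix(1L, size[1], size[2])  # nucleus fills the field: no ring
  rois <- derive_rois(lab)
  fld <- image_field(list(chromatin = matrix(1, 60, 60),
                          m = matrix(0, 60, 60)))
  mi <- marker_intensities(fld, rois)
  expect_true(mi$bg_undefined)
  expect_true(is.na(mi$nuclear_intensity))
  expect_true(mi$ratio_undefined)
  expect_true(is.na(mi$radial_distribution))
})
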