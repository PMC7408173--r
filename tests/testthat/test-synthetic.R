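test_that("zero-noise fields reproduce configured region means exactly", {
  cfg <- image_sim_config(
    field_size_px = c(360, 360), n_nuclei = 3,
    nucleus_radius_px = c(mean = 40, sd = 3), camera_noise_sd = 0,
    marker_specs = list(
      marker_spec("m1", nuclear_mean = 0.5, cytoplasm_mean = 0.1,
                  periphery_enrichment = 2)),
    seed = 1)
  sim <- generate_cell_field(cfg)
  gt <- sim$truth
  expect_equal(sort(unique(gt$nucleus_labels[gt$nucleus_labels > 0])), 1:3)

  chrom <- get_channel(sim$field, "chromatin")
  for (i in 1:3) {
    idx <- which(gt$nucleus_labels == i)
    expect_equal(mean(chrom[idx]), cfg$chromatin_level)
  }
  expect_equal(mean(chrom[gt$nucleus_labels == 0]), cfg$cytoplasm_level)

  # periphery band mean = 2 x nuclear mean, verified by brute force over the
  # painted band mask (independent distance computation in the helper)
  m1 <- get_channel(sim$field, "m1")
  for (i in 1:3) {
    reg <- brute_regions(gt$nucleus_labels == i)
    expect_equal(mean(m1[reg$band]), 2 * 0.5)
    truth_band <- gt$marker_truth$true_mean[
      gt$marker_truth$nucleus_id == i &
        gt$marker_truth$region == "periphery_band"]
    expect_equal(mean(m1[reg$band]), truth_band)
  }
})

test_that("identical config and seed give bit-identical output, seeds differ", {
  cfg <- image_sim_config(field_size_px = c(300, 300), n_nuclei = 2,
                          nucleus_radius_px = c(mean = 35, sd = 2), seed = 5)
  a <- generate_cell_field(cfg)
  b <- generate_cell_field(cfg)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$nucleus_labels, b$truth$nucleus_labels)
  cfg2 <- cfg; cfg2$seed <- 6L
  c2 <- generate_cell_field(cfg2)
  expect_false(identical(a$truth$nucleus_table$cx, c2$truth$nucleus_table$cx))
})

test_that("ground-truth masks nest: voids inside nuclei, nuclei disjoint", {
  cfg <- image_sim_config(
    field_size_px = c(420, 420), n_nuclei = 3,
    nucleus_radius_px = c(mean = 45, sd = 3),
    nucleoli_per_nucleus = dist_spec("point", value = 2),
    nucleolus_radius_px = dist_spec("uniform", min = 5, max = 8),
    hole_prevalence = 1, seed = 2)
  sim <- generate_cell_field(cfg)
  gt <- sim$truth
  expect_true(all(gt$nucleus_labels[gt$void_labels > 0] > 0))
  for (v in gt$void_table$void_id) {
    owners <- unique(gt$nucleus_labels[gt$void_labels == v])
    expect_identical(owners, gt$void_table$nucleus_id[
      gt$void_table$void_id == v])
  }
  # labels partition the field: each pixel belongs to at most one nucleus by
  # construction of the label raster; check components are where claimed
  for (i in 1:3)
    expect_gt(sum(gt$nucleus_labels == i), pi * 35^2)
})

test_that("impossible placement is rejected naming the offending parameter", {
  cfg <- image_sim_config(field_size_px = c(128, 128), n_nuclei = 6,
                          nucleus_radius_px = c(mean = 40, sd = 0), seed = 1)
  expect_error(generate_cell_field(cfg), "placement|fit")
})

test_that("in vitro nuclei: prevalence 0 and 1 behave exactly", {
  sim0 <- generate_invitro_nuclei(tiny_nucleus_cfg(hole_prevalence = 0))
  expect_false(any(sim0$truth$has_hole))

  cfg1 <- tiny_nucleus_cfg(hole_prevalence = 1, hole_radius = 8, seed = 3)
  cfg1$n_nuclei <- 6L
  sim1 <- generate_invitro_nuclei(cfg1)
  expect_true(all(sim1$truth$has_hole))
  # painted hole area ~ pi r^2 (rasterization only; before any blurring)
  expect_true(all(abs(sim1$truth$hole_area_px2 - pi * 64) < 0.05 * pi * 64))
})

test_that("empirical hole prevalence falls in the 95% binomial CI", {
  cfg <- tiny_nucleus_cfg(hole_prevalence = 0.3, seed = 17,
                          size = c(128, 128), radius = 30)
  cfg$n_nuclei <- 500L
  sim <- generate_invitro_nuclei(cfg)
  phat <- mean(sim$truth$has_hole)
  ci <- stats::binom.test(round(phat * 500), 500, p = 0.3)$conf.int
  expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
})

test_that("track quantization is the ceiling of the continuous duration", {
  cfg <- track_sim_config(
    n_tracks = 200, frame_interval_min = 1,
    exit_duration_model = dist_spec("lognormal", meanlog = log(20),
                                    sdlog = 0.4),
    seed = 4)
  sim <- generate_tracks(cfg)
  per <- vapply(split(sim$tracks, sim$tracks$track_id), function(tr) {
    after <- tr[tr$time_min >= 0, ]
    after$time_min[match("inter", after$phase)]
  }, 1)
  d <- per[order(as.integer(names(per)))] - sim$truth$true_exit_min
  expect_true(all(d >= 0 & d < 1))
  expect_equal(unname(per[order(as.integer(names(per)))]),
               sim$truth$quantized_exit_min)
})

test_that("point-mass exit durations produce exact phase blocks", {
  cfg <- track_sim_config(
    n_tracks = 10, frame_interval_min = 3,
    exit_duration_model = dist_spec("point", value = 21),
    ana_duration_model = dist_spec("point", value = 6), seed = 1)
  sim <- generate_tracks(cfg)
  for (tr in split(sim$tracks, sim$tracks$track_id)) {
    expect_equal(tr$time_min[tr$phase == "ana"], c(0, 3))
    expect_equal(min(tr$time_min[tr$phase == "inter" & tr$time_min >= 0]), 21)
    expect_equal(tr$time_min[tr$phase == "telo"], seq(6, 18, by = 3))
  }
})

test_that("phase sequence is monotone inter->...->ana->telo->inter", {
  sim <- generate_tracks(track_sim_config(n_tracks = 50, seed = 9))
  ord <- c(inter = 0, pro = 1, prometa = 2, meta = 3, ana = 4, telo = 5)
  for (tr in split(sim$tracks, sim$tracks$track_id)) {
    codes <- ord[tr$phase]
    post <- codes[tr$time_min >= 0]
    # after onset: ana block, optional telo block, then inter forever
    runs <- rle(unname(post))$values
    expect_true(all(runs %in% c(4, 5, 0)))
    expect_true(identical(runs, c(4, 5, 0)) || identical(runs, c(4, 0)))
  }
})

test_that("quantized-duration median matches the analytic median (10k tracks)", {
  med <- 24
  cfg <- track_sim_config(
    n_tracks = 10000, frame_interval_min = 3,
    exit_duration_model = dist_spec("lognormal", meanlog = log(med),
                                    sdlog = 0.3),
    seed = 21)
  sim <- generate_tracks(cfg)
  expect_lte(abs(stats::median(sim$truth$quantized_exit_min) -
                   dist_median(cfg$exit_duration_model)), 3)
})
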