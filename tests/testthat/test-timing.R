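hand_track <- function(times, phases, id = 1L)
  data.frame(track_id = id, frame = seq_along(times), time_min = times,
             phase = phases)

test_that("dwell time of a hand-countable track is exact", {
  tr <- hand_track(seq(0, 24, by = 3),
                   c("ana", "ana", rep("telo", 5), "inter", "inter"))
  d <- mitotic_exit_dwell(tr)
  expect_equal(d$dwell_min, 21)
  expect_equal(d$ana_min, 6)
  expect_equal(d$telo_min, 15)
  expect_false(d$censored)
})

test_that("tracks ending in telophase are censored", {
  tr <- hand_track(seq(0, 12, by = 3), c("ana", rep("telo", 4)))
  d <- mitotic_exit_dwell(tr)
  expect_true(d$censored)
  expect_true(is.na(d$dwell_min))
  expect_error(mitotic_exit_dwell(
    hand_track(c(0, 3), c("inter", "inter"))), "no anaphase")
  expect_error(mitotic_exit_dwell(
    hand_track(c(0, 3), c("ana", "interphase"))), "unknown phase")
})

test_that("label flicker smoothing is optional and width-1", {
  tr <- hand_track(seq(0, 18, by = 3),
                   c("ana", "ana", "telo", "ana", "telo", "inter", "inter"))
  raw <- mitotic_exit_dwell(tr)
  sm <- mitotic_exit_dwell(tr, smooth_flicker = TRUE)
  expect_equal(raw$dwell_min, 15)
  expect_equal(sm$dwell_min, 15)
  # the single telo frame flanked by ana frames is relabeled when smoothing
  expect_equal(raw$telo_min, 6)
  expect_equal(sm$telo_min, 3)
})

test_that("dwell summaries report median and IQR per condition", {
  tracks <- rbind(
    hand_track(seq(0, 21, 3), c("ana", "ana", rep("telo", 4), "inter", "inter"), 1),
    hand_track(seq(0, 24, 3), c("ana", "ana", rep("telo", 5), "inter", "inter"), 2),
    hand_track(seq(0, 27, 3), c("ana", "ana", rep("telo", 6), "inter", "inter"), 3))
  s <- dwell_summary(tracks)
  expect_equal(s$median_min, 21)
  expect_equal(s$iqr_min, 6)  # [18, 21, 24] under the n+1 convention
  one <- dwell_summary(tracks[tracks$track_id == 2, ])
  expect_equal(one$median_min, 21)
  expect_equal(one$iqr_min, 0)
  # explicit [18, 21, 24] multiset via conditions
  cond <- data.frame(track_id = 1:3, condition = c("a", "a", "b"))
  s2 <- dwell_summary(tracks, cond)
  expect_equal(s2$median_min[s2$condition == "a"], 19.5)
})

test_that("summary medians recover the analytic fixture median", {
  meds <- vapply(1:20, function(s) {
    cfg <- track_sim_config(
      n_tracks = 250, frame_interval_min = 3,
      exit_duration_model = dist_spec("lognormal", meanlog = log(25.5),
                                      sdlog = 0.3),
      seed = s)
    dwell_summary(generate_tracks(cfg)$tracks)$median_min
  }, 1)
  expect_true(all(abs(meds - 25.5) <= 3))
})

test_that("the cumulative interphase curve equals the brute-force ECDF", {
  sim <- generate_tracks(track_sim_config(n_tracks = 120, seed = 13))
  curve <- cumulative_interphase_curve(sim$tracks)
  expect_true(all(diff(curve$percent_interphase) >= 0))
  expect_equal(max(curve$percent_interphase), 100)
  # oracle: sort quantized durations and count by hand
  d <- sort(sim$truth$quantized_exit_min)
  oracle <- vapply(curve$time_min, function(t) 100 * sum(d <= t) / length(d), 1)
  expect_equal(curve$percent_interphase, oracle)

  # point-mass exits: a single step from 0 to 100 at t = 21
  pm <- generate_tracks(track_sim_config(
    n_tracks = 30, exit_duration_model = dist_spec("point", value = 21),
    seed = 1))
  cpm <- cumulative_interphase_curve(pm$tracks, times = c(0, 20.9, 21, 30))
  expect_equal(cpm$percent_interphase, c(0, 0, 100, 100))
})

test_that("censored tracks cap the curve below 100%", {
  cfg <- track_sim_config(n_tracks = 50, max_time_min = 21,
                          exit_duration_model =
                            dist_spec("lognormal", meanlog = log(21),
                                      sdlog = 0.3),
                          seed = 3)
  sim <- generate_tracks(cfg)
  expect_gt(sum(sim$truth$censored), 0)
  curve <- cumulative_interphase_curve(sim$tracks)
  expect_lt(max(curve$percent_interphase), 100)
  expect_equal(max(curve$percent_interphase),
               100 * mean(!sim$truth$censored))
})

test_that("N/C ratio series: trivial ratios and onset alignment", {
  s <- data.frame(frame = 1:10, nuclear_mean = rep(2, 10),
                  cytoplasm_mean = rep(2, 10))
  r <- nc_ratio_series(s, onset_frame = 4, frame_interval_min = 3)
  expect_equal(r$ratio, rep(1, 10))
  expect_equal(r$time_min[4], 0)
  s$nuclear_mean <- 2 * s$cytoplasm_mean
  expect_equal(nc_ratio_series(s, 4)$ratio, rep(2, 10))
  s$cytoplasm_mean[7] <- 0
  r3 <- nc_ratio_series(s, 4)
  expect_equal(nrow(r3), 9)
  expect_equal(attr(r3, "n_dropped"), 1)
})

test_that("import kinetics fit recovers the configured plateau within 5%", {
  s <- generate_nc_series(plateau = 2.5, rate_per_min = 0.15, seed = 2)
  fit <- fit_import_kinetics(nc_ratio_series(s, onset_frame = 5))
  expect_lt(abs(fit$plateau - 2.5) / 2.5, 0.05)
})

test_that("measured durations obey the quantization bound per track", {
  for (dt in c(1, 3)) {
    cfg <- track_sim_config(n_tracks = 150, frame_interval_min = dt,
                            seed = 7 + dt)
    sim <- generate_tracks(cfg)
    per <- nucquant:::dwell_per_track(sim$tracks)
    gap <- per$dwell_min[order(per$track_id)] - sim$truth$true_exit_min
    expect_true(all(gap >= 0 & gap < dt))
  }
})
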