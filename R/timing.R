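#' Mitotic-exit dwell time of one annotated track
#'
#' The exit duration is the time from anaphase onset (first `ana`-labeled
#' frame) to the end of telophase, operationalized as the first frame
#' annotated `inter` after that onset. Tracks that never reach interphase
#' (movie end) are censored. The per-phase split reports annotated frame
#' counts times the frame interval.
#'
#' @param track data.frame for a single track with columns `time_min` and
#'   `phase` (levels in [MITOTIC_PHASES]).
#' @param smooth_flicker Apply a width-1 majority filter to smooth single
#'   frame label flickers (off by default).
#' @return List with `dwell_min` (NA if censored), `ana_min`, `telo_min`,
#'   `censored`, `onset_min`.
#' @export
mitotic_exit_dwell <- function(track, smooth_flicker = FALSE) {
  stopifnot(all(c("time_min", "phase") %in% names(track)))
  bad <- setdiff(unique(track$phase), MITOTIC_PHASES)
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  o <- order(track$time_min)
  time <- track$time_min[o]
  phase <- as.character(track$phase[o])
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("track times must be strictly increasing")
  }
  if (smooth_flicker && length(phase) >= 3) {
    for (j in 2:(length(phase) - 1))
      if (phase[j] != phase[j - 1] && phase[j - 1] == phase[j + 1])
        phase[j] <- phase[j - 1]
  }
  onset <- match("ana", phase)
  if (is.na(onset)) stop("track contains no anaphase frame")
  after <- seq(onset, length(phase))
  exit_rel <- match("inter", phase[after])
  dt1 <- if (length(time) > 1) min(diff(time)) else NA_real_
  ana_frames <- sum(phase[after] == "ana")
  telo_frames <- sum(phase[after] == "telo")
  if (is.na(exit_rel))
    return(list(dwell_min = NA_real_, ana_min = ana_frames * dt1,
                telo_min = telo_frames * dt1, censored = TRUE,
                onset_min = time[onset]))
  exit_i <- after[exit_rel]
  # frames after exit do not belong to the ana/telo split
  span <- phase[onset:(exit_i - 1L)]
  list(dwell_min = time[exit_i] - time[onset],
       ana_min = sum(span == "ana") * dt1,
       telo_min = sum(span == "telo") * dt1,
       censored = FALSE, onset_min = time[onset])
}

# internal: per-track dwell over a track table
dwell_per_track <- function(tracks, smooth_flicker = FALSE) {
  stopifnot(all(c("track_id", "time_min", "phase") %in% names(tracks)))
  ids <- unique(tracks$track_id)
  res <- lapply(ids, function(id)
    mitotic_exit_dwell(tracks[tracks$track_id == id, , drop = FALSE],
                       smooth_flicker))
  data.frame(track_id = ids,
             dwell_min = vapply(res, `[[`, 1, "dwell_min"),
             ana_min = vapply(res, `[[`, 1, "ana_min"),
             telo_min = vapply(res, `[[`, 1, "telo_min"),
             censored = vapply(res, `[[`, TRUE, "censored"))
}

#' Dwell-time summary per condition
#'
#' Median and interquartile range of uncensored exit durations per
#' condition, pooled across replicates, with the anaphase/telophase frame
#' split. Even-length medians use the midpoint convention.
#'
#' @param tracks Track table (columns `track_id`, `time_min`, `phase`).
#' @param condition Optional vector mapping each `track_id` to a condition:
#'   either a named vector indexed by track id, or a data.frame with
#'   columns `track_id` and `condition`. Omitted = single condition
#'   `"all"`.
#' @param smooth_flicker Passed to [mitotic_exit_dwell()].
#' @return data.frame with one row per condition: `condition`, `n`,
#'   `n_censored`, `median_min`, `iqr_min`, `median_ana_min`,
#'   `median_telo_min`.
#' @export
dwell_summary <- function(tracks, condition = NULL, smooth_flicker = FALSE) {
  per <- dwell_per_track(tracks, smooth_flicker)
  cond <- if (is.null(condition)) rep("all", nrow(per))
  else if (is.data.frame(condition))
    condition$condition[match(per$track_id, condition$track_id)]
  else condition[as.character(per$track_id)]
  rows <- lapply(split(per, cond), function(d) {
    unc <- d[!d$censored, , drop = FALSE]
    if (!nrow(unc)) {
      warning("all tracks censored in a condition; empty summary")
      return(data.frame(condition = NA_character_, n = nrow(d),
                        n_censored = sum(d$censored),
                        median_min = NA_real_, iqr_min = NA_real_,
                        median_ana_min = NA_real_,
                        median_telo_min = NA_real_))
    }
    data.frame(condition = NA_character_, n = nrow(d),
               n_censored = sum(d$censored),
               median_min = stats::median(unc$dwell_min),
               # n+1 percentile convention, as used by the common graphing
               # software for quartile whiskers
               iqr_min = stats::IQR(unc$dwell_min, type = 6),
               median_ana_min = stats::median(unc$ana_min),
               median_telo_min = stats::median(unc$telo_min))
  })
  out <- do.call(rbind, rows)
  out$condition <- names(rows)
  rownames(out) <- NULL
  out[, c("condition", "n", "n_censored", "median_min", "iqr_min",
          "median_ana_min", "median_telo_min")]
}

#' Cumulative percentage of tracks in interphase after anaphase onset
#'
#' The step curve rises at each uncensored exit duration and plateaus at
#' `100 * uncensored / total`; it equals the empirical CDF of the exit
#' duration multiset scaled by the uncensored fraction.
#'
#' @param tracks Track table.
#' @param times Optional evaluation grid (minutes after anaphase onset);
#'   default the sorted unique exit times including 0.
#' @return data.frame with `time_min` and `percent_interphase`
#'   (nondecreasing, starts at the percentage exiting at t <= first grid
#'   point).
#' @export
cumulative_interphase_curve <- function(tracks, times = NULL) {
  per <- dwell_per_track(tracks)
  n <- nrow(per)
  d <- per$dwell_min[!per$censored]
  if (is.null(times)) times <- sort(unique(c(0, d)))
  pct <- vapply(times, function(t) 100 * sum(d <= t) / n, 1)
  data.frame(time_min = times, percent_interphase = pct)
}

#' Nuclear-to-cytoplasmic ratio time series
#'
#' Computes the per-frame N/C ratio and shifts the time axis so anaphase
#' onset is t = 0. Frames with non-positive cytoplasmic mean are dropped
#' and counted in `n_dropped`.
#'
#' @param series data.frame with `frame`, `nuclear_mean`, `cytoplasm_mean`
#'   and either `time_min` or a constant `frame_interval_min`.
#' @param onset_frame Frame index of anaphase onset.
#' @param frame_interval_min Frame interval, used when `time_min` is
#'   absent.
#' @return data.frame with `time_min` (0 at onset), `nuclear_mean`,
#'   `cytoplasm_mean`, `ratio`; attribute `n_dropped` counts removed
#'   frames.
#' @export
nc_ratio_series <- function(series, onset_frame, frame_interval_min = 3) {
  stopifnot(all(c("frame", "nuclear_mean", "cytoplasm_mean") %in%
                  names(series)),
            onset_frame %in% series$frame)
  tm <- if ("time_min" %in% names(series)) series$time_min else
    (series$frame - 1) * frame_interval_min
  t0 <- tm[match(onset_frame, series$frame)]
  ok <- series$cytoplasm_mean > 0
  out <- data.frame(time_min = tm[ok] - t0,
                    nuclear_mean = series$nuclear_mean[ok],
                    cytoplasm_mean = series$cytoplasm_mean[ok],
                    ratio = series$nuclear_mean[ok] / series$cytoplasm_mean[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Fit exponential import kinetics to an N/C ratio series
#'
#' Fits `ratio(t) = 1 + (plateau - 1) * (1 - exp(-rate * t))` to the
#' post-onset part of a ratio series by nonlinear least squares.
#'
#' @param ratio_series Output of [nc_ratio_series()].
#' @return List with `plateau` and `rate_per_min`.
#' @export
fit_import_kinetics <- function(ratio_series) {
  d <- ratio_series[ratio_series$time_min >= 0, , drop = FALSE]
  stopifnot(nrow(d) >= 4)
  start <- list(plateau = max(d$ratio), rate = 0.1)
  fit <- stats::nls(ratio ~ 1 + (plateau - 1) * (1 - exp(-rate * time_min)),
                    data = d, start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  co <- stats::coef(fit)
  list(plateau = unname(co["plateau"]), rate_per_min = unname(co["rate"]))
}
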