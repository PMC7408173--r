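#' Write a multi-channel ImageField as multi-page TIFF
#'
#' One page per channel, written as 32-bit float (default) or quantized to
#' the field's nominal bit depth; channel names go to a sidecar CSV
#' `<path>.channels.csv`.
#'
#' @param field An `ImageField`.
#' @param path Output TIFF path.
#' @param bits 8, 16 or 32 bits per sample (32 = float, lossless for
#'   simulated intensities in `[0, 1]`).
#' @return `path`, invisibly.
#' @export
write_image_field <- function(field, path, bits = 32L) {
  stopifnot(inherits(field, "ImageField"), bits %in% c(8L, 16L, 32L))
  pages <- lapply(field$channels, function(ch) {
    if (max(ch) > 1 || min(ch) < 0)
      stop("channel intensities must lie in [0, 1] for TIFF export; rescale")
    ch
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  utils::write.csv(
    data.frame(page = seq_along(pages), channel = names(field$channels)),
    paste0(path, ".channels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a multi-channel 2D TIFF into an ImageField
#'
#' Pages become channels; channel names come from `channels`, from a
#' sidecar `<path>.channels.csv`, or default to `channel_1..k`. Sample
#' depth is preserved as written by [write_image_field()] (values in
#' `[0, 1]`). Pages with a third dimension (Z stacks or RGB) are rejected:
#' maximum-project or split such data upstream.
#'
#' @param path TIFF path.
#' @param channels Optional channel names (length = number of pages).
#' @return An `ImageField`.
#' @export
read_image_field <- function(path, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages)
    if (length(dim(p)) != 2)
      stop("TIFF page is not a single-channel 2D raster (dims: ",
           paste(dim(p), collapse = "x"),
           "); max-project Z stacks and split RGB before reading")
  dims <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("TIFF pages differ in shape: ", paste(unique(dims), collapse = ", "))
  if (is.null(channels)) {
    sidecar <- paste0(path, ".channels.csv")
    channels <- if (file.exists(sidecar))
      utils::read.csv(sidecar)$channel
    else paste0("channel_", seq_along(pages))
  }
  if (length(channels) != length(pages))
    stop("need ", length(pages), " channel names, got ", length(channels))
  if (anyDuplicated(channels)) stop("channel names must be unique")
  names(pages) <- channels
  image_field(pages)
}

#' Write an integer label map as 16-bit TIFF
#' @param labels Integer matrix (values < 65536).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) < 65536, min(labels) >= 0)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_label_map()]
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a data frame as CSV with a provenance comment
#'
#' The first line is a `#` comment recording the tool version and a short
#' content hash, so every exported table is traceable; readers skip it.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param what Short content description for the comment.
#' @return `path`, invisibly.
#' @export
write_csv_prov <- function(df, path, what = "table") {
  ver <- as.character(utils::packageVersion("nucquant"))
  hash <- sum(utf8ToInt(paste(utils::capture.output(utils::str(df)),
                              collapse = ""))) %% 100000L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nucquant %s | %s | hash %05d", ver, what, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a phase-annotated track table from CSV
#'
#' Validates required columns and phase labels, sorts by track and time,
#' and warns on nonuniform frame intervals (the per-track interval is
#' attached as attribute `"intervals"`).
#'
#' @param path CSV path (lines starting with `#` are skipped).
#' @return data.frame with `track_id`, `frame`, `time_min`, `phase`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "time_min", "phase")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("track CSV lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!df$phase %in% MITOTIC_PHASES)
  if (length(bad))
    stop("unknown phase token '", df$phase[bad[1]], "' at row ", bad[1],
         " (allowed: ", paste(MITOTIC_PHASES, collapse = ", "), ")")
  df <- df[order(df$track_id, df$time_min), need]
  rownames(df) <- NULL
  ints <- tapply(df$time_min, df$track_id, function(t)
    if (length(t) > 1) unique(round(diff(t), 9)) else numeric(0))
  if (any(vapply(ints, length, 1L) > 1))
    warning("nonuniform frame interval in track(s): ",
            paste(names(ints)[vapply(ints, length, 1L) > 1], collapse = ", "))
  attr(df, "intervals") <- ints
  df
}

#' Write a track table to CSV with provenance comment
#' @param tracks Track table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write_csv_prov(tracks[, c("track_id", "frame", "time_min", "phase")],
                 path, "phase-annotated tracks")
}
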