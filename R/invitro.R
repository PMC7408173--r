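#' Parameters for DNA-staining void ("hole") detection
#'
#' A nucleus is called hole-positive when it contains at least one interior
#' connected region whose blurred chromatin intensity falls below
#' `void_intensity_fraction` of the in-nucleus median and whose area is at
#' least `min_void_px2`. The threshold is relative, so the call is invariant
#' to global intensity scaling. These formalize, with declared tunable
#' constants, a phenotype that is scored visually at the bench.
#'
#' @param void_intensity_fraction Fraction of the nuclear median (default
#'   0.35) below which a pixel counts as void.
#' @param min_void_px2 Minimum void area (default 100).
#' @param blur_sigma_px Gaussian blur before thresholding (default 1.5).
#' @return A `hole_params` object.
#' @export
hole_params <- function(void_intensity_fraction = 0.35, min_void_px2 = 100,
                        blur_sigma_px = 1.5) {
  stopifnot(void_intensity_fraction > 0, void_intensity_fraction < 1,
            min_void_px2 > 0, blur_sigma_px > 0)
  structure(list(void_intensity_fraction = void_intensity_fraction,
                 min_void_px2 = min_void_px2, blur_sigma_px = blur_sigma_px),
            class = "hole_params")
}

#' Detect DNA-staining voids in a single chromatin structure
#'
#' @param chromatin Chromatin channel matrix (or `ImageField`).
#' @param mask Logical (or 0/1) nucleus mask; must be non-empty.
#' @param params A [hole_params()].
#' @param channel Channel name when `chromatin` is an `ImageField`.
#' @return List with `has_hole` (logical) and `voids` (data.frame of void
#'   areas and centroids; zero rows when negative).
#' @export
detect_holes <- function(chromatin, mask, params = hole_params(),
                         channel = "chromatin") {
  if (inherits(chromatin, "ImageField"))
    chromatin <- get_channel(chromatin, channel)
  mask <- mask > 0
  stopifnot(is.matrix(chromatin), all(dim(mask) == dim(chromatin)))
  if (!any(mask)) stop("empty nucleus mask")
  size <- dim(chromatin)
  idx <- which(mask)
  co <- arrayInd(idx, size)
  pad <- ceiling(4 * params$blur_sigma_px)
  x0 <- max(1L, min(co[, 1]) - pad); x1 <- min(size[1], max(co[, 1]) + pad)
  y0 <- max(1L, min(co[, 2]) - pad); y1 <- min(size[2], max(co[, 2]) + pad)
  inmask <- matrix(FALSE, x1 - x0 + 1L, y1 - y0 + 1L)
  inmask[cbind(co[, 1] - x0 + 1L, co[, 2] - y0 + 1L)] <- TRUE
  crop <- chromatin[x0:x1, y0:y1, drop = FALSE]
  med <- stats::median(crop[inmask])
  crop[!inmask] <- med  # keep the exterior from bleeding into the interior
  bl <- as_mat(EBImage::gblur(crop, sigma = params$blur_sigma_px))
  cand <- inmask & bl < params$void_intensity_fraction * med
  din <- as_mat(EBImage::distmap(inmask + 0))
  comp <- as_mat(EBImage::bwlabel(cand + 0))
  rows <- list()
  if (max(comp) > 0) {
    for (p in seq_len(max(comp))) {
      pidx <- which(comp == p)
      if (length(pidx) < params$min_void_px2) next
      if (any(din[pidx] <= 1)) next  # not interior
      ij <- arrayInd(pidx, dim(comp))
      rows[[length(rows) + 1L]] <- data.frame(
        void_id = length(rows) + 1L, area_px2 = length(pidx),
        centroid_x = mean(ij[, 1] + x0 - 1), centroid_y = mean(ij[, 2] + y0 - 1))
    }
  }
  voids <- if (length(rows)) do.call(rbind, rows) else
    data.frame(void_id = integer(0), area_px2 = integer(0),
               centroid_x = numeric(0), centroid_y = numeric(0))
  list(has_hole = nrow(voids) > 0, voids = voids)
}

#' Hole detection over a batch of single-structure fields
#'
#' Segments each field (unless true masks are supplied) and applies
#' [detect_holes()] to the largest object.
#'
#' @param fields List of `ImageField`s (e.g., from
#'   [generate_invitro_nuclei()]).
#' @param params A [hole_params()].
#' @param masks Optional list of nucleus masks to use instead of
#'   segmenting.
#' @param seg A [seg_params()] used when segmenting.
#' @param channel Chromatin channel name.
#' @return Logical vector of per-structure hole flags; structures where no
#'   nucleus was found are `NA`.
#' @export
detect_holes_batch <- function(fields, params = hole_params(), masks = NULL,
                               seg = seg_params(), channel = "chromatin") {
  vapply(seq_along(fields), function(i) {
    ch <- get_channel(fields[[i]], channel)
    mask <- if (!is.null(masks)) masks[[i]] > 0 else {
      lab <- segment_nuclei(ch, seg)
      if (max(lab) == 0) return(NA)
      areas <- tabulate(lab[lab > 0])
      lab == which.max(areas)
    }
    detect_holes(ch, mask, params)$has_hole
  }, TRUE)
}

#' Prevalence of hole-positive structures
#'
#' Without grouping, returns the pooled percentage of flagged structures.
#' With `experiment` grouping, returns the mean of per-experiment
#' percentages and their SD, the replicate-averaging convention used for
#' cell-free assay figures (n = experiments, not pooled structures).
#'
#' @param flags Logical vector of per-structure hole calls (`NA` dropped
#'   with a warning).
#' @param experiment Optional grouping vector (same length) of experiment
#'   ids.
#' @return A single percentage, or (grouped) a list with `percent` (mean of
#'   per-experiment percentages), `sd`, and `per_experiment`.
#' @export
holes_prevalence <- function(flags, experiment = NULL) {
  if (!length(flags)) stop("no structures supplied")
  if (anyNA(flags)) {
    warning(sum(is.na(flags)), " structures without a nucleus call dropped")
    keep <- !is.na(flags)
    flags <- flags[keep]
    if (!is.null(experiment)) experiment <- experiment[keep]
  }
  if (is.null(experiment)) return(100 * mean(flags))
  stopifnot(length(experiment) == length(flags))
  per <- vapply(split(flags, experiment), function(f) 100 * mean(f), 1)
  list(percent = mean(per), sd = stats::sd(per),
       per_experiment = per)
}

#' Parameters for dextran penetration scoring
#'
#' @param positive_fraction_threshold Structure is penetration-positive when
#'   its interior dextran mean is at least this fraction of the surrounding
#'   extract mean (default 0.5).
#' @param annulus_inner_px,annulus_outer_px Surrounding-extract annulus
#'   bounds outside the chromatin mask (defaults 5 and 20).
#' @return A `penetration_params` object.
#' @export
penetration_params <- function(positive_fraction_threshold = 0.5,
                               annulus_inner_px = 5, annulus_outer_px = 20) {
  stopifnot(positive_fraction_threshold > 0,
            positive_fraction_threshold <= 1,
            annulus_inner_px >= 0, annulus_outer_px > annulus_inner_px)
  structure(list(positive_fraction_threshold = positive_fraction_threshold,
                 annulus_inner_px = annulus_inner_px,
                 annulus_outer_px = annulus_outer_px),
            class = "penetration_params")
}

#' Score dextran penetration of a chromatin structure
#'
#' A structure is penetration-positive when the mean dextran signal inside
#' the chromatin mask reaches `positive_fraction_threshold` times the mean
#' in a surrounding extract annulus. Excluded structures (intact envelopes
#' keeping large dextrans out) score negative. The call is invariant to
#' global intensity scaling and monotone in the threshold.
#'
#' @param dextran Dextran channel matrix (or `ImageField`).
#' @param mask Chromatin structure mask.
#' @param params A [penetration_params()].
#' @param channel Channel name when `dextran` is an `ImageField`.
#' @return List with `positive` (logical; `NA` with `flagged = TRUE` when
#'   the annulus is empty), `ratio` (interior/annulus mean), `flagged`.
#' @export
dextran_penetration <- function(dextran, mask,
                                params = penetration_params(),
                                channel = "dextran") {
  if (inherits(dextran, "ImageField"))
    dextran <- get_channel(dextran, channel)
  mask <- mask > 0
  stopifnot(is.matrix(dextran), all(dim(mask) == dim(dextran)))
  if (!any(mask)) stop("empty chromatin mask")
  dout <- as_mat(EBImage::distmap(1 - (mask + 0)))
  ann <- !mask & dout > params$annulus_inner_px &
    dout <= params$annulus_outer_px
  if (!any(ann))
    return(list(positive = NA, ratio = NA_real_, flagged = TRUE))
  inside <- mean(dextran[mask])
  around <- mean(dextran[ann])
  ratio <- if (around > 0) inside / around else NA_real_
  list(positive = if (is.na(ratio)) NA else
         ratio >= params$positive_fraction_threshold,
       ratio = ratio, flagged = is.na(ratio))
}

#' Population percentage of dextran-penetrated structures
#'
#' @param fields List of `ImageField`s carrying a dextran channel.
#' @param masks List of chromatin masks (same length).
#' @param params A [penetration_params()].
#' @param channel Dextran channel name.
#' @return List with `percent`, `calls` (per-structure logical) and
#'   `ratios`.
#' @export
dextran_penetration_batch <- function(fields, masks,
                                      params = penetration_params(),
                                      channel = "dextran") {
  stopifnot(length(fields) == length(masks))
  res <- lapply(seq_along(fields), function(i)
    dextran_penetration(fields[[i]], masks[[i]], params, channel))
  calls <- vapply(res, `[[`, NA, "positive")
  list(percent = 100 * mean(calls, na.rm = TRUE),
       calls = calls,
       ratios = vapply(res, `[[`, NA_real_, "ratio"))
}
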