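#' Segmentation parameters
#'
#' The segmentation recipe follows the primary-object idiom of interactive
#' image-analysis pipelines: Gaussian smoothing, global Otsu threshold on the
#' normalized intensity histogram, hole filling (so nucleolar voids do not
#' perforate the nuclear outline), 4-connected component labeling, and a
#' minimum-area filter. Objects touching the field border are dropped by
#' default because their derived ROIs would extend off-field.
#'
#' @param gaussian_sigma_px Smoothing sigma before thresholding.
#' @param min_area_px2 Minimum object area kept.
#' @param drop_border Drop objects touching the field border.
#' @return A `seg_params` object.
#' @export
seg_params <- function(gaussian_sigma_px = 2, min_area_px2 = 500,
                       drop_border = TRUE) {
  stopifnot(gaussian_sigma_px > 0, min_area_px2 > 0)
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 min_area_px2 = min_area_px2, drop_border = drop_border),
            class = "seg_params")
}

#' ROI geometry parameters
#'
#' Distances (in px) defining the three ROIs derived from each nuclear
#' outline: the chromatin periphery band (annulus between the outline and
#' its `periphery_shrink_px` shrink), the cytoplasm background ring
#' (between the `background_inner_px` and `background_outer_px` expansions)
#' and the nuclear-envelope toroid (`ne_halfwidth_px` to either side of the
#' outline). All shrinks/expansions use the Euclidean distance transform.
#'
#' @param periphery_shrink_px Band width (default 20).
#' @param background_inner_px,background_outer_px Ring bounds (default 5, 20).
#' @param ne_halfwidth_px Toroid half-width (default 5).
#' @return A `roi_params` object.
#' @export
roi_params <- function(periphery_shrink_px = 20, background_inner_px = 5,
                       background_outer_px = 20, ne_halfwidth_px = 5) {
  stopifnot(periphery_shrink_px > 0, background_inner_px > 0,
            background_outer_px > background_inner_px, ne_halfwidth_px > 0)
  structure(list(periphery_shrink_px = periphery_shrink_px,
                 background_inner_px = background_inner_px,
                 background_outer_px = background_outer_px,
                 ne_halfwidth_px = ne_halfwidth_px),
            class = "roi_params")
}

#' Segment nuclei from a chromatin channel
#'
#' @param chromatin Numeric matrix (single channel) or an `ImageField`; for
#'   a field the channel named by `channel` is used.
#' @param params A [seg_params()].
#' @param channel Channel name when `chromatin` is an `ImageField`.
#' @return Integer label matrix (0 = background, k > 0 = nucleus k, labels
#'   consecutive) with attribute `provenance` recording the parameters.
#' @export
segment_nuclei <- function(chromatin, params = seg_params(),
                           channel = "chromatin") {
  if (inherits(chromatin, "ImageField"))
    chromatin <- get_channel(chromatin, channel)
  stopifnot(is.matrix(chromatin), is.numeric(chromatin),
            all(chromatin >= 0, na.rm = TRUE))
  rng <- range(chromatin, finite = TRUE)
  out_attr <- list(params = params, channel = channel)
  if (diff(rng) == 0) {
    warning("constant chromatin channel: no nuclei segmented")
    lab <- matrix(0L, nrow(chromatin), ncol(chromatin))
    attr(lab, "provenance") <- out_attr
    return(lab)
  }
  # normalize so Otsu sees a [0,1] histogram: intensity-scale invariant
  norm <- (chromatin - rng[1]) / diff(rng)
  sm <- as_mat(EBImage::gblur(norm, sigma = params$gaussian_sigma_px))
  sm <- pmin(pmax(sm, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- as_mat(EBImage::fillHull((sm > thr) + 0)) > 0
  lab <- as_mat(EBImage::bwlabel(mask + 0))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < params$min_area_px2)
    if (params$drop_border) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      drop <- union(drop, border[border > 0])
    }
    if (length(drop)) lab[lab %in% drop] <- 0
    # relabel to consecutive positive integers
    keep <- sort(unique(lab[lab > 0]))
    if (length(keep)) {
      remap <- integer(max(keep))
      remap[keep] <- seq_along(keep)
      pos <- lab > 0
      lab[pos] <- remap[lab[pos]]
    }
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  attr(lab, "provenance") <- out_attr
  lab
}

#' Derive per-nucleus measurement ROIs from a label map
#'
#' For each nucleus the Euclidean distance transform yields: the periphery
#' band (pixels within `periphery_shrink_px` of the outline, inside), the
#' cytoplasm background ring (outside pixels between the inner and outer
#' expansions, excluding pixels within the outer expansion of any other
#' nucleus), and the nuclear-envelope toroid (pixels within
#' `ne_halfwidth_px` of the outline on either side). A nucleus too small to
#' contain a band interior is flagged degenerate and its band equals the
#' whole mask.
#'
#' @param labels Integer label matrix from [segment_nuclei()] (or ground
#'   truth).
#' @param params A [roi_params()].
#' @return An object of class `RoiSet`: a list with `dim` and `rois`, the
#'   latter one entry per nucleus holding integer pixel-index vectors
#'   `nuclear`, `periphery_band`, `cytoplasm_ring`, `ne_toroid` and a
#'   `degenerate` flag.
#' @export
derive_rois <- function(labels, params = roi_params()) {
  stopifnot(is.matrix(labels))
  size <- dim(labels)
  ids <- sort(unique(labels[labels > 0]))
  shrink <- params$periphery_shrink_px
  inner <- params$background_inner_px
  outer <- params$background_outer_px
  ne <- params$ne_halfwidth_px
  pre <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    idx <- which(labels == ids[k])
    co <- arrayInd(idx, size)
    pad <- ceiling(outer + ne + 2)
    x0 <- max(1L, min(co[, 1]) - pad); x1 <- min(size[1], max(co[, 1]) + pad)
    y0 <- max(1L, min(co[, 2]) - pad); y1 <- min(size[2], max(co[, 2]) + pad)
    sub <- matrix(0, x1 - x0 + 1L, y1 - y0 + 1L)
    sub[cbind(co[, 1] - x0 + 1L, co[, 2] - y0 + 1L)] <- 1
    din <- as_mat(EBImage::distmap(sub))
    dout <- as_mat(EBImage::distmap(1 - sub))
    loc <- function(cond) {
      ij <- which(cond, arr.ind = TRUE)
      as.integer((y0 + ij[, 2] - 2L) * size[1] + (x0 + ij[, 1] - 1L))
    }
    degenerate <- !any(din > shrink)
    pre[[k]] <- list(
      nucleus_id = ids[k],
      nuclear = idx,
      periphery_band = if (degenerate) idx else loc(sub > 0 & din <= shrink),
      cytoplasm_ring = loc(sub == 0 & dout > inner & dout <= outer),
      ne_toroid = loc((sub > 0 & din <= ne) | (sub == 0 & dout <= ne)),
      expand_outer = loc(sub > 0 | dout <= outer),
      degenerate = degenerate)
  }
  # exclude, from each ring, pixels claimed by any other nucleus's outer
  # expansion (background estimates must not bleed across neighbors)
  rings <- lapply(seq_along(pre), function(k) {
    others <- unlist(lapply(pre[-k], `[[`, "expand_outer"), use.names = FALSE)
    setdiff(pre[[k]]$cytoplasm_ring, others)
  })
  for (k in seq_along(pre)) {
    pre[[k]]$cytoplasm_ring <- rings[[k]]
    pre[[k]]$expand_outer <- NULL
  }
  structure(list(dim = size, rois = pre, params = params), class = "RoiSet")
}

#' @export
print.RoiSet <- function(x, ...) {
  cat("<RoiSet> ", length(x$rois), " nuclei on a ",
      paste(x$dim, collapse = " x "), " px field (",
      sum(vapply(x$rois, `[[`, TRUE, "degenerate")), " degenerate)\n",
      sep = "")
  invisible(x)
}

#' Render a RoiSet as a coded label matrix for one nucleus
#'
#' Codes: 1 = nuclear interior (outside band), 2 = periphery band,
#' 3 = cytoplasm ring, 4 = NE toroid (overwrites overlapping codes).
#'
#' @param rois A `RoiSet`.
#' @param nucleus_id Which nucleus to render.
#' @return Integer matrix.
#' @export
roi_codes <- function(rois, nucleus_id) {
  stopifnot(inherits(rois, "RoiSet"))
  r <- NULL
  for (e in rois$rois) if (e$nucleus_id == nucleus_id) r <- e
  if (is.null(r)) stop("nucleus_id ", nucleus_id, " not in RoiSet")
  m <- matrix(0L, rois$dim[1], rois$dim[2])
  m[r$nuclear] <- 1L
  m[r$periphery_band] <- 2L
  m[r$cytoplasm_ring] <- 3L
  m[r$ne_toroid] <- 4L
  m
}
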