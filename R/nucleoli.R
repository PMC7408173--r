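#' Parameters for nucleolus-as-chromatin-hole detection
#'
#' Mirrors the manual Fiji workflow for detecting nucleoli as intensity
#' voids in a chromatin (H2B/DAPI) image: 8-bit conversion, Gaussian blur
#' (sigma 1.5), Otsu auto-threshold, LUT inversion, particle analysis. The
#' conversion rescales per nucleus (min-max), the threshold runs per
#' nucleus, and a minimum Otsu class-separation (`min_separation`, the
#' between-class share of variance at the chosen threshold) guards against
#' spurious particles in nuclei whose histogram is effectively unimodal.
#'
#' @param gaussian_sigma_px Blur sigma (default 1.5).
#' @param min_particle_px2 Minimum accepted particle area (default 20).
#' @param max_particle_fraction Maximum particle area as a fraction of the
#'   nucleus area (default 0.5).
#' @param min_separation Minimum Otsu between-class variance fraction in
#'   `(0, 1)`; below it the nucleus is flagged `weak_bimodality` and yields
#'   0 nucleoli (default 0.8).
#' @return A `nucleoli_params` object.
#' @export
nucleoli_params <- function(gaussian_sigma_px = 1.5, min_particle_px2 = 20,
                            max_particle_fraction = 0.5,
                            min_separation = 0.8) {
  stopifnot(gaussian_sigma_px > 0, min_particle_px2 > 0,
            max_particle_fraction > 0, max_particle_fraction <= 1,
            min_separation > 0, min_separation < 1)
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 min_particle_px2 = min_particle_px2,
                 max_particle_fraction = max_particle_fraction,
                 min_separation = min_separation),
            class = "nucleoli_params")
}

# Otsu threshold on 8-bit values plus its between-class variance fraction
otsu_8bit <- function(v) {
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h) / n
  mu <- cumsum(h * lev) / n
  mu_t <- mu[256]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  tot <- sum(h * (lev - mu_t)^2) / n
  list(threshold = lev[k],
       separation = if (tot > 0) sb2[k] / tot else 0)
}

#' Detect nucleoli as chromatin voids within segmented nuclei
#'
#' Per nucleus: rescale the chromatin intensities inside the nucleus to
#' 8-bit (min-max), blur, Otsu-threshold, and take the *inverted* (dark)
#' class as candidate particles; label 4-connected components and keep those
#' with `min_particle_px2 <= area <= max_particle_fraction * nucleus area`
#' that do not touch the nuclear boundary. The blur serves detection only:
#' particle pixels and areas are measured on the unblurred 8-bit values
#' within each detected component, so the blur neither inflates
#' sub-resolution dips nor erodes genuine voids. Pixels outside the nucleus
#' are padded with the in-nucleus median before blurring so the boundary
#' does not bleed into the void class.
#'
#' @param field An `ImageField` (or a plain chromatin matrix).
#' @param labels Integer nucleus label matrix from the same field.
#' @param params A [nucleoli_params()].
#' @param chromatin Chromatin channel name when `field` is an `ImageField`.
#' @param invert Detect the dark class (default). `invert = FALSE` detects
#'   the bright class; running with `invert = FALSE` on the negated image
#'   reproduces the default particle set (inversion duality).
#' @return List with `labels` (integer nucleolus label matrix, ids global
#'   across nuclei), `records` (data.frame: `nucleus_id`, `nucleolus_id`,
#'   `area_px2`, `centroid_x`, `centroid_y`, and `mean_<channel>` per
#'   channel when a field is supplied) and `flags` (per-nucleus data.frame
#'   with `n_nucleoli` and `weak_bimodality`).
#' @export
nucleoli_masks <- function(field, labels, params = nucleoli_params(),
                           chromatin = "chromatin", invert = TRUE) {
  chrom <- if (inherits(field, "ImageField"))
    get_channel(field, chromatin) else field
  stopifnot(is.matrix(chrom), is.matrix(labels),
            all(dim(chrom) == dim(labels)))
  size <- dim(chrom)
  ids <- sort(unique(labels[labels > 0]))
  out_lab <- matrix(0L, size[1], size[2])
  recs <- list()
  flags <- list()
  next_id <- 0L
  for (i in ids) {
    idx <- which(labels == i)
    co <- arrayInd(idx, size)
    pad <- ceiling(4 * params$gaussian_sigma_px)
    x0 <- max(1L, min(co[, 1]) - pad); x1 <- min(size[1], max(co[, 1]) + pad)
    y0 <- max(1L, min(co[, 2]) - pad); y1 <- min(size[2], max(co[, 2]) + pad)
    inmask <- matrix(FALSE, x1 - x0 + 1L, y1 - y0 + 1L)
    inmask[cbind(co[, 1] - x0 + 1L, co[, 2] - y0 + 1L)] <- TRUE
    vals <- chrom[idx]
    rngv <- range(vals)
    if (diff(rngv) < 1 / 255) {  # near-constant: no 8-bit contrast
      flags[[length(flags) + 1L]] <- data.frame(
        nucleus_id = i, n_nucleoli = 0L, weak_bimodality = TRUE)
      next
    }
    crop <- chrom[x0:x1, y0:y1, drop = FALSE]
    q8 <- round(pmin(pmax((crop - rngv[1]) / diff(rngv), 0), 1) * 255)
    q8[!inmask] <- stats::median(q8[inmask])
    bl <- as_mat(EBImage::gblur(q8 / 255, sigma = params$gaussian_sigma_px))
    bl8 <- as.integer(round(pmin(pmax(bl, 0), 1) * 255))
    ot <- otsu_8bit(bl8[inmask])
    if (ot$separation < params$min_separation) {
      flags[[length(flags) + 1L]] <- data.frame(
        nucleus_id = i, n_nucleoli = 0L, weak_bimodality = TRUE)
      next
    }
    bl8m <- matrix(bl8, nrow(q8), ncol(q8))
    # inversion selects the dark (void) class; invert = FALSE selects the
    # bright class, so the recipe on a negated image gives the same set
    dark <- (if (invert) bl8m <= ot$threshold else bl8m > ot$threshold) & inmask
    # blur serves detection only; particle extent is measured on the
    # unblurred 8-bit values, so sub-resolution dips are not inflated
    raw_dark <- (if (invert) q8 <= ot$threshold else q8 > ot$threshold) & inmask
    # particles touching the nuclear boundary are background leakage
    din <- as_mat(EBImage::distmap(inmask + 0))
    comp <- as_mat(EBImage::bwlabel(dark + 0))
    n_found <- 0L
    if (max(comp) > 0) {
      for (p in seq_len(max(comp))) {
        detected <- which(comp == p)
        if (any(din[detected] <= 1)) next  # touches boundary
        pidx <- detected[raw_dark[detected]]
        if (length(pidx) < params$min_particle_px2) next
        if (length(pidx) > params$max_particle_fraction * length(idx)) next
        ij <- arrayInd(pidx, dim(comp))
        gx <- ij[, 1] + x0 - 1L; gy <- ij[, 2] + y0 - 1L
        gidx <- (gy - 1L) * size[1] + gx
        next_id <- next_id + 1L
        n_found <- n_found + 1L
        out_lab[gidx] <- next_id
        rec <- data.frame(nucleus_id = i, nucleolus_id = next_id,
                          area_px2 = length(gidx),
                          centroid_x = mean(gx), centroid_y = mean(gy))
        if (inherits(field, "ImageField"))
          for (ch in names(field$channels))
            rec[[paste0("mean_", ch)]] <- mean(field$channels[[ch]][gidx])
        recs[[length(recs) + 1L]] <- rec
      }
    }
    flags[[length(flags) + 1L]] <- data.frame(
      nucleus_id = i, n_nucleoli = n_found, weak_bimodality = FALSE)
  }
  list(labels = out_lab,
       records = if (length(recs)) do.call(rbind, recs) else NULL,
       flags = if (length(flags)) do.call(rbind, flags) else
         data.frame(nucleus_id = integer(0), n_nucleoli = integer(0),
                    weak_bimodality = logical(0)))
}

#' Nucleolar fraction of a marker signal
#'
#' Ratio of the summed marker signal inside a nucleus's nucleoli to the
#' summed signal over the whole nucleus; lies in `[0, 1]` for nonnegative
#' channels and is invariant to channel scaling.
#'
#' @param field An `ImageField` (or a marker matrix).
#' @param nucleolus_labels Nucleolus label matrix from [nucleoli_masks()].
#' @param labels Nucleus label matrix.
#' @param channel Marker channel name when `field` is an `ImageField`.
#' @return data.frame with `nucleus_id`, `nucleolar_fraction`, and
#'   `undefined` (TRUE when the total nuclear signal is zero).
#' @export
nucleolar_fraction <- function(field, nucleolus_labels, labels,
                               channel = NULL) {
  marker <- if (inherits(field, "ImageField")) {
    if (is.null(channel)) stop("channel required for an ImageField")
    get_channel(field, channel)
  } else field
  stopifnot(is.matrix(marker), all(dim(marker) == dim(labels)),
            all(dim(nucleolus_labels) == dim(labels)))
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(i) {
    nuc <- labels == i
    tot <- sum(marker[nuc])
    inside <- sum(marker[nuc & nucleolus_labels > 0])
    data.frame(nucleus_id = i,
               nucleolar_fraction = if (tot == 0) NA_real_ else inside / tot,
               undefined = tot == 0)
  })
  do.call(rbind, rows)
}
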