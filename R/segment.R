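# Nucleus segmentation
# --------------------
# Nuclei are segmented per frame from the nuclear-marker channel: Gaussian
# smoothing in physical units, per-frame Otsu (or fixed) thresholding, and
# splitting of touching nuclei by a distance-transform-seeded watershed:
# seeds are 3D local maxima of the anisotropic depth map (suppressed below
# a minimum physical separation) and each connected component is divided
# among its seeds by proximity.  Objects are flagged, never deleted, so
# downstream stages decide what to exclude.

#' Segmentation parameters
#'
#' @param smoothing_sigma_um Gaussian smoothing bandwidth (um) applied to
#'   the marker before thresholding.
#' @param threshold_method `"otsu"` (per frame, on the smoothed marker) or
#'   `"fixed"`.
#' @param threshold_value absolute threshold (detector units) for
#'   `"fixed"`.
#' @param min_volume_um3,max_volume_um3 volume bounds; objects outside are
#'   flagged `too_small` / `too_large`.
#' @param seed_min_distance_um minimum physical separation (um) between
#'   watershed seeds; local maxima of the depth map closer than this to a
#'   deeper maximum are suppressed, so a nucleus yields a single seed while
#'   touching nuclei keep one each.
#' @param border_margin_vox objects whose bounding box comes within this
#'   many voxels of the lateral field border are flagged `border`.
#' @param mitotic_solidity_cutoff objects with solidity strictly below this
#'   are flagged `mitotic` by [flag_mitotic()].
#' @param mitotic_contrast_cutoff objects whose marker nucleus/perinuclear
#'   intensity ratio is strictly below this are flagged `mitotic`.
#' @param max_mask_fraction if thresholding selects more than this fraction
#'   of the field, the frame is treated as containing no separable nuclei
#'   (prevents spurious detections on blank or fully dispersed frames).
#' @export
segmentation_params <- function(smoothing_sigma_um = 1,
                                threshold_method = c("otsu", "fixed"),
                                threshold_value = NULL,
                                min_volume_um3 = 50,
                                max_volume_um3 = 8000,
                                seed_min_distance_um = 5,
                                border_margin_vox = 1,
                                mitotic_solidity_cutoff = 0.6,
                                mitotic_contrast_cutoff = 1.5,
                                max_mask_fraction = 0.35) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(threshold_value))
    stop("threshold_value required for fixed thresholding")
  stopifnot(min_volume_um3 < max_volume_um3, smoothing_sigma_um >= 0)
  structure(list(smoothing_sigma_um = smoothing_sigma_um,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_volume_um3 = min_volume_um3,
                 max_volume_um3 = max_volume_um3,
                 seed_min_distance_um = seed_min_distance_um,
                 border_margin_vox = border_margin_vox,
                 mitotic_solidity_cutoff = mitotic_solidity_cutoff,
                 mitotic_contrast_cutoff = mitotic_contrast_cutoff,
                 max_mask_fraction = max_mask_fraction),
            class = "segmentation_params")
}

# Otsu threshold of a numeric vector (EBImage's implementation, applied to
# the flattened volume so one threshold serves the whole frame)
.otsu_threshold <- function(v) {
  rg <- range(v)
  if (rg[1] == rg[2]) return(rg[2]) # constant image: nothing above
  img <- EBImage::Image(matrix((v - rg[1]) / (rg[2] - rg[1]), ncol = 1))
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
  rg[1] + th * (rg[2] - rg[1])
}

# Distance-transform-seeded splitting of a binary mask.  Seeds are 26-
# connected local maxima of the anisotropic depth map (distance to
# background, um); maxima within min_sep_um of a deeper one are suppressed
# (ties resolve in (z, y, x) raster order).  Each 6-connected component is
# then partitioned among its seeds by anisotropic proximity; components
# without a surviving seed keep a single label.
.split_by_depth <- function(mask, spacing, min_sep_um) {
  d <- dim(mask)
  depth <- .depth_map(mask, spacing)
  comp <- label_components(mask)
  is_max <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (d[3] == 1 && dz != 0) next
    is_max <- is_max & (depth >= .shift3(depth, dy, dx, dz))
  }
  # discard shallow maxima (necks/bridges between touching nuclei): a
  # genuine nucleus seed sits at least min_sep/2 um from the background
  # and at least half as deep as the deepest seed of its component
  cand <- which(is_max & depth >= min_sep_um / 2)
  if (length(cand) == 0) return(comp)
  cmax <- tapply(depth[cand], comp[cand], max)
  cand <- cand[depth[cand] >= 0.5 * cmax[as.character(comp[cand])]]
  ai <- arrayInd(cand, d)
  sp_dims <- .spacing_dims(spacing)
  pos <- sweep(ai - 1, 2, sp_dims, `*`) # um, (y, x, z)
  ord <- order(-depth[cand], ai[, 3], ai[, 1], ai[, 2])
  cand <- cand[ord]; pos <- pos[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_along(cand)) {
    if (length(kept)) {
      q <- pos[kept, , drop = FALSE]
      if (any(colSums((t(q) - pos[i, ])^2) < min_sep_um^2)) next
    }
    kept <- c(kept, i)
  }
  seeds <- cand[kept]; spos <- pos[kept, , drop = FALSE]
  seed_comp <- comp[seeds]
  out <- array(0L, d)
  next_lab <- 0L
  for (cc in sort(unique(comp[comp > 0L]))) {
    vox <- which(comp == cc)
    s <- which(seed_comp == cc)
    if (length(s) <= 1L) {
      next_lab <- next_lab + 1L
      out[vox] <- next_lab
    } else {
      vai <- arrayInd(vox, d)
      vpos <- sweep(vai - 1, 2, sp_dims, `*`)
      d2 <- vapply(s, function(si)
        colSums((t(vpos) - spos[si, ])^2), numeric(length(vox)))
      d2 <- matrix(d2, nrow = length(vox))
      nearest <- max.col(-d2, ties.method = "first")
      out[vox] <- next_lab + nearest
      next_lab <- next_lab + length(s)
    }
  }
  out
}

# depth map of a mask: anisotropic distance to the nearest background
# voxel, with the field border itself counting as background (a nucleus
# cut by the field of view must not gain spurious depth at the edge)
.depth_map <- function(mask, spacing) {
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(TRUE, dp) # background sites
  padded[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] <- !mask
  if (d[3] == 1L) { # single-plane image: no z-borders
    padded[, , 1] <- FALSE; padded[, , 3] <- FALSE
  }
  full <- distance_transform(padded, spacing)
  depth <- full[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1), drop = FALSE]
  dim(depth) <- d
  depth[!mask] <- 0
  depth
}

# moment-based solidity proxy: object volume over the volume of the
# uniform ellipsoid with the same second moments (1 for a solid ellipsoid,
# < 1 for ragged or fragmented shapes).  A per-axis variance of
# spacing^2/12 (uniform within a voxel) regularises flat objects.
.solidity <- function(coords_um, spacing, n) {
  v <- apply(coords_um, 2, function(x) sum((x - mean(x))^2) / n)
  v <- v + (spacing^2) / 12
  vol_ell <- 4 / 3 * pi * prod(sqrt(5 * v))
  min(1, n * prod(spacing) / vol_ell)
}

#' Segment nuclei in one frame
#'
#' @param movie a [multichannel_movie()].
#' @param frame 1-based frame index.
#' @param marker_channel channel carrying the broad nuclear marker used for
#'   segmentation.
#' @param params a [segmentation_params()].
#' @return list of class `nucleus_segmentation` with `labels` (integer
#'   array (y, x, z)), `nuclei` (a `nuclei` [measurement_table()]:
#'   geometry, solidity, QC flags) and `intensity` (a `nucleus_intensity`
#'   table with per-channel mean and summed intensity per label).  A frame
#'   with nothing segmentable yields zero rows, which is not an error.
#' @export
segment_nuclei_frame <- function(movie, frame, marker_channel,
                                 params = segmentation_params()) {
  stopifnot(inherits(movie, "multichannel_movie"))
  vol <- movie_volume(movie, marker_channel, frame)
  sp <- movie$spacing
  d <- dim(vol)
  sm <- if (params$smoothing_sigma_um > 0)
    gaussian_smooth(vol, params$smoothing_sigma_um, sp) else vol
  if (params$threshold_method == "otsu") {
    # two-stage Otsu: the first split may separate embryo from mounting
    # medium rather than nuclei from cytoplasm.  If the selected voxels are
    # themselves strongly bimodal (between-class variance ratio of a second
    # split > 0.7), adopt the second threshold.
    th <- .otsu_threshold(as.numeric(sm))
    mask <- sm > th
    if (any(mask)) {
      v <- as.numeric(sm[mask])
      th2 <- .otsu_threshold(v)
      hi <- v > th2
      w2 <- mean(hi)
      if (w2 > 0 && w2 < 1) {
        eta2 <- (1 - w2) * w2 * (mean(v[hi]) - mean(v[!hi]))^2 / var(v)
        if (!is.na(eta2) && eta2 > 0.7) {
          th <- th2
          mask <- sm > th
        }
      }
    }
  } else {
    th <- params$threshold_value
    mask <- sm > th
  }

  empty <- function() {
    nuclei <- measurement_table(
      data.frame(frame = integer(), label = integer(),
                 centroid_z_um = numeric(), centroid_y_um = numeric(),
                 centroid_x_um = numeric(), volume_um3 = numeric(),
                 solidity = numeric(), qc_flags = character()), "nuclei")
    intensity <- measurement_table(
      data.frame(frame = integer(), label = integer(),
                 channel = character(), mean_intensity = numeric(),
                 sum_intensity = numeric()), "nucleus_intensity")
    structure(list(labels = array(0L, d), nuclei = nuclei,
                   intensity = intensity, frame = frame),
              class = "nucleus_segmentation")
  }
  if (!any(mask) || mean(mask) > params$max_mask_fraction) return(empty())

  # split touching nuclei: distance-transform-seeded watershed
  lab <- .split_by_depth(mask, sp, params$seed_min_distance_um)
  # tighten to the raw marker: smoothing inflates the mask by a
  # partial-volume shell of cytoplasm that would dilute nuclear means
  lab[vol <= th] <- 0L
  nlab <- max(lab)
  if (nlab == 0L) return(empty())
  # a frame whose components are all below the minimum nucleus volume
  # (noise specks) or all above the maximum (an undivided embryo region on
  # a fully dispersed mitotic frame) contains nothing nucleus-like
  voxvol0 <- prod(sp)
  sizes <- tabulate(lab[lab > 0L])
  sizes <- sizes[sizes > 0]
  if (max(sizes) * voxvol0 < params$min_volume_um3 ||
      min(sizes) * voxvol0 > params$max_volume_um3)
    return(empty())

  idx <- which(lab > 0L)
  labv <- lab[idx]
  ai <- arrayInd(idx, d)
  voxvol <- prod(sp)
  sp_dims <- .spacing_dims(sp) # (y, x, z)

  chans <- names(movie$channels)
  rows <- vector("list", nlab)
  irows <- vector("list", nlab)
  split_idx <- split(seq_along(idx), labv)
  keep_labels <- as.integer(names(split_idx))
  for (j in seq_along(split_idx)) {
    sel <- split_idx[[j]]
    L <- keep_labels[j]
    n <- length(sel)
    coords <- ai[sel, , drop = FALSE]
    coords_um <- sweep(coords - 1, 2, sp_dims, `*`)
    cen <- colMeans(coords_um) # (y, x, z)
    volume <- n * voxvol
    sol <- .solidity(coords_um, sp_dims, n)
    flags <- character()
    if (volume < params$min_volume_um3) flags <- c(flags, "too_small")
    if (volume > params$max_volume_um3) flags <- c(flags, "too_large")
    m <- params$border_margin_vox
    if (any(coords[, 1] <= m) || any(coords[, 1] > d[1] - m) ||
        any(coords[, 2] <= m) || any(coords[, 2] > d[2] - m))
      flags <- c(flags, "border")
    rows[[j]] <- data.frame(
      frame = frame, label = L,
      centroid_z_um = cen[3], centroid_y_um = cen[1],
      centroid_x_um = cen[2], volume_um3 = volume, solidity = sol,
      qc_flags = paste(flags, collapse = ";"))
    vox <- idx[sel]
    irows[[j]] <- data.frame(
      frame = frame, label = L, channel = chans,
      mean_intensity = vapply(chans, function(cn)
        mean(movie$channels[[cn]][, , , frame][vox]), numeric(1)),
      sum_intensity = vapply(chans, function(cn)
        sum(as.numeric(movie$channels[[cn]][, , , frame][vox])), numeric(1)),
      row.names = NULL)
  }
  structure(list(labels = lab,
                 nuclei = measurement_table(do.call(rbind, rows), "nuclei"),
                 intensity = measurement_table(do.call(rbind, irows),
                                               "nucleus_intensity"),
                 frame = frame),
            class = "nucleus_segmentation")
}

#' Flag mitotic objects
#'
#' An object is flagged `mitotic` when its solidity is strictly below the
#' cutoff or its marker nucleus/perinuclear contrast (mean intensity inside
#' the label over mean intensity in a 2 um shell around it) is strictly
#' below the contrast cutoff.  Order and count of records are preserved.
#'
#' @param seg a `nucleus_segmentation` from [segment_nuclei_frame()].
#' @param movie the movie the segmentation came from.
#' @param marker_channel marker channel name.
#' @param params a [segmentation_params()].
#' @return `seg` with updated `qc_flags`.
#' @export
flag_mitotic <- function(seg, movie, marker_channel,
                         params = segmentation_params()) {
  stopifnot(inherits(seg, "nucleus_segmentation"))
  nuc <- seg$nuclei
  if (nrow(nuc) == 0) return(seg)
  vol <- movie_volume(movie, marker_channel, seg$frame)
  for (i in seq_len(nrow(nuc))) {
    L <- nuc$label[i]
    shell <- .ring_indices(seg$labels, L, movie$spacing,
                           outer_um = 2, inner_um = 0,
                           exclude_all = FALSE)
    contrast <- if (length(shell) == 0) Inf else {
      nm <- seg$intensity$mean_intensity[
        seg$intensity$label == L &
          seg$intensity$channel == marker_channel]
      nm / mean(vol[shell])
    }
    if (nuc$solidity[i] < params$mitotic_solidity_cutoff ||
        contrast < params$mitotic_contrast_cutoff) {
      fl <- strsplit(nuc$qc_flags[i], ";", fixed = TRUE)[[1]]
      fl <- unique(c(fl[nzchar(fl)], "mitotic"))
      nuc$qc_flags[i] <- paste(fl, collapse = ";")
    }
  }
  seg$nuclei <- nuc
  seg
}

#' Estimate the far-field background level
#'
#' The background of a channel in one frame is the median intensity of all
#' voxels farther than `outer_um` (default: the outer cytoplasmic-ring
#' radius) from every nucleus, so background never overlaps any compartment
#' used for measurement.  Deterministic.
#'
#' @param movie a [multichannel_movie()].
#' @param frame frame index.
#' @param channel channel name.
#' @param labels integer label array (y, x, z) of the frame's nuclei.
#' @param outer_um exclusion radius around nuclei (um).
#' @return background level in detector units.
#' @export
estimate_background <- function(movie, frame, channel, labels,
                                outer_um = 8.3) {
  vol <- movie_volume(movie, channel, frame)
  if (any(labels > 0L)) {
    dist <- distance_transform(labels > 0L, movie$spacing)
    eligible <- dist > outer_um
  } else {
    eligible <- array(TRUE, dim(vol))
  }
  n <- sum(eligible)
  if (n < 1000)
    stop("degenerate-field: only ", n, " voxels beyond ", outer_um,
         " um of all nuclei; cannot estimate background")
  median(vol[eligible])
}
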