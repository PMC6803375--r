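# Cytoplasmic ring masks and N/C ratios
# -------------------------------------
# The cytoplasmic signal of a nucleus is sampled in an annulus at a fixed
# physical distance from the nucleus surface: voxels farther than the inner
# exclusion zone but within the outer radius, excluding every nuclear mask
# and (by default) the inner halo of every other nucleus as well.  "Distance
# from the nucleus" is the anisotropic Euclidean distance to the nearest
# voxel of the nucleus mask, computed by distance transform; for isotropic
# voxels this matches repeated unit dilations, and it stays well defined for
# coarse z-steps.  Rings of neighbouring nuclei may overlap; each nucleus is
# measured independently.

#' Cytoplasmic ring parameters
#'
#' @param outer_um outer ring radius measured from the nucleus surface (um).
#' @param inner_um inner exclusion zone around the nucleus (um).
#' @param exclude_all_nuclei if `TRUE` (default) the ring also excludes all
#'   other nuclei and their inner halos.
#' @export
ring_params <- function(outer_um = 8.3, inner_um = 3.3,
                        exclude_all_nuclei = TRUE) {
  stopifnot(inner_um >= 0, inner_um < outer_um)
  structure(list(outer_um = outer_um, inner_um = inner_um,
                 exclude_all_nuclei = exclude_all_nuclei),
            class = "ring_params")
}

# linear indices (into the full array) of the ring voxels of one label,
# computed on a cropped bounding box for speed
.ring_indices <- function(labels, label, spacing, outer_um, inner_um,
                          exclude_all = TRUE) {
  d <- dim(labels)
  idx <- which(labels == label)
  if (length(idx) == 0) stop("label ", label, " not present in mask")
  ai <- arrayInd(idx, d)
  sp_dims <- .spacing_dims(spacing) # (y, x, z)
  pad <- ceiling((outer_um + inner_um) / sp_dims) + 1L
  lo <- pmax(1L, apply(ai, 2, min) - pad)
  hi <- pmin(d, apply(ai, 2, max) + pad)
  crop <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(crop) <- hi - lo + 1L
  d_self <- distance_transform(crop == label, spacing)
  ring <- d_self > inner_um & d_self <= outer_um & crop == 0L
  if (exclude_all && inner_um > 0) {
    d_any <- distance_transform(crop > 0L, spacing)
    ring <- ring & d_any > inner_um
  }
  ridx <- which(ring)
  if (length(ridx) == 0) return(integer(0))
  rai <- arrayInd(ridx, dim(crop))
  rai <- sweep(rai, 2, lo - 1L, `+`)
  rai[, 1] + (rai[, 2] - 1) * d[1] + (rai[, 3] - 1) * d[1] * d[2]
}

#' Cytoplasmic ring mask of one nucleus
#'
#' A voxel belongs to the ring iff its distance to the nucleus lies in
#' `(inner_um, outer_um]` um, it is inside no nuclear label, and (with
#' `exclude_all_nuclei`) it is farther than `inner_um` from every nucleus.
#' An empty ring is returned as an all-`FALSE` mask, not an error.
#'
#' @param labels integer label array (y, x, z).
#' @param label nucleus label to ring.
#' @param spacing named vector `c(z=, y=, x=)` um/voxel.
#' @param params a [ring_params()].
#' @return logical array of the ring, same dimensions as `labels`.
#' @export
cytoplasm_mask <- function(labels, label, spacing,
                           params = ring_params()) {
  spacing <- .check_spacing(spacing)
  idx <- .ring_indices(labels, label, spacing, params$outer_um,
                       params$inner_um, params$exclude_all_nuclei)
  out <- array(FALSE, dim(labels))
  out[idx] <- TRUE
  out
}

#' Measure N/C ratio time courses
#'
#' For every (track, frame, channel) of an interphase nucleus, computes the
#' background-corrected nuclear mean, cytoplasmic ring mean and their ratio
#' `nc_ratio = (nuc_mean - background) / (cyto_mean - background)`.
#' Background is estimated per frame and channel from the far field (beyond
#' the outer ring radius of every nucleus).  Rows whose ring holds fewer
#' than `min_cyto_voxels` voxels, or whose cytoplasmic mean does not exceed
#' background, carry a missing ratio.
#'
#' @param movie a [multichannel_movie()].
#' @param tracks a `track_set` from [link_tracks()] (or a `tracks`
#'   [measurement_table()]).
#' @param labels integer label array (y, x, z, frame).
#' @param channels channels to measure (default: all).
#' @param ring a [ring_params()].
#' @param min_cyto_voxels minimum ring size for a valid ratio.
#' @param stages optional `stages` table from [annotate_stages()] supplying
#'   per-frame stage labels.
#' @param embryo_id identifier written into the table.
#' @return a `nc_ratio` [measurement_table()].
#' @export
measure_nc <- function(movie, tracks, labels, channels = NULL,
                       ring = ring_params(), min_cyto_voxels = 100,
                       stages = NULL, embryo_id = "embryo1") {
  tr <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  if (is.null(channels)) channels <- names(movie$channels)
  times <- frame_times(movie)
  stage_of <- function(f) {
    if (is.null(stages)) return(NA_character_)
    i <- match(f, stages$frame)
    if (is.na(i)) NA_character_ else stages$stage_label[i]
  }
  out <- vector("list", 0)
  for (f in sort(unique(tr$frame))) {
    lab3 <- labels[, , , f, drop = FALSE]
    dim(lab3) <- dim(labels)[1:3]
    vols <- lapply(setNames(channels, channels), movie_volume,
                   movie = movie, frame = f)
    far <- if (any(lab3 > 0L))
      distance_transform(lab3 > 0L, movie$spacing) > ring$outer_um
    else array(TRUE, dim(lab3))
    if (sum(far) < 1000)
      stop("degenerate-field: cannot estimate background at frame ", f)
    bg <- vapply(vols, function(v) median(v[far]), numeric(1))
    rows <- tr[tr$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      L <- rows$label[i]
      nidx <- which(lab3 == L)
      if (length(nidx) == 0) next
      ridx <- .ring_indices(lab3, L, movie$spacing, ring$outer_um,
                            ring$inner_um, ring$exclude_all_nuclei)
      for (cn in channels) {
        vol <- vols[[cn]]
        nuc_mean <- mean(vol[nidx])
        cyto_mean <- if (length(ridx)) mean(vol[ridx]) else NA_real_
        ok <- length(ridx) >= min_cyto_voxels && !is.na(cyto_mean) &&
          cyto_mean > bg[[cn]]
        out[[length(out) + 1L]] <- data.frame(
          embryo_id = embryo_id, track_id = rows$track_id[i], frame = f,
          time_s = times[f], channel = cn, nuc_mean = nuc_mean,
          cyto_mean = cyto_mean,
          nc_ratio = if (ok) (nuc_mean - bg[[cn]]) / (cyto_mean - bg[[cn]])
                     else NA_real_,
          background = bg[[cn]], n_cyto_voxels = length(ridx),
          stage_label = stage_of(f))
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(embryo_id = character(), track_id = integer(),
               frame = integer(), time_s = numeric(), channel = character(),
               nuc_mean = numeric(), cyto_mean = numeric(),
               nc_ratio = numeric(), background = numeric(),
               n_cyto_voxels = integer(), stage_label = character())
  measurement_table(df, "nc_ratio")
}

#' Normalise N/C ratios to a reference stage
#'
#' Adds `relative_nc = nc_ratio / mean(nc_ratio at the reference stage)`,
#' computed per (embryo, channel), so the reference-stage mean of
#' `relative_nc` is 1 by construction.
#'
#' @param table a `nc_ratio` [measurement_table()].
#' @param reference_stage_label e.g. `"32-cell"`.
#' @return a `nc_relative` [measurement_table()].
#' @export
normalize_to_stage <- function(table, reference_stage_label = "32-cell") {
  df <- as.data.frame(table)
  df$relative_nc <- NA_real_
  for (em in unique(df$embryo_id)) {
    for (cn in unique(df$channel)) {
      sel <- df$embryo_id == em & df$channel == cn
      ref <- sel & !is.na(df$stage_label) &
        df$stage_label == reference_stage_label & !is.na(df$nc_ratio)
      if (!any(ref))
        stop("missing-reference: no '", reference_stage_label,
             "' rows for embryo '", em, "', channel '", cn, "'")
      df$relative_nc[sel] <- df$nc_ratio[sel] / mean(df$nc_ratio[ref])
    }
  }
  measurement_table(df, "nc_relative")
}

#' Aggregate N/C ratios across embryos
#'
#' The embryo is the replicate unit: per (group, channel) each embryo is
#' first reduced to its own mean, then n, mean and s.d. are taken across
#' embryo means.  With a single embryo the s.d. is reported missing.
#'
#' @param tables list of `nc_ratio` / `nc_relative` tables (one or more
#'   embryos; `embryo_id` distinguishes them).
#' @param group_by `"stage_label"` or `"time_bin"`.
#' @param time_bin_s bin width (s) when grouping by time.
#' @return a `nc_aggregate` [measurement_table()] with columns group,
#'   channel, n_embryos, mean, sd.
#' @export
aggregate_embryos <- function(tables, group_by = c("stage_label",
                                                   "time_bin"),
                              time_bin_s = 300) {
  group_by <- match.arg(group_by)
  if (inherits(tables, "data.frame")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  value <- if ("relative_nc" %in% names(df)) df$relative_nc else df$nc_ratio
  grp <- if (group_by == "stage_label") df$stage_label else
    sprintf("t%06.0f", floor(df$time_s / time_bin_s) * time_bin_s)
  keep <- !is.na(value) & !is.na(grp)
  df <- df[keep, , drop = FALSE]; value <- value[keep]; grp <- grp[keep]
  per_embryo <- aggregate(value,
                          by = list(group = grp, channel = df$channel,
                                    embryo_id = df$embryo_id),
                          FUN = mean)
  agg <- do.call(rbind, lapply(
    split(per_embryo, list(per_embryo$group, per_embryo$channel),
          drop = TRUE),
    function(g) data.frame(group = g$group[1], channel = g$channel[1],
                           n_embryos = nrow(g), mean = mean(g$x),
                           sd = if (nrow(g) > 1) sd(g$x) else NA_real_)))
  measurement_table(agg[order(agg$group, agg$channel), ], "nc_aggregate")
}

#' Static single-frame nuclear intensity measurement
#'
#' Emulates fixed-sample quantification: nuclear masks are obtained by
#' thresholding a DNA channel and the mean intensity of each signal channel
#' is measured per nucleus (no cytoplasm, no tracking).
#'
#' @param movie a [multichannel_movie()] (only `frame` is used).
#' @param frame frame index (default 1).
#' @param dna_channel channel used for thresholding (e.g. a DNA stain).
#' @param signal_channels channels to measure (default: all others).
#' @param params a [segmentation_params()].
#' @return a `static_intensity` [measurement_table()].
#' @export
measure_static <- function(movie, frame = 1, dna_channel,
                           signal_channels = NULL,
                           params = segmentation_params()) {
  if (is.null(signal_channels))
    signal_channels <- setdiff(names(movie$channels), dna_channel)
  seg <- segment_nuclei_frame(movie, frame, dna_channel, params)
  ints <- seg$intensity
  sel <- ints$channel %in% signal_channels
  counts <- table(seg$labels[seg$labels > 0L])
  df <- data.frame(label = ints$label[sel], channel = ints$channel[sel],
                   mean_intensity = ints$mean_intensity[sel],
                   n_voxels = as.integer(counts[as.character(
                     ints$label[sel])]))
  measurement_table(df, "static_intensity")
}
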