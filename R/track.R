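# Interphase track linking and stage annotation
# ---------------------------------------------
# Detections are linked frame to frame by optimal bipartite matching on
# centroid displacement (maximum-weight matching with a hard displacement
# gate), which keeps identities through the coherent, path-crossing motion
# of cleavage-stage nuclei better than nearest-neighbour linking.  Tracks
# end silently at mitosis; manual corrections arrive as an ordered CSV that
# replaces the original interactive review step.

#' Link nucleus detections into interphase tracks
#'
#' @param nuclei a `nuclei` [measurement_table()] covering all frames (as
#'   produced by [segment_nuclei_frame()], possibly row-bound across
#'   frames).  Records flagged `mitotic` are excluded from linking.
#' @param max_displacement_um hard gate: no link may span more than this
#'   centroid displacement (um).
#' @param max_gap maximum number of consecutive missed frames a track may
#'   bridge (default 1).
#' @return a `track_set`: list with `tracks` (a `tracks`
#'   [measurement_table()]), `unassigned` (detections removed by
#'   corrections), and `max_gap`.
#' @export
link_tracks <- function(nuclei, max_displacement_um, max_gap = 1) {
  df <- as.data.frame(nuclei)
  df <- df[!grepl("mitotic", df$qc_flags), , drop = FALSE]
  frames <- sort(unique(df$frame))
  # active track state
  act_id <- integer(0); act_frame <- integer(0)
  act_pos <- matrix(numeric(0), 0, 3)
  out <- list(); next_id <- 1L
  for (f in frames) {
    det <- df[df$frame == f, , drop = FALSE]
    det <- det[order(det$label), , drop = FALSE]
    dpos <- as.matrix(det[, c("centroid_z_um", "centroid_y_um",
                              "centroid_x_um")])
    keep <- f - act_frame <= max_gap + 1L
    cand <- which(keep)
    assigned_det <- rep(NA_integer_, nrow(det)) # -> index into cand
    if (length(cand) && nrow(det)) {
      cost <- matrix(Inf, length(cand), nrow(det))
      for (i in seq_along(cand))
        cost[i, ] <- sqrt(colSums((t(dpos) - act_pos[cand[i], ])^2))
      m <- .match_bipartite(cost, max_displacement_um)
      assigned_det[!is.na(m)] <- m[!is.na(m)]
    }
    for (j in seq_len(nrow(det))) {
      if (!is.na(assigned_det[j])) {
        ti <- cand[assigned_det[j]]
        out[[length(out) + 1L]] <- data.frame(
          track_id = act_id[ti], frame = f, label = det$label[j])
        act_frame[ti] <- f
        act_pos[ti, ] <- dpos[j, ]
      } else {
        out[[length(out) + 1L]] <- data.frame(
          track_id = next_id, frame = f, label = det$label[j])
        act_id <- c(act_id, next_id)
        act_frame <- c(act_frame, f)
        act_pos <- rbind(act_pos, dpos[j, , drop = FALSE])
        next_id <- next_id + 1L
      }
    }
    # retire tracks that fell out of the gap window
    live <- f - act_frame <= max_gap
    act_id <- act_id[live]; act_frame <- act_frame[live]
    act_pos <- act_pos[live, , drop = FALSE]
  }
  tracks <- if (length(out)) do.call(rbind, out) else
    data.frame(track_id = integer(), frame = integer(), label = integer())
  ts <- structure(list(tracks = measurement_table(tracks, "tracks"),
                       unassigned = data.frame(frame = integer(),
                                               label = integer()),
                       max_gap = max_gap),
                  class = "track_set")
  validate_track_set(ts)
  ts
}

# maximum-weight bipartite matching minimising total displacement among
# maximum-cardinality gated matchings.  cost: tracks x detections matrix;
# entries > gate are forbidden.  Returns, per detection, the matched track
# row index or NA.
.match_bipartite <- function(cost, gate) {
  nt <- nrow(cost); nd <- ncol(cost)
  ok <- which(cost <= gate, arr.ind = TRUE)
  res <- rep(NA_integer_, nd)
  if (nrow(ok) == 0) return(res)
  # cardinality-first weighting: C > (k+1) * gate for any feasible k
  C <- (min(nt, nd) + 2) * gate
  edges <- as.vector(t(cbind(ok[, 1], nt + ok[, 2])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nt), rep(TRUE, nd)),
                                    edges)
  igraph::E(g)$weight <- C - cost[ok]
  m <- igraph::max_bipartite_match(g)$matching
  for (j in seq_len(nd)) {
    v <- m[nt + j]
    if (!is.na(v)) res[j] <- as.integer(v)
  }
  res
}

#' Validate a track set
#'
#' Checks the structural invariants: no (frame, label) appears twice across
#' tracks or the unassigned set, and frames within each track are strictly
#' increasing with gaps of at most `max_gap` frames.
#'
#' @param ts a `track_set`.
#' @return `ts`, invisibly; stops on violation.
#' @export
validate_track_set <- function(ts) {
  tr <- ts$tracks
  key <- paste(tr$frame, tr$label)
  if (anyDuplicated(c(key, paste(ts$unassigned$frame,
                                 ts$unassigned$label))))
    stop("invalid track set: a (frame, label) pair appears twice")
  for (id in unique(tr$track_id)) {
    fr <- tr$frame[tr$track_id == id]
    if (is.unsorted(fr, strictly = TRUE))
      stop("invalid track set: frames of track ", id,
           " not strictly increasing")
    if (length(fr) > 1 && any(diff(fr) > ts$max_gap + 1L))
      stop("invalid track set: track ", id, " has a gap larger than ",
           ts$max_gap)
  }
  invisible(ts)
}

#' Apply manual track corrections
#'
#' Edits are applied in file order; each references a (frame, label)
#' detection.  Actions: `reassign` moves the detection to `target_track`
#' (idempotent); `terminate` cuts the detection's track after the given
#' frame; `merge` moves the whole track containing the detection into
#' `target_track`; `delete` moves the detection to the unassigned set.
#' The result must satisfy all track-set invariants.
#'
#' @param ts a `track_set`.
#' @param edits a `corrections` [measurement_table()] (or a data.frame with
#'   columns action, frame, label, target_track), or a CSV path.
#' @return the corrected `track_set`.
#' @export
apply_corrections <- function(ts, edits) {
  if (is.character(edits)) edits <- read_table(edits, "corrections")
  edits <- as.data.frame(edits)
  tr <- as.data.frame(ts$tracks)
  un <- ts$unassigned
  where <- function(f, l) which(tr$frame == f & tr$label == l)
  for (e in seq_len(nrow(edits))) {
    act <- edits$action[e]; f <- edits$frame[e]; l <- edits$label[e]
    tgt <- edits$target_track[e]
    i <- where(f, l)
    in_un <- any(un$frame == f & un$label == l)
    if (length(i) == 0 && !in_un)
      stop("unknown-reference in correction ", e, " (", act,
           "): no detection (frame ", f, ", label ", l, ")")
    if (act == "reassign") {
      if (!tgt %in% tr$track_id)
        stop("unknown-reference in correction ", e,
             ": target track ", tgt, " does not exist")
      if (length(i) && tr$track_id[i] == tgt) next # idempotent
      if (any(tr$track_id == tgt & tr$frame == f))
        stop("correction ", e, ": target track ", tgt,
             " already has a detection at frame ", f)
      if (length(i)) tr <- tr[-i, , drop = FALSE]
      else un <- un[!(un$frame == f & un$label == l), , drop = FALSE]
      tr <- rbind(tr, data.frame(track_id = tgt, frame = f, label = l))
    } else if (act == "terminate") {
      id <- tr$track_id[i]
      cut <- tr$track_id == id & tr$frame > f
      un <- rbind(un, tr[cut, c("frame", "label")])
      tr <- tr[!cut, , drop = FALSE]
    } else if (act == "merge") {
      id <- tr$track_id[i]
      if (!tgt %in% tr$track_id)
        stop("unknown-reference in correction ", e,
             ": target track ", tgt, " does not exist")
      if (id == tgt) next
      tr$track_id[tr$track_id == id] <- tgt
    } else if (act == "delete") {
      if (length(i)) {
        un <- rbind(un, tr[i, c("frame", "label")])
        tr <- tr[-i, , drop = FALSE]
      }
    } else stop("unknown correction action '", act, "' in edit ", e)
  }
  tr <- tr[order(tr$track_id, tr$frame), , drop = FALSE]
  ts$tracks <- measurement_table(tr, "tracks")
  ts$unassigned <- un
  validate_track_set(ts)
  ts
}

#' Annotate developmental stages from nucleus counts
#'
#' Division waves are detected where the median-smoothed interphase count
#' first exceeds 1.5 times the current cycle's plateau (the median of
#' positive smoothed counts seen so far in the cycle); the cycle index
#' increments at each wave and the embryo-wide stage label doubles.
#'
#' @param counts integer vector of interphase nucleus counts per frame (use
#'   0 for mitotic/empty frames), or a data.frame with columns `frame` and
#'   `n_interphase`.
#' @param initial_stage_count embryo-wide nucleus count of the first
#'   observed cycle (a power of 2, e.g. 64).
#' @param fov_fraction fraction of the embryo's nuclei visible in the field
#'   of view (recorded for reference; counts are interpreted per field).
#' @param smooth_k width of the running-median smoother (odd, default 3).
#' @return a `stages` [measurement_table()].
#' @export
annotate_stages <- function(counts, initial_stage_count, fov_fraction = 1,
                            smooth_k = 3) {
  if (is.data.frame(counts)) {
    counts <- counts$n_interphase[order(counts$frame)]
  }
  if (log2(initial_stage_count) %% 1 != 0)
    stop("initial_stage_count must be a power of 2")
  n <- length(counts)
  sm <- if (n >= smooth_k) as.numeric(runmed(counts, smooth_k)) else
    as.numeric(counts)
  cycle <- integer(n)
  ci <- 0L; start <- 1L
  for (f in seq_len(n)) {
    if (f > start) {
      prev <- sm[start:(f - 1L)]
      prev <- prev[prev > 0]
      if (length(prev) && sm[f] > 1.5 * median(prev)) {
        ci <- ci + 1L
        start <- f
      }
    }
    cycle[f] <- ci
  }
  measurement_table(
    data.frame(frame = seq_len(n), n_interphase = as.integer(counts),
               cycle_index = cycle,
               stage_label = .stage_label(initial_stage_count * 2^cycle)),
    "stages")
}
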