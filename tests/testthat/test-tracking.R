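# build a nuclei table from bare centroid positions:
# pos[[frame]] = matrix with columns (z, y, x) um; labels 1..n per frame
nuclei_from_positions <- function(pos, flags = NULL) {
  rows <- lapply(seq_along(pos), function(f) {
    p <- pos[[f]]
    if (is.null(p) || nrow(p) == 0) return(NULL)
    data.frame(frame = f, label = seq_len(nrow(p)),
               centroid_z_um = p[, 1], centroid_y_um = p[, 2],
               centroid_x_um = p[, 3], volume_um3 = 100, solidity = 0.95,
               qc_flags = if (is.null(flags)) "" else flags[[f]])
  })
  measurement_table(do.call(rbind, rows), "nuclei")
}

test_that("a stationary nucleus forms a single full-length track", {
  pos <- replicate(10, cbind(4, 10, 10), simplify = FALSE)
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(nrow(ts$tracks), 10)
  expect_equal(ts$tracks$frame, 1:10)
})

test_that("assignment minimises total displacement when nuclei approach", {
  # two nuclei converging: naive nearest-neighbour would swap them
  pos <- lapply(0:5, function(t)
    rbind(c(4, 10, 10 + t), c(4, 10, 22 - t)))
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5)
  tr <- as.data.frame(ts$tracks)
  expect_equal(length(unique(tr$track_id)), 2)
  # identity: label 1 stays with track of frame-1 label 1
  t1 <- tr$track_id[tr$frame == 1 & tr$label == 1]
  expect_equal(tr$label[tr$track_id == t1], rep(1, 6))
})

test_that("links beyond the displacement gate open new tracks", {
  pos <- list(cbind(4, 10, 10), cbind(4, 10, 30))
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5)
  expect_equal(length(unique(ts$tracks$track_id)), 2)
})

test_that("a single missed detection is bridged up to max_gap", {
  pos <- list(cbind(4, 10, 10), NULL, cbind(4, 10, 11),
              NULL, NULL, cbind(4, 10, 12))
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5,
                    max_gap = 1)
  tr <- as.data.frame(ts$tracks)
  # frames 1 and 3 joined; the 2-frame gap to frame 6 is not bridged
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(sort(tr$frame[tr$track_id == tr$track_id[1]]), c(1, 3))
})

test_that("linking is invariant to label permutation within frames", {
  set.seed(42)
  pos <- list()
  base <- cbind(c(4, 4, 4), c(5, 15, 25), c(10, 12, 14))
  for (f in 1:6) pos[[f]] <- base + cbind(0, rnorm(3, 0, .3),
                                          rnorm(3, 0, .3))
  nt <- nuclei_from_positions(pos)
  perm <- as.data.frame(nt)
  for (f in 1:6) {
    sel <- which(perm$frame == f)
    perm$label[sel] <- sample(perm$label[sel])
  }
  grouping <- function(ts) {
    tr <- as.data.frame(ts$tracks)
    key <- paste(tr$frame, round(pos_lookup(tr), 3))
    unname(split(key, tr$track_id))
  }
  pos_lookup <- function(tr) {
    vapply(seq_len(nrow(tr)), function(i) {
      src <- as.data.frame(nt)
      src$centroid_y_um[src$frame == tr$frame[i] &
                          src$label == tr$label[i]]
    }, numeric(1))
  }
  ts1 <- link_tracks(nt, 5)
  # permuted labels: compare the sets of (frame, y-position) per track
  src2 <- measurement_table(perm, "nuclei")
  ts2 <- link_tracks(src2, 5)
  g1 <- grouping(ts1)
  tr2 <- as.data.frame(ts2$tracks)
  key2 <- paste(tr2$frame, round(vapply(seq_len(nrow(tr2)), function(i) {
    perm$centroid_y_um[perm$frame == tr2$frame[i] &
                         perm$label == tr2$label[i]]
  }, numeric(1)), 3))
  g2 <- unname(split(key2, tr2$track_id))
  expect_setequal(vapply(g1, paste, character(1), collapse = "|"),
                  vapply(g2, paste, character(1), collapse = "|"))
})

test_that("a division movie yields clean generation turnover without identity switches", {
  sim <- small_division_sim()
  segs <- lapply(1:16, function(f)
    flag_mitotic(segment_nuclei_frame(sim$movie, f, "marker"),
                 sim$movie, "marker"))
  nuclei <- measurement_table(
    do.call(rbind, lapply(segs, function(s) as.data.frame(s$nuclei))),
    "nuclei")
  ts <- link_tracks(nuclei, max_displacement_um = 6)
  tr <- as.data.frame(ts$tracks)
  gen1 <- unique(tr$track_id[tr$frame <= 8])
  gen2 <- unique(tr$track_id[tr$frame >= 11])
  expect_equal(length(gen1), 4)
  expect_equal(length(gen2), 8)
  expect_length(intersect(gen1, gen2), 0)
  # identity switches vs ground truth: map detections to true tracks by
  # centroid proximity; each linked track must follow one true track
  gtt <- as.data.frame(sim$ground_truth$tracks)
  gtt <- gtt[gtt$phase == "interphase", ]
  det <- merge(tr, as.data.frame(nuclei), by = c("frame", "label"))
  truth_of <- vapply(seq_len(nrow(det)), function(i) {
    g <- gtt[gtt$frame == det$frame[i], ]
    d <- sqrt((g$centroid_z_um - det$centroid_z_um[i])^2 +
              (g$centroid_y_um - det$centroid_y_um[i])^2 +
              (g$centroid_x_um - det$centroid_x_um[i])^2)
    g$track_id[which.min(d)]
  }, numeric(1))
  switches <- sum(vapply(split(truth_of, det$track_id), function(x)
    length(unique(x)) - 1L, integer(1)))
  expect_equal(switches, 0)
})

test_that("corrections reassign, delete and merge while keeping invariants", {
  pos <- lapply(1:6, function(f) rbind(c(4, 10, 10 + f), c(4, 20, 10 + f)))
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5)
  # cut track 2 at frame 3, then merge the orphaned tail back
  ts2 <- apply_corrections(ts, data.frame(
    action = "terminate", frame = 3, label = 2, target_track = NA))
  expect_equal(max(ts2$tracks$frame[ts2$tracks$track_id == 2]), 3)
  expect_equal(nrow(ts2$unassigned), 3)
  # reassign one detection, idempotently
  e <- data.frame(action = "reassign", frame = 4, label = 2,
                  target_track = 2)
  ts3 <- apply_corrections(ts2, e)
  ts3b <- apply_corrections(ts3, e)
  expect_identical(as.data.frame(ts3$tracks), as.data.frame(ts3b$tracks))
  # delete a spurious detection
  ts4 <- apply_corrections(ts, data.frame(
    action = "delete", frame = 5, label = 1, target_track = NA))
  expect_false(any(ts4$tracks$frame == 5 & ts4$tracks$label == 1))
  expect_true(any(ts4$unassigned$frame == 5 & ts4$unassigned$label == 1))
  validate_track_set(ts4)
  # merging two fragments separated by a one-frame gap (the jump exceeds
  # the displacement gate, so linking leaves two fragments)
  frag <- list(cbind(4, 10, 10), cbind(4, 10, 11), NULL,
               cbind(4, 10, 19), cbind(4, 10, 20))
  tsf <- link_tracks(nuclei_from_positions(frag), max_displacement_um = 5,
                     max_gap = 1)
  expect_equal(length(unique(tsf$tracks$track_id)), 2)
  first <- tsf$tracks$track_id[tsf$tracks$frame == 1]
  tsm <- apply_corrections(tsf, data.frame(
    action = "merge", frame = 4, label = 1, target_track = first))
  expect_equal(length(unique(tsm$tracks$track_id)), 1)
  expect_equal(sort(tsm$tracks$frame), c(1, 2, 4, 5))
})

test_that("corrections referencing unknown detections fail loudly", {
  pos <- list(cbind(4, 10, 10), cbind(4, 10, 11))
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5)
  expect_error(apply_corrections(ts, data.frame(
    action = "reassign", frame = 9, label = 1, target_track = 1)),
    "unknown-reference")
  expect_error(apply_corrections(ts, data.frame(
    action = "reassign", frame = 1, label = 1, target_track = 99)),
    "unknown-reference")
})

test_that("random correction sequences never duplicate a detection", {
  set.seed(7)
  pos <- lapply(1:8, function(f)
    rbind(c(4, 10, 10 + f), c(4, 20, 10 + f), c(4, 30, 10 + f)))
  ts <- link_tracks(nuclei_from_positions(pos), max_displacement_um = 5)
  for (rep in 1:20) {
    tr <- as.data.frame(ts$tracks)
    i <- sample(nrow(tr), 1)
    act <- sample(c("delete", "terminate", "reassign"), 1)
    tgt <- if (act == "reassign") tr$track_id[i] else NA
    ts <- tryCatch(
      apply_corrections(ts, data.frame(action = act, frame = tr$frame[i],
                                       label = tr$label[i],
                                       target_track = tgt)),
      error = function(e) ts) # rejected edits leave the set unchanged
    key <- paste(ts$tracks$frame, ts$tracks$label)
    expect_false(anyDuplicated(c(key, paste(ts$unassigned$frame,
                                            ts$unassigned$label))) > 0)
  }
})

test_that("stage annotation detects doubling waves", {
  st <- annotate_stages(c(8, 8, 8, 16, 16, 16), initial_stage_count = 8)
  expect_equal(st$cycle_index, c(0, 0, 0, 1, 1, 1))
  expect_equal(st$stage_label, rep(c("8-cell", "16-cell"), each = 3))
  # constant counts: one cycle throughout
  st2 <- annotate_stages(rep(16, 10), initial_stage_count = 256)
  expect_equal(unique(st2$cycle_index), 0)
  expect_equal(unique(st2$stage_label), "256-cell")
  # counts dropping through mitosis do not trigger a wave; the doubling does
  st3 <- annotate_stages(c(8, 8, 8, 8, 0, 0, 16, 16, 16, 16),
                         initial_stage_count = 512)
  expect_equal(st3$cycle_index[c(1, 4, 10)], c(0, 0, 1))
  expect_equal(st3$stage_label[10], "1k-cell")
})
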