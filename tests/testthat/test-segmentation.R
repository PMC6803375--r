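test_that("well-separated zero-noise nuclei are recovered with sub-voxel centroids", {
  sim <- small_division_sim(noise = FALSE)
  gt <- sim$ground_truth
  seg <- segment_nuclei_frame(sim$movie, 2, "marker")
  nuc <- as.data.frame(seg$nuclei)
  expect_equal(nrow(nuc), 4)
  expect_true(all(nuc$qc_flags %in% c("", "border")))
  gtf <- as.data.frame(gt$tracks)
  gtf <- gtf[gtf$frame == 2, ]
  sp <- sim$movie$spacing
  for (i in seq_len(nrow(nuc))) {
    d <- sqrt((gtf$centroid_z_um - nuc$centroid_z_um[i])^2 +
              (gtf$centroid_y_um - nuc$centroid_y_um[i])^2 +
              (gtf$centroid_x_um - nuc$centroid_x_um[i])^2)
    expect_lt(min(d), max(sp)) # within one voxel of a true centre
  }
})

test_that("per-channel intensities are measured over each label", {
  sim <- small_division_sim(noise = FALSE)
  seg <- segment_nuclei_frame(sim$movie, 2, "marker")
  ints <- as.data.frame(seg$intensity)
  expect_setequal(unique(ints$channel), c("marker", "signal"))
  mk <- ints[ints$channel == "marker", ]
  # zero-noise marker nuclei sit at bg + 4 * (cyto - bg) = 650 exactly
  expect_true(all(abs(mk$mean_intensity - 650) < 1))
})

test_that("blank frames yield zero records, noisy or not", {
  mk <- function(vals) multichannel_movie(
    list(marker = array(as.integer(vals), c(48, 48, 4, 1))),
    spacing = c(z = 2, y = 0.5, x = 0.5), frame_interval = 1)
  seg0 <- segment_nuclei_frame(mk(rep(50L, 48 * 48 * 4)), 1, "marker")
  expect_equal(nrow(seg0$nuclei), 0)
  set.seed(9)
  noisy <- pmax(round(rnorm(48 * 48 * 4, 50, 6)), 0)
  segn <- segment_nuclei_frame(mk(noisy), 1, "marker")
  expect_equal(nrow(segn$nuclei), 0)
})

test_that("two overlapping nuclei are split into two labels", {
  # two spheres whose centres are 1.9 radii apart (10% overlap of radius)
  d <- c(64, 64, 9)
  sp <- c(z = 1.5, y = 0.5, x = 0.5)
  r <- 4
  ai <- arrayInd(seq_len(prod(d)), d)
  pos <- sweep(ai - 1, 2, unname(sp[c("y", "x", "z")]), `*`)
  c1 <- c(12, 16, 6); c2 <- c(12 + 1.9 * r, 16, 6) # (y, x, z) um
  inside <- sqrt(colSums((t(pos) - c1[c(1, 2, 3)])^2)) <= r |
            sqrt(colSums((t(pos) - c2[c(1, 2, 3)])^2)) <= r
  vol <- array(100L, d)
  vol[inside] <- 400L
  movie <- multichannel_movie(list(marker = array(vol, c(d, 1))),
                              spacing = sp, frame_interval = 1)
  seg <- segment_nuclei_frame(movie, 1, "marker",
                              segmentation_params(seed_min_distance_um = 5))
  expect_equal(nrow(seg$nuclei), 2)
  cy <- sort(seg$nuclei$centroid_y_um)
  expect_equal(cy, c(12, 12 + 1.9 * r), tolerance = 0.15)
})

test_that("fully dispersed mitotic frames produce no unflagged objects", {
  sim <- small_division_sim()
  for (f in 9:10) { # mitotic wave
    seg <- segment_nuclei_frame(sim$movie, f, "marker")
    seg <- flag_mitotic(seg, sim$movie, "marker")
    unflagged <- !grepl("mitotic", seg$nuclei$qc_flags)
    expect_equal(sum(unflagged), 0)
  }
})

test_that("solidity at the mitotic cutoff is not flagged (strict inequality)", {
  d <- c(24, 24, 3)
  labels <- array(0L, d); labels[10:14, 10:14, 2] <- 1L
  vol <- array(100L, d); vol[labels == 1L] <- 500L
  movie <- multichannel_movie(list(marker = array(vol, c(d, 1))),
                              spacing = c(z = 2, y = 0.5, x = 0.5),
                              frame_interval = 1)
  mkseg <- function(sol) structure(list(
    labels = labels, frame = 1,
    nuclei = measurement_table(data.frame(
      frame = 1L, label = 1L, centroid_z_um = 2, centroid_y_um = 5.5,
      centroid_x_um = 5.5, volume_um3 = 12.5, solidity = sol,
      qc_flags = ""), "nuclei"),
    intensity = measurement_table(data.frame(
      frame = 1L, label = 1L, channel = "marker",
      mean_intensity = 500, sum_intensity = 500 * 25), "nucleus_intensity")),
    class = "nucleus_segmentation")
  p <- segmentation_params(mitotic_solidity_cutoff = 0.6)
  at <- flag_mitotic(mkseg(0.6), movie, "marker", p)
  below <- flag_mitotic(mkseg(0.59), movie, "marker", p)
  expect_false(grepl("mitotic", at$nuclei$qc_flags))
  expect_true(grepl("mitotic", below$nuclei$qc_flags))
})

test_that("otsu segmentation is invariant to positive intensity scaling", {
  sim <- small_division_sim()
  seg1 <- segment_nuclei_frame(sim$movie, 3, "marker")
  scaled <- sim$movie
  scaled$channels$marker <- scaled$channels$marker * 3L
  seg2 <- segment_nuclei_frame(scaled, 3, "marker")
  agree <- mean((seg1$labels > 0) == (seg2$labels > 0))
  expect_gt(agree, 0.999) # identical up to threshold-tie voxels
})

test_that("labels never overlap and stay within the field volume", {
  sim <- small_division_sim()
  seg <- segment_nuclei_frame(sim$movie, 12, "marker")
  counts <- table(seg$labels[seg$labels > 0])
  expect_equal(sum(counts) + sum(seg$labels == 0), prod(dim(seg$labels)))
  expect_true(all(as.data.frame(seg$nuclei)$volume_um3 > 0))
  expect_false(any(duplicated(as.data.frame(seg$nuclei)$label)))
})

test_that("background is the far-field median and degenerates loudly", {
  cm <- constructed_compartment_movie()
  expect_equal(estimate_background(cm$movie, 1, "ch",
                                   cm$labels[, , , 1]), 50)
  # uniform image with an empty mask: the uniform value
  uni <- multichannel_movie(list(ch = array(77L, c(20, 20, 4, 1))),
                            spacing = c(z = 1, y = 1, x = 1),
                            frame_interval = 1)
  expect_equal(estimate_background(uni, 1, "ch",
                                   array(0L, c(20, 20, 4))), 77)
  # mask everywhere: nothing left to estimate from
  expect_error(estimate_background(uni, 1, "ch",
                                   array(1L, c(20, 20, 4))),
               "degenerate-field")
})
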