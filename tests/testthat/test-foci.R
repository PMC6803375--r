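test_that("rendered foci are detected at their true positions", {
  sim <- single_nucleus_foci_sim()
  gt <- sim$ground_truth
  f <- 6 # at the configured peak time (150 s)
  lab <- gt$labels[, , , f]
  det <- detect_foci(sim$movie, f, "signal", lab, 1L)
  expect_equal(nrow(det), 2)
  truth <- as.data.frame(gt$foci)
  truth <- truth[truth$frame == f, ]
  sp <- sim$movie$spacing
  for (k in 1:2) {
    d <- sqrt((truth$z_um - det$z_um[k])^2 + (truth$y_um - det$y_um[k])^2 +
              (truth$x_um - det$x_um[k])^2)
    expect_lt(min(d), max(sp)) # within one voxel
  }
})

test_that("a uniform nucleus contains no foci", {
  sim <- single_nucleus_foci_sim()
  lab <- sim$ground_truth$labels[, , , 6]
  det <- detect_foci(sim$movie, 6, "marker", lab, 1L) # marker has no foci
  expect_equal(nrow(det), 0)
})

test_that("detection keeps the most prominent maxima and scales with intensity", {
  # three Gaussian bumps of graded amplitude in a box nucleus
  d <- c(48, 48, 9)
  sp <- c(z = 1, y = 0.4, x = 0.4)
  lab <- array(0L, d); lab[6:43, 6:43, 2:8] <- 1L
  ai <- arrayInd(seq_len(prod(d)), d)
  pos <- sweep(ai - 1, 2, unname(sp[c("y", "x", "z")]), `*`)
  vol <- array(200, d)
  centers <- list(c(5, 5, 4), c(12, 5, 4), c(5, 13, 4)) # (y, x, z) um
  amps <- c(300, 200, 100)
  for (i in 1:3) {
    g <- exp(-0.5 * colSums((t(pos) - centers[[i]])^2) / 0.6^2)
    vol <- vol + amps[i] * array(g, d)
  }
  set.seed(1)
  vol <- vol + array(rnorm(prod(d), 0, 3), d)
  movie <- multichannel_movie(list(sig = array(as.integer(round(vol)),
                                               c(d, 1))),
                              spacing = sp, frame_interval = 1)
  det <- detect_foci(movie, 1, "sig", lab, 1L,
                     foci_params(max_foci = 2, detection_sigma_um = 0.5))
  expect_equal(nrow(det), 2)
  got <- det[, c("y_um", "x_um")]
  expect_equal(sort(got$y_um), c(5, 12), tolerance = 0.5)
  # global intensity scaling leaves the detected voxels unchanged
  movie2 <- movie
  movie2$channels$sig <- movie2$channels$sig * 5L
  det2 <- detect_foci(movie2, 1, "sig", lab, 1L,
                      foci_params(max_foci = 2, detection_sigma_um = 0.5))
  expect_equal(det2[, c("y_idx", "x_idx", "z_idx")],
               det[, c("y_idx", "x_idx", "z_idx")])
})

test_that("the maximal-section plane matches a per-plane area oracle", {
  sim <- single_nucleus_foci_sim()
  gt <- sim$ground_truth
  f <- 6
  lab <- gt$labels[, , , f]
  det <- detect_foci(sim$movie, f, "signal", lab, 1L)
  zp <- max_section_plane(sim$movie, f, "signal", det[1, ], lab, 1L)
  # oracle: count above-half-max pixels near the focus on every plane
  vol <- movie_volume(sim$movie, "signal", f)
  nucmed <- median(vol[lab == 1L])
  peak <- vol[det$y_idx[1], det$x_idx[1], det$z_idx[1]]
  thr <- nucmed + 0.5 * (peak - nucmed)
  sp <- sim$movie$spacing
  yc <- (seq_len(dim(vol)[1]) - 1) * sp[["y"]]
  xc <- (seq_len(dim(vol)[2]) - 1) * sp[["x"]]
  disc <- outer((yc - det$y_um[1])^2, (xc - det$x_um[1])^2, `+`) <= 1.5^2
  areas <- vapply(seq_len(dim(vol)[3]), function(z)
    sum(disc & vol[, , z] >= thr & lab[, , z] == 1L), numeric(1))
  expect_equal(areas[zp], max(areas))
  # spherical focus: the plane of the centre
  expect_equal(zp, det$z_idx[1])
  # single-plane movie degenerates to plane 1
  flat <- multichannel_movie(
    list(sig = array(1L, c(8, 8, 1, 1))),
    spacing = c(z = 1, y = 1, x = 1), frame_interval = 1)
  expect_equal(max_section_plane(flat, 1, "sig",
                                 list(y_idx = 4, x_idx = 4, z_idx = 1),
                                 array(1L, c(8, 8, 1)), 1L), 1L)
})

test_that("ROI membership matches pixel-centre enumeration at both pixel sizes", {
  for (px in c(0.2, 0.1)) {
    n <- 41
    movie <- multichannel_movie(
      list(ch = array(10L, c(n, n, 1, 1))),
      spacing = c(z = 1, y = px, x = px), frame_interval = 1)
    ctr <- c(y = (21 - 1) * px, x = (21 - 1) * px) # a pixel centre
    fi <- focus_intensity(movie, 1, "ch", 1, ctr,
                          foci_params(roi_diameter_um = 1))
    # enumeration oracle over integer pixel offsets
    r_px <- 0.5 / px
    want <- sum(outer((-20:20)^2, (-20:20)^2, `+`) <= r_px^2)
    expect_equal(fi$n_pixels, want)
    expect_equal(fi$roi_sum, want * 10)
    if (px == 0.2) expect_equal(fi$n_pixels, 21L)
  }
})

test_that("ROI sums are linear in intensity and zero on dark regions", {
  n <- 31
  base <- array(7L, c(n, n, 1, 1))
  movie <- multichannel_movie(list(ch = base),
                              spacing = c(z = 1, y = 0.2, x = 0.2),
                              frame_interval = 1)
  ctr <- c(y = 3, x = 3)
  f1 <- focus_intensity(movie, 1, "ch", 1, ctr)
  movie$channels$ch <- base * 2L
  f2 <- focus_intensity(movie, 1, "ch", 1, ctr)
  expect_equal(f2$roi_sum, 2 * f1$roi_sum)
  movie$channels$ch <- array(0L, dim(base))
  f0 <- focus_intensity(movie, 1, "ch", 1, ctr)
  expect_equal(f0$roi_sum, 0)
  expect_error(focus_intensity(movie, 1, "ch", 1, c(y = 500, x = 500)),
               "out-of-bounds")
})

test_that("foci/nucleus ratios behave as mean- and sum-mode normalisations", {
  expect_equal(foci_nucleus_ratio(210, 10, 5000, 10, "mean"), 1)
  expect_equal(foci_nucleus_ratio(210, 50, 5000, 10, "mean"), 5)
  expect_equal(foci_nucleus_ratio(210, 50, 4200, 10, "sum"), 0.05)
  expect_error(foci_nucleus_ratio(1, 1, 0, 0), "zero-nucleus")
  # uniform nucleus: mean-mode ratio 1 wherever the ROI sits
  sim <- single_nucleus_foci_sim()
  lab <- sim$ground_truth$labels[, , , 2]
  ft <- measure_foci(sim$movie, data.frame(track_id = 1L, frame = 6L,
                                           label = 1L),
                     sim$ground_truth$labels, channels = "signal")
  expect_true(all(ft$ratio_mean > 1)) # bright foci exceed the nuclear mean
})

test_that("co-localised measurement uses identical ROIs across channels", {
  sim <- single_nucleus_foci_sim()
  ft <- measure_foci(sim$movie, data.frame(track_id = 1L, frame = 6L,
                                           label = 1L),
                     sim$ground_truth$labels,
                     channels = c("marker", "signal"),
                     params = foci_params(reference_channel = "signal"))
  mk <- ft[ft$channel == "marker", c("y_um", "x_um", "z_um", "z_plane")]
  sg <- ft[ft$channel == "signal", c("y_um", "x_um", "z_um", "z_plane")]
  expect_equal(mk, sg, ignore_attr = TRUE)
})

test_that("peak time picks the smoothed maximum with documented edge rules", {
  tt <- seq(0, 600, by = 60)
  tri <- pmax(0, 1 - abs(tt - 300) / 300)
  expect_equal(peak_time(tt, tri), 300)
  mono <- seq_along(tt)
  expect_equal(peak_time(tt, mono), 600) # monotone: last point
  expect_equal(peak_time(tt, rep(1, length(tt))), 0) # ties: earliest
  expect_error(peak_time(tt[1:4], tri[1:4]), "at least 5")
  expect_error(peak_time(tt, rep(NA_real_, length(tt))), "all-missing")
})

test_that("staggered channel peaks are recovered in the right order", {
  cfg <- sim_config(
    field_dim = c(z = 8, y = 128, x = 128),
    spacing_um = c(z = 1.5, y = 0.5, x = 0.5),
    frame_interval_s = 30, n_frames = 14, n_initial = 2,
    cycle_length_s = 4000, mitosis_duration_s = 100,
    nucleus_radius_um = 4, motion_sd_um = 0.1,
    channels = list(
      channel_spec("marker", traj_constant(4), 200),
      channel_spec("chA", traj_constant(2), 200,
                   foci_spec(1, 0, peak_time_s = 150, amplitude = 6)),
      channel_spec("chB", traj_constant(2), 200,
                   foci_spec(1, 0, peak_time_s = 240, amplitude = 6))),
    noise = list(poisson = TRUE, gain = 1, gaussian_sd = 3),
    embryo_radius_frac = 0.35, placement_clearance_um = 2,
    initial_stage_count = 64, seed = 21)
  sim <- simulate_embryo_movie(cfg)
  gt <- sim$ground_truth
  tr <- as.data.frame(gt$tracks)
  tr <- tr[tr$phase == "interphase", c("track_id", "frame", "label")]
  ft <- measure_foci(sim$movie, tr, gt$labels,
                     channels = c("chA", "chB"))
  pd <- peak_time_differences(ft, "chA", "chB")
  expect_gt(nrow(pd), 0)
  expect_true(all(pd$diff_s < 0)) # channel A peaks first
  expect_equal(median(pd$diff_s), -90, tolerance = 0.5) # one frame slack
})
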