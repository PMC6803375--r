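# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small two-cycle embryo movie: 4 -> 8 nuclei, marker + ramping signal
# channel with two staggered foci; moderate noise
small_division_sim <- function(seed = 3, noise = TRUE) {
  cached(paste0("divsim", seed, noise), {
    cfg <- sim_config(
      field_dim = c(z = 8, y = 192, x = 192),
      spacing_um = c(z = 3, y = 0.6, x = 0.6),
      frame_interval_s = 30, n_frames = 16, n_initial = 4,
      cycle_length_s = 300, mitosis_duration_s = 60,
      nucleus_radius_um = 5, radius_shrink = 0.8, motion_sd_um = 0.2,
      channels = list(
        channel_spec("marker", traj_constant(4), 200),
        channel_spec("signal", traj_ramp(1, 3, 0, 450), 200)),
      noise = if (noise) list(poisson = TRUE, gain = 1, gaussian_sd = 4)
              else list(poisson = FALSE, gain = 1, gaussian_sd = 0),
      embryo_radius_frac = 0.25, initial_stage_count = 64, seed = seed)
    simulate_embryo_movie(cfg)
  })
}

# single static nucleus with two bright foci, zero noise
single_nucleus_foci_sim <- function() {
  cached("focisim", {
    cfg <- sim_config(
      field_dim = c(z = 10, y = 96, x = 96),
      spacing_um = c(z = 1, y = 0.4, x = 0.4),
      frame_interval_s = 30, n_frames = 12, n_initial = 1,
      cycle_length_s = 4000, mitosis_duration_s = 100,
      nucleus_radius_um = 4, motion_sd_um = 0,
      channels = list(
        channel_spec("marker", traj_constant(4), 200),
        channel_spec("signal", traj_constant(2), 200,
                     foci_spec(2, onset_time_s = 0, peak_time_s = 150,
                               amplitude = 5, sigma_um = 0.6))),
      noise = list(poisson = FALSE, gain = 1, gaussian_sd = 0),
      embryo_radius_frac = 0.4, placement_clearance_um = 2,
      initial_stage_count = 64, seed = 11)
    simulate_embryo_movie(cfg)
  })
}

# hand-built single-nucleus image with exact compartment levels:
# nucleus 300 within r_nuc um of the centre, cytoplasm 100 out to
# r_cyto um, pure background 50 beyond; isotropic 1 um voxels
constructed_compartment_movie <- function(nuc_value = 300,
                                          cyto_value = 100,
                                          bg_value = 50,
                                          r_nuc = 2, r_cyto = 11) {
  d <- c(40, 40, 9)
  ctr <- c(20, 20, 5)
  vol <- array(bg_value, d)
  ai <- arrayInd(seq_len(prod(d)), d)
  dist <- sqrt(colSums((t(ai) - ctr)^2))
  vol[dist <= r_cyto] <- cyto_value
  vol[dist <= r_nuc] <- nuc_value
  labels <- array(0L, d)
  labels[dist <= r_nuc] <- 1L
  movie <- multichannel_movie(list(ch = array(as.integer(vol), c(d, 1))),
                              spacing = c(z = 1, y = 1, x = 1),
                              frame_interval = 1)
  list(movie = movie, labels = array(labels, c(d, 1)),
       tracks = measurement_table(
         data.frame(track_id = 1L, frame = 1L, label = 1L), "tracks"))
}

# brute-force distance from each voxel of `from` (logical) to the nearest
# TRUE voxel of `sites`, in um; independent of the package's transform
brute_force_distance <- function(sites, spacing, subset = NULL) {
  d <- dim(sites)
  sidx <- which(sites)
  sai <- arrayInd(sidx, d)
  sp <- unname(spacing[c("y", "x", "z")])
  spos <- sweep(sai - 1, 2, sp, `*`)
  q <- if (is.null(subset)) seq_len(prod(d)) else subset
  qai <- arrayInd(q, d)
  qpos <- sweep(qai - 1, 2, sp, `*`)
  out <- numeric(length(q))
  chunk <- 2000L
  for (s in seq(1, length(q), by = chunk)) {
    e <- min(s + chunk - 1L, length(q))
    block <- qpos[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(spos))) +
      outer(rep(1, nrow(block)), rowSums(spos^2)) -
      2 * block %*% t(spos)
    j <- max.col(-d2, ties.method = "first")
    out[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), j)], 0))
  }
  out
}
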