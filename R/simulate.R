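# Synthetic embryo movies with ground truth
# -----------------------------------------
# The generator emulates the statistical structure the analysis assumes in
# cleavage-stage embryo recordings: near-synchronous nucleus-count doubling
# across cycles, per-channel N/C ratio trajectories over a diffuse
# cytoplasmic background, up to two intranuclear foci per nucleus with
# channel-specific, temporally staggered intensity peaks, mitotic signal
# dispersal, and Poisson + Gaussian detector noise.  Every run returns the
# movie together with full ground truth (label masks, tracks, true N/C
# values, focus positions and peak times, stage labels).

#' Intensity trajectories for the nuclear/cytoplasmic ratio
#'
#' `traj_constant` holds the true N/C ratio fixed; `traj_ramp` rises
#' linearly from `from` to `to` between `t_start_s` and `t_end_s` (clamped
#' outside), emulating the gradual nuclear enrichment of a modification
#' across developmental stages.
#'
#' @param value,from,to dimensionless N/C ratio values.
#' @param t_start_s,t_end_s ramp interval in seconds.
#' @return a trajectory specification (list) usable in [channel_spec()].
#' @export
traj_constant <- function(value) {
  stopifnot(value >= 0)
  list(type = "constant", value = value)
}

#' @rdname traj_constant
#' @export
traj_ramp <- function(from, to, t_start_s, t_end_s) {
  stopifnot(from >= 0, to >= 0, t_end_s > t_start_s)
  list(type = "ramp", from = from, to = to,
       t_start_s = t_start_s, t_end_s = t_end_s)
}

#' Evaluate a trajectory at time t (seconds); vectorised over t.
#' @param traj a trajectory from [traj_constant()] / [traj_ramp()].
#' @param t time(s) in seconds.
#' @export
traj_value <- function(traj, t) {
  switch(traj$type,
    constant = rep(traj$value, length(t)),
    ramp = {
      f <- pmin(1, pmax(0, (t - traj$t_start_s) /
                             (traj$t_end_s - traj$t_start_s)))
      traj$from + f * (traj$to - traj$from)
    },
    stop("unknown trajectory type"))
}

#' Intranuclear focus specification
#'
#' Foci are rendered as 3D Gaussians whose amplitude follows a triangular
#' ramp: zero before `onset_time_s`, rising linearly to 1 at `peak_time_s`,
#' then fading linearly to zero over `fade_time_s` (default: symmetric with
#' the rise).  At peak, the focus adds `amplitude` times the nuclear mean
#' signal (above background) at its centre.
#'
#' @param n_foci foci per nucleus (1 or 2; two emulates the two alleles of a
#'   single early-transcribed locus).
#' @param onset_time_s,peak_time_s absolute times (s).
#' @param fade_time_s fall duration (s).
#' @param amplitude peak amplitude as a multiple of the nuclear mean.
#' @param sigma_um Gaussian width (um).
#' @param offset_frac focus centre offset from the nucleus centre, as a
#'   fraction of the nucleus radius.
#' @export
foci_spec <- function(n_foci = 2, onset_time_s, peak_time_s,
                      fade_time_s = peak_time_s - onset_time_s,
                      amplitude = 4, sigma_um = 0.6, offset_frac = 0.4) {
  stopifnot(n_foci >= 1, n_foci <= 2, peak_time_s > onset_time_s,
            fade_time_s > 0, amplitude >= 0, sigma_um > 0)
  list(n_foci = as.integer(n_foci), onset_time_s = onset_time_s,
       peak_time_s = peak_time_s, fade_time_s = fade_time_s,
       amplitude = amplitude, sigma_um = sigma_um,
       offset_frac = offset_frac)
}

#' Channel specification for the simulator
#'
#' @param name channel name.
#' @param nc N/C ratio trajectory ([traj_constant()] / [traj_ramp()]); this
#'   is the background-subtracted ratio, so nuclei are rendered at
#'   `background + nc * (cytoplasm_level - background)`.
#' @param cytoplasm_level absolute cytoplasmic signal level inside the
#'   embryo (detector units; must exceed the background).
#' @param foci optional [foci_spec()].
#' @export
channel_spec <- function(name, nc, cytoplasm_level, foci = NULL) {
  stopifnot(is.character(name), cytoplasm_level > 0)
  list(name = name, nc = nc, cytoplasm_level = cytoplasm_level, foci = foci)
}

#' Simulation configuration
#'
#' Defaults describe a confocal-like recording of one animal-pole field of
#' view across two cleavage cycles: 0.8 um lateral pixels, 4 um z-steps,
#' 1 min frame interval, 15 min cycles with a 3 min mitotic phase, and
#' nuclei that shrink each cycle.
#'
#' @param field_dim named integer vector `c(z=, y=, x=)`, voxels.
#' @param spacing_um named vector `c(z=, y=, x=)`, um/voxel.
#' @param frame_interval_s seconds between frames.
#' @param n_frames number of frames.
#' @param n_initial nuclei present in the field at t = 0.
#' @param cycle_length_s cell-cycle length (s).
#' @param mitosis_duration_s length of the mitotic phase ending each cycle
#'   (s); during it nuclear signal disperses into the cytoplasm and no
#'   interphase ground truth exists.
#' @param nucleus_radius_um nucleus radius in the first cycle (um).
#' @param radius_shrink multiplicative radius change per cycle.
#' @param motion_sd_um per-frame random-walk displacement s.d. of nucleus
#'   centres (um, per lateral axis; axial motion is 1/4 of this).
#' @param channels list of [channel_spec()]s; the first channel is
#'   conventionally the nuclear marker.
#' @param background diffuse background level (detector units).
#' @param noise list with `poisson` (logical), `gain` (detector units per
#'   photon-equivalent) and `gaussian_sd` (additive read noise, detector
#'   units).
#' @param initial_stage_count embryo-wide nucleus count at t = 0 (power of
#'   2); together with `n_initial` it fixes the field-of-view fraction.
#' @param embryo_radius_frac lateral semi-axes of the blastoderm cap as a
#'   fraction of the field extent.  Cytoplasm fills this ellipse (all z);
#'   outside lies pure background, which is what far-field background
#'   estimation relies on.  The cap does not grow as cells divide.
#' @param placement_clearance_um nuclei are kept this far (plus their
#'   radius) inside the cap boundary, so the full cytoplasmic ring of every
#'   nucleus stays within the embryo.
#' @param background_gradient optional peak-to-peak amplitude of an additive
#'   low-frequency background ramp across x (detector units), to stress
#'   background estimation.
#' @param seed RNG seed making the simulation fully reproducible.
#' @return validated `sim_config` object.
#' @export
sim_config <- function(field_dim = c(z = 8, y = 256, x = 256),
                       spacing_um = c(z = 4, y = 0.8, x = 0.8),
                       frame_interval_s = 60,
                       n_frames = 30,
                       n_initial = 8,
                       cycle_length_s = 900,
                       mitosis_duration_s = 180,
                       nucleus_radius_um = 5,
                       radius_shrink = 0.8,
                       motion_sd_um = 0.3,
                       channels = list(
                         channel_spec("marker", traj_constant(4), 200),
                         channel_spec("signal", traj_ramp(1, 3, 0, 1500), 200)
                       ),
                       background = 50,
                       noise = list(poisson = TRUE, gain = 1,
                                    gaussian_sd = 4),
                       initial_stage_count = 64,
                       embryo_radius_frac = 0.2,
                       placement_clearance_um = 9.5,
                       background_gradient = 0,
                       seed = 1) {
  field_dim <- field_dim[c("z", "y", "x")]
  spacing_um <- .check_spacing(spacing_um)
  stopifnot(all(field_dim >= 1), frame_interval_s > 0, n_frames >= 1,
            n_initial >= 1, cycle_length_s > 0,
            mitosis_duration_s > 0, mitosis_duration_s < cycle_length_s,
            nucleus_radius_um > 0, radius_shrink > 0,
            length(channels) >= 1, background >= 0)
  if (log2(initial_stage_count) %% 1 != 0)
    stop("initial_stage_count must be a power of 2")
  nm <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate channel names")
  names(channels) <- nm
  for (ch in channels)
    if (ch$cytoplasm_level <= background)
      stop("cytoplasm_level of channel '", ch$name,
           "' must exceed the background")
  structure(list(
    field_dim = field_dim, spacing_um = spacing_um,
    frame_interval_s = frame_interval_s, n_frames = n_frames,
    n_initial = n_initial, cycle_length_s = cycle_length_s,
    mitosis_duration_s = mitosis_duration_s,
    nucleus_radius_um = nucleus_radius_um, radius_shrink = radius_shrink,
    motion_sd_um = motion_sd_um, channels = channels,
    background = background, noise = noise,
    initial_stage_count = initial_stage_count,
    fov_fraction = n_initial / initial_stage_count,
    embryo_radius_frac = embryo_radius_frac,
    placement_clearance_um = placement_clearance_um,
    background_gradient = background_gradient,
    seed = seed), class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors the arguments of [sim_config()]; trajectories are given
#' as mappings with a `type` key (`constant` / `ramp`) and foci as mappings
#' mirroring [foci_spec()].
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$channels)) {
    y$channels <- lapply(y$channels, function(ch) {
      nc <- ch$nc
      nc <- if (identical(nc$type, "constant")) traj_constant(nc$value)
            else traj_ramp(nc$from, nc$to, nc$t_start_s, nc$t_end_s)
      fs <- if (!is.null(ch$foci)) do.call(foci_spec, ch$foci) else NULL
      channel_spec(ch$name, nc, ch$cytoplasm_level, fs)
    })
  }
  for (f in c("field_dim", "spacing_um"))
    if (!is.null(y[[f]])) {
      v <- unlist(y[[f]])
      # YAML 1.1 parses a bare `y` key as boolean TRUE
      names(v)[names(v) == "TRUE"] <- "y"
      y[[f]] <- v
    }
  do.call(sim_config, y)
}

# stage label from an embryo-wide nucleus count
.stage_label <- function(n) {
  ifelse(n >= 1024 & n %% 1024 == 0, paste0(n %/% 1024, "k-cell"),
         paste0(n, "-cell"))
}

# run code with a private, restored RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# blastoderm-cap geometry: nuclei live inside a lateral ellipse shrunk by
# (radius + clearance), with a z margin of one radius
.cap_geometry <- function(ext_um, frac, clearance) {
  list(cz = ext_um[1] / 2, cy = ext_um[2] / 2, cx = ext_um[3] / 2,
       ay = frac * ext_um[2], ax = frac * ext_um[3],
       ext = ext_um, clearance = clearance)
}

.clamp_cap <- function(p, geom, r) {
  # p = c(z, y, x); pull back into the shrunk ellipse and z margins
  ay <- max(geom$ay - r - geom$clearance, 1e-6)
  ax <- max(geom$ax - r - geom$clearance, 1e-6)
  dy <- p[2] - geom$cy; dx <- p[3] - geom$cx
  rho <- sqrt((dy / ay)^2 + (dx / ax)^2)
  if (rho > 1) { dy <- dy / rho; dx <- dx / rho }
  zlo <- min(r, geom$ext[1] / 2)
  c(min(max(p[1], zlo), max(geom$ext[1] - zlo, zlo)),
    geom$cy + dy, geom$cx + dx)
}

# sample a placement for n nuclei with pairwise centre separation
# >= sep_frac * 2r, inside the cap; bounded retries
.place_nuclei <- function(n, geom, r, sep_frac = 1.05, max_tries = 2000) {
  centers <- matrix(NA_real_, n, 3) # columns z,y,x (um)
  ay <- max(geom$ay - r - geom$clearance, 1e-6)
  ax <- max(geom$ax - r - geom$clearance, 1e-6)
  zlo <- min(r, geom$ext[1] / 2)
  zhi <- max(geom$ext[1] - zlo, zlo)
  sep2 <- (sep_frac * 2 * r)^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      repeat {
        dy <- runif(1, -1, 1); dx <- runif(1, -1, 1)
        if (dy^2 + dx^2 <= 1) break
      }
      p <- c(runif(1, zlo, zhi), geom$cy + dy * ay, geom$cx + dx * ax)
      if (i == 1) { ok <- TRUE } else {
        d2 <- colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - p)^2)
        ok <- all(d2 >= sep2)
      }
      if (ok) { centers[i, ] <- p; break }
    }
    if (!ok) stop("placement-overflow: could not place ", n,
                  " non-overlapping nuclei in the blastoderm cap")
  }
  centers
}

#' Simulate a multichannel embryo movie with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `movie` (a [multichannel_movie()] of integer detector
#'   counts) and `ground_truth`, a list holding `labels` (integer array
#'   (y, x, z, frame); 0 outside nuclei, per-frame labels), and measurement
#'   tables `tracks` (`gt_tracks`), `nc` (`gt_nc`), `foci` (`gt_foci`) and
#'   `stages` (`gt_stages`).
#' @export
simulate_embryo_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  .with_seed(cf$seed, {
    ny <- cf$field_dim[["y"]]; nx <- cf$field_dim[["x"]]
    nz <- cf$field_dim[["z"]]; nt <- cf$n_frames
    sp <- cf$spacing_um # c(z,y,x)
    ext_um <- c(nz * sp[["z"]], ny * sp[["y"]], nx * sp[["x"]]) # z,y,x

    dt <- cf$frame_interval_s
    times <- (seq_len(nt) - 1) * dt
    cycle_of <- floor(times / cf$cycle_length_s)
    in_interphase <- (times %% cf$cycle_length_s) <
      (cf$cycle_length_s - cf$mitosis_duration_s)

    # nucleus state
    r0 <- cf$nucleus_radius_um
    geom <- .cap_geometry(ext_um, cf$embryo_radius_frac,
                          cf$placement_clearance_um)
    nuc <- data.frame(track_id = seq_len(cf$n_initial),
                      z = NA_real_, y = NA_real_, x = NA_real_,
                      radius = r0)
    nuc[, c("z", "y", "x")] <- .place_nuclei(cf$n_initial, geom, r0)
    next_id <- cf$n_initial + 1L

    # fixed per-channel focus direction offsets (unit vectors, mostly
    # lateral), sampled per nucleus and inherited by daughters
    foci_channels <- names(cf$channels)[!vapply(cf$channels, function(ch)
      is.null(ch$foci), logical(1))]
    sample_offsets <- function(nfoci) {
      o <- matrix(rnorm(3 * nfoci), nfoci, 3)
      o[, 1] <- o[, 1] * 0.25
      o <- o / sqrt(rowSums(o^2))
      # two foci (sister alleles) sit in opposite hemispheres, so they are
      # always resolvable at the configured offset
      if (nfoci == 2) o[2, ] <- -o[1, ]
      o
    }
    offsets <- list() # track_id -> list(channel -> unit matrix)
    add_offsets <- function(ids) {
      for (id in ids) {
        offsets[[as.character(id)]] <<- lapply(cf$channels, function(ch) {
          if (is.null(ch$foci)) NULL else sample_offsets(ch$foci$n_foci)
        })
      }
    }
    add_offsets(nuc$track_id)

    # outputs
    channels <- lapply(cf$channels, function(ch)
      array(NA_integer_, c(ny, nx, nz, nt)))
    labels <- array(0L, c(ny, nx, nz, nt))
    gt_tracks <- list(); gt_nc <- list(); gt_foci <- list()

    # voxel-centre coordinate vectors (um)
    yc <- (seq_len(ny) - 1) * sp[["y"]]
    xc <- (seq_len(nx) - 1) * sp[["x"]]
    zc <- (seq_len(nz) - 1) * sp[["z"]]
    grad <- if (cf$background_gradient > 0)
      matrix(rep(cf$background_gradient * (xc / max(xc[2], max(xc))),
                 each = ny), ny, nx) else NULL
    # blastoderm cap (lateral ellipse, all z): cytoplasm inside, pure
    # background outside
    cap2d <- outer(((yc - geom$cy) / geom$ay)^2,
                   ((xc - geom$cx) / geom$ax)^2, `+`) <= 1

    prev_cycle <- 0L
    for (f in seq_len(nt)) {
      t <- times[f]
      # division at the boundary into a new cycle
      if (cycle_of[f] > prev_cycle) {
        for (rep in seq_len(cycle_of[f] - prev_cycle)) {
          rnew <- nuc$radius[1] * cf$radius_shrink
          daughters <- vector("list", nrow(nuc))
          for (i in seq_len(nrow(nuc))) {
            placed <- FALSE
            for (try in 1:300) {
              u <- rnorm(3) * c(0.25, 1, 1)
              u <- u / sqrt(sum(u^2))
              # under crowding, retries progressively widen the push and
              # relax the separation requirement rather than failing
              mag <- 1.2 * rnew * (1 + 0.5 * runif(1))
              relax <- if (try <= 100) 1 else if (try <= 200) 0.8 else 0.6
              d1 <- as.numeric(nuc[i, c("z", "y", "x")]) + mag * u
              d2 <- as.numeric(nuc[i, c("z", "y", "x")]) - mag * u
              cand <- rbind(.clamp_cap(d1, geom, rnew),
                            .clamp_cap(d2, geom, rnew))
              others <- do.call(rbind, daughters[seq_len(i - 1)])
              minsep <- (1.9 * rnew * relax)^2
              ok <- sum((cand[1, ] - cand[2, ])^2) >= minsep * 0.8
              if (ok && !is.null(others)) {
                pos <- others[, c("z", "y", "x"), drop = FALSE]
                for (k in 1:2) {
                  dd <- colSums((t(pos) - cand[k, ])^2)
                  if (any(dd < minsep)) { ok <- FALSE; break }
                }
              }
              if (ok) { placed <- TRUE; break }
            }
            if (!placed)
              stop("placement-overflow: daughters could not be placed ",
                   "without overlap")
            ids <- c(next_id, next_id + 1L)
            daughters[[i]] <- data.frame(
              track_id = ids, z = cand[, 1], y = cand[, 2], x = cand[, 3],
              radius = rnew, parent = nuc$track_id[i])
            next_id <- next_id + 2L
          }
          newnuc <- do.call(rbind, daughters)
          add_offsets(newnuc$track_id)
          # daughters inherit focus offsets of the parent? independent draws
          nuc <- newnuc[, c("track_id", "z", "y", "x", "radius")]
        }
        prev_cycle <- cycle_of[f]
      }

      # random-walk motion (applied every frame after the first)
      if (f > 1 && cf$motion_sd_um > 0) {
        n <- nrow(nuc)
        step <- cbind(rnorm(n, 0, cf$motion_sd_um * 0.25),
                      rnorm(n, 0, cf$motion_sd_um),
                      rnorm(n, 0, cf$motion_sd_um))
        pos <- as.matrix(nuc[, c("z", "y", "x")]) + step
        for (i in seq_len(n))
          pos[i, ] <- .clamp_cap(pos[i, ], geom, nuc$radius[i])
        nuc[, c("z", "y", "x")] <- pos
      }

      interphase <- in_interphase[f]
      # per-channel ideal images: background outside the cap, absolute
      # cytoplasm level inside
      ideal <- lapply(cf$channels, function(ch) {
        base <- matrix(cf$background, ny, nx)
        base[cap2d] <- ch$cytoplasm_level
        if (!is.null(grad)) base <- base + grad
        array(rep(base, nz), c(ny, nx, nz))
      })
      labf <- array(0L, c(ny, nx, nz))

      if (interphase) {
        for (i in seq_len(nrow(nuc))) {
          cz <- nuc$z[i]; cy <- nuc$y[i]; cx <- nuc$x[i]; r <- nuc$radius[i]
          iy <- which(abs(yc - cy) <= r)
          ix <- which(abs(xc - cx) <= r)
          iz <- which(abs(zc - cz) <= r)
          if (!length(iy) || !length(ix) || !length(iz)) next
          dy2 <- (yc[iy] - cy)^2; dx2 <- (xc[ix] - cx)^2
          dz2 <- (zc[iz] - cz)^2
          inside <- outer(outer(dy2, dx2, `+`), dz2, `+`) <= r^2
          # label mask
          sub <- labf[iy, ix, iz, drop = FALSE]
          sub[inside] <- i
          labf[iy, ix, iz] <- sub
          g_in <- if (!is.null(grad)) {
            g3 <- array(rep(grad[iy, ix, drop = FALSE], length(iz)),
                        dim(inside))
            g3[inside]
          } else 0
          for (cn in names(cf$channels)) {
            ch <- cf$channels[[cn]]
            ncv <- traj_value(ch$nc, t)
            vol <- ideal[[cn]][iy, ix, iz, drop = FALSE]
            vol[inside] <- cf$background +
              ncv * (ch$cytoplasm_level - cf$background) + g_in
            ideal[[cn]][iy, ix, iz] <- vol
          }
          gt_tracks[[length(gt_tracks) + 1L]] <- data.frame(
            track_id = nuc$track_id[i], frame = f, label = i,
            centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx,
            phase = "interphase")
          for (cn in names(cf$channels)) {
            gt_nc[[length(gt_nc) + 1L]] <- data.frame(
              channel = cn, track_id = nuc$track_id[i], frame = f,
              nc_true = traj_value(cf$channels[[cn]]$nc, t))
          }
        }
        # foci (rendered during interphase only)
        for (cn in foci_channels) {
          ch <- cf$channels[[cn]]
          fs <- ch$foci
          amp_frac <- if (t < fs$onset_time_s) 0
            else if (t <= fs$peak_time_s)
              (t - fs$onset_time_s) / (fs$peak_time_s - fs$onset_time_s)
            else max(0, 1 - (t - fs$peak_time_s) / fs$fade_time_s)
          ncv <- traj_value(ch$nc, t)
          amp <- amp_frac * fs$amplitude * ncv *
            (ch$cytoplasm_level - cf$background)
          for (i in seq_len(nrow(nuc))) {
            u <- offsets[[as.character(nuc$track_id[i])]][[cn]]
            for (k in seq_len(fs$n_foci)) {
              ctr <- as.numeric(nuc[i, c("z", "y", "x")]) +
                fs$offset_frac * nuc$radius[i] * u[k, ]
              gt_foci[[length(gt_foci) + 1L]] <- data.frame(
                channel = cn, track_id = nuc$track_id[i], frame = f,
                focus_index = k, z_um = ctr[1], y_um = ctr[2],
                x_um = ctr[3], amplitude_frac = amp_frac,
                peak_time_s = fs$peak_time_s)
              if (amp <= 0) next
              s <- fs$sigma_um
              iy <- which(abs(yc - ctr[2]) <= 3 * s)
              ix <- which(abs(xc - ctr[3]) <= 3 * s)
              iz <- which(abs(zc - ctr[1]) <= 3 * s)
              if (!length(iy) || !length(ix) || !length(iz)) next
              gy <- exp(-0.5 * ((yc[iy] - ctr[2]) / s)^2)
              gx <- exp(-0.5 * ((xc[ix] - ctr[3]) / s)^2)
              gz <- exp(-0.5 * ((zc[iz] - ctr[1]) / s)^2)
              g <- outer(outer(gy, gx), gz)
              sub <- ideal[[cn]][iy, ix, iz, drop = FALSE]
              dim(g) <- dim(sub)
              ideal[[cn]][iy, ix, iz] <- sub + amp * g
            }
          }
        }
      } else {
        # mitosis: nuclear compartment disperses; nothing rendered, ground
        # truth carries phase only (no label)
        for (i in seq_len(nrow(nuc))) {
          gt_tracks[[length(gt_tracks) + 1L]] <- data.frame(
            track_id = nuc$track_id[i], frame = f, label = NA_integer_,
            centroid_z_um = nuc$z[i], centroid_y_um = nuc$y[i],
            centroid_x_um = nuc$x[i], phase = "mitosis")
        }
      }

      labels[, , , f] <- labf
      for (cn in names(cf$channels)) {
        v <- ideal[[cn]]
        if (isTRUE(cf$noise$poisson)) {
          gain <- cf$noise$gain %||% 1
          v <- gain * rpois(length(v), v / gain)
        }
        if ((cf$noise$gaussian_sd %||% 0) > 0)
          v <- v + rnorm(length(v), 0, cf$noise$gaussian_sd)
        v <- as.integer(pmin(pmax(round(v), 0), 65535))
        channels[[cn]][, , , f] <- v
      }
    }

    movie <- multichannel_movie(channels, sp, dt)
    stage_n <- cf$initial_stage_count * 2^cycle_of
    gt <- list(
      labels = labels,
      tracks = measurement_table(do.call(rbind, gt_tracks), "gt_tracks"),
      nc = measurement_table(do.call(rbind, gt_nc), "gt_nc"),
      foci = if (length(gt_foci))
        measurement_table(do.call(rbind, gt_foci), "gt_foci")
      else measurement_table(
        data.frame(channel = character(), track_id = integer(),
                   frame = integer(), focus_index = integer(),
                   z_um = numeric(), y_um = numeric(), x_um = numeric(),
                   amplitude_frac = numeric(), peak_time_s = numeric()),
        "gt_foci"),
      stages = measurement_table(
        data.frame(frame = seq_len(nt),
                   n_interphase = .count_interphase(gt_tracks, nt),
                   stage_label = .stage_label(stage_n)),
        "gt_stages"),
      config = cf)
    list(movie = movie, ground_truth = gt)
  })
}

# count interphase nuclei per frame from the accumulated gt rows
.count_interphase <- function(gt_tracks, nt) {
  df <- do.call(rbind, gt_tracks)
  df <- df[df$phase == "interphase", ]
  counts <- integer(nt)
  tb <- table(df$frame)
  counts[as.integer(names(tb))] <- as.integer(tb)
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a FRAP recovery curve
#'
#' Forward model of double-exponential association recovery: pre-bleach
#' frames have relative intensity 1; from the first post-bleach frame,
#' `I(t) = p1 (1 - exp(-k1 t)) + p2 (1 - exp(-k2 t)) + c` with `t` the time
#' since bleaching (t = 0 at the first post-bleach frame).  I.i.d. Gaussian
#' noise is added on top.
#'
#' @param p1,p2 plateau fractions of the two recovering populations.
#' @param k1,k2 rate constants (1/s), must be positive.
#' @param c baseline (unbleached) fraction.
#' @param times strictly increasing sample times (s).
#' @param bleach_index number of pre-bleach frames (>= 1); the bleach event
#'   falls between samples `bleach_index` and `bleach_index + 1`.
#' @param noise_sd Gaussian noise s.d. (relative-intensity units).
#' @param seed optional RNG seed.
#' @return list with `curve` (a [frap_curve()], background 0) and `truth`
#'   (the generating parameters).
#' @export
simulate_frap_curve <- function(p1, k1, p2, k2, c, times, bleach_index,
                                noise_sd = 0, seed = NULL) {
  if (k1 <= 0 || k2 <= 0)
    stop("invalid-parameter: rate constants must be positive")
  stopifnot(p1 >= 0, p2 >= 0, c >= 0, bleach_index >= 1,
            bleach_index < length(times))
  if (p1 + p2 + c > 1 + 1e-6)
    stop("invalid-parameter: p1 + p2 + c must not exceed 1")
  gen <- function() {
    n <- length(times)
    post <- (bleach_index + 1):n
    tt <- times[post] - times[bleach_index + 1]
    ideal <- c(rep(1, bleach_index),
               p1 * (1 - exp(-k1 * tt)) + p2 * (1 - exp(-k2 * tt)) + c)
    raw <- ideal + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    list(curve = frap_curve(times, raw, background = 0,
                            bleach_index = bleach_index),
         truth = list(p1 = p1, k1 = k1, p2 = p2, k2 = k2, c = c))
  }
  if (!is.null(seed)) .with_seed(seed, gen()) else gen()
}
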