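# Pipeline driver
# ---------------
# Each stage reads its upstream artifacts from the output directory and
# writes its own, so the manual-correction loop (edit the corrections CSV,
# re-run `track` onward) works exactly like the original review workflow.
# A run manifest records the resolved configuration hash, seed and package
# version; identical configuration and inputs reproduce identical tables.

#' Pipeline configuration
#'
#' @param output_dir directory for all stage artifacts.
#' @param input_movie optional path to an existing TIFF; when absent, the
#'   `simulate` stage generates one from `simulation`.
#' @param marker_channel channel used for segmentation and tracking.
#' @param channels channels to quantify (default: all).
#' @param simulation a [sim_config()] used by the `simulate` stage.
#' @param segmentation a [segmentation_params()].
#' @param ring a [ring_params()].
#' @param foci a [foci_params()].
#' @param tracking list with `max_displacement_um`, `max_gap`.
#' @param reference_stage stage label for N/C normalisation (e.g.
#'   `"32-cell"`); `NULL` skips normalisation.
#' @param corrections optional path of a corrections CSV applied by the
#'   `track` stage.
#' @param frap list with `input_csv`, `bleach_index` (optional) and
#'   `fit_start_offset` for the `frap` stage.
#' @param seed seed recorded in the manifest and used for simulation.
#' @export
pipeline_config <- function(output_dir,
                            input_movie = NULL,
                            marker_channel = "marker",
                            channels = NULL,
                            simulation = sim_config(),
                            segmentation = segmentation_params(),
                            ring = ring_params(),
                            foci = foci_params(),
                            tracking = list(max_displacement_um = 10,
                                            max_gap = 1),
                            reference_stage = NULL,
                            corrections = NULL,
                            frap = NULL,
                            seed = 1) {
  simulation$seed <- seed
  structure(list(output_dir = output_dir, input_movie = input_movie,
                 marker_channel = marker_channel, channels = channels,
                 simulation = simulation, segmentation = segmentation,
                 ring = ring, foci = foci, tracking = tracking,
                 reference_stage = reference_stage,
                 corrections = corrections, frap = frap, seed = seed),
            class = "pipeline_config")
}

.artifact <- function(cfg, name) file.path(cfg$output_dir, name)

.require_artifact <- function(cfg, name, stage) {
  p <- .artifact(cfg, name)
  if (!file.exists(p))
    stop("missing-upstream: stage '", stage, "' needs '", name,
         "'; run the producing stage first")
  p
}

.load_movie <- function(cfg) {
  p <- if (!is.null(cfg$input_movie)) cfg$input_movie
       else .require_artifact(cfg, "movie.tif", "segment")
  read_stack(p)
}

.load_labels <- function(cfg, stage) {
  p <- .require_artifact(cfg, "labels.tif", stage)
  lm <- read_stack(p)
  lm$channels[["labels"]]
}

#' Run pipeline stages
#'
#' Commands: `simulate` writes the synthetic movie, ground truth and label
#' masks; `segment` segments every frame of the movie and writes nuclei +
#' intensity tables and detected label masks; `track` links tracks (and
#' applies the corrections CSV when configured) and annotates stages;
#' `quantify` measures N/C ratios (and stage-normalised ratios when a
#' reference stage is set); `foci` measures foci/nucleus ratio time
#' courses; `frap` fits the configured recovery CSV; `all` chains
#' simulate-or-load, segment, track, quantify and foci.
#'
#' @param command one of `simulate`, `segment`, `track`, `quantify`,
#'   `foci`, `frap`, `all`.
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(command = c("all", "simulate", "segment", "track",
                                     "quantify", "foci", "frap"),
                         config) {
  command <- match.arg(command)
  cfg <- config
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  w <- function(nm, p) written[[nm]] <<- p

  if (command %in% c("simulate", "all") && is.null(cfg$input_movie)) {
    sim <- simulate_embryo_movie(cfg$simulation)
    w("movie", write_stack(sim$movie, .artifact(cfg, "movie.tif")))
    glab <- multichannel_movie(list(labels = sim$ground_truth$labels),
                               sim$movie$spacing,
                               sim$movie$frame_interval)
    w("gt_labels", write_stack(glab, .artifact(cfg, "gt_labels.tif")))
    for (nm in c("tracks", "nc", "foci", "stages")) {
      p <- .artifact(cfg, paste0("gt_", nm, ".csv"))
      write_table(sim$ground_truth[[nm]], p)
      w(paste0("gt_", nm), p)
    }
  }

  if (command %in% c("segment", "all")) {
    movie <- .load_movie(cfg)
    nt <- n_frames(movie)
    labs <- array(0L, dim(movie$channels[[1]]))
    nuclei <- list(); intens <- list()
    for (f in seq_len(nt)) {
      seg <- segment_nuclei_frame(movie, f, cfg$marker_channel,
                                  cfg$segmentation)
      seg <- flag_mitotic(seg, movie, cfg$marker_channel, cfg$segmentation)
      labs[, , , f] <- seg$labels
      nuclei[[f]] <- as.data.frame(seg$nuclei)
      intens[[f]] <- as.data.frame(seg$intensity)
    }
    lm <- multichannel_movie(list(labels = labs), movie$spacing,
                             movie$frame_interval)
    w("labels", write_stack(lm, .artifact(cfg, "labels.tif")))
    nt1 <- measurement_table(do.call(rbind, nuclei), "nuclei")
    it1 <- measurement_table(do.call(rbind, intens), "nucleus_intensity")
    w("nuclei", write_table(nt1, .artifact(cfg, "nuclei.csv")))
    w("intensity",
      write_table(it1, .artifact(cfg, "nucleus_intensity.csv")))
  }

  if (command %in% c("track", "all")) {
    nuclei <- read_table(.require_artifact(cfg, "nuclei.csv", "track"),
                         "nuclei")
    ts <- link_tracks(nuclei, cfg$tracking$max_displacement_um,
                      cfg$tracking$max_gap)
    if (!is.null(cfg$corrections) && file.exists(cfg$corrections))
      ts <- apply_corrections(ts, cfg$corrections)
    w("tracks", write_table(ts$tracks, .artifact(cfg, "tracks.csv")))
    movie <- .load_movie(cfg)
    counts <- integer(n_frames(movie))
    ok <- !grepl("mitotic", nuclei$qc_flags)
    tb <- table(nuclei$frame[ok])
    counts[as.integer(names(tb))] <- as.integer(tb)
    st <- annotate_stages(counts, cfg$simulation$initial_stage_count,
                          cfg$simulation$fov_fraction)
    w("stages", write_table(st, .artifact(cfg, "stages.csv")))
  }

  if (command %in% c("quantify", "all")) {
    movie <- .load_movie(cfg)
    tracks <- read_table(.require_artifact(cfg, "tracks.csv", "quantify"),
                         "tracks")
    stages <- read_table(.require_artifact(cfg, "stages.csv", "quantify"),
                         "stages")
    labels <- .load_labels(cfg, "quantify")
    nc <- measure_nc(movie, tracks, labels, cfg$channels, cfg$ring,
                     stages = stages)
    w("nc_ratio", write_table(nc, .artifact(cfg, "nc_ratio.csv")))
    if (!is.null(cfg$reference_stage)) {
      rel <- normalize_to_stage(nc, cfg$reference_stage)
      w("nc_relative",
        write_table(rel, .artifact(cfg, "nc_relative.csv")))
    }
  }

  if (command %in% c("foci", "all")) {
    movie <- .load_movie(cfg)
    tracks <- read_table(.require_artifact(cfg, "tracks.csv", "foci"),
                         "tracks")
    labels <- .load_labels(cfg, "foci")
    ft <- measure_foci(movie, tracks, labels, cfg$channels, cfg$foci)
    w("foci", write_table(ft, .artifact(cfg, "foci.csv")))
  }

  if (command == "frap") {
    if (is.null(cfg$frap) || is.null(cfg$frap$input_csv))
      stop("missing-upstream: frap stage needs frap$input_csv")
    curve <- read_frap_csv(cfg$frap$input_csv, cfg$frap$bleach_index)
    fit <- fit_double_exponential(curve,
                                  cfg$frap$fit_start_offset %||% 4)
    w("frap_fit",
      write_table(frap_fit_table(fit), .artifact(cfg, "frap_fit.csv")))
  }

  manifest <- .artifact(cfg, "run-manifest.json")
  cfg_json <- .artifact(cfg, "config.resolved.json")
  jsonlite::write_json(.serialize_config(cfg), cfg_json,
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(command = command,
         config_md5 = unname(tools::md5sum(cfg_json)),
         seed = cfg$seed,
         package_version = as.character(utils::packageVersion("fabquant")),
         artifacts = written),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(written)
}

# flatten a pipeline_config into plain lists for hashing/serialisation
.serialize_config <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}
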