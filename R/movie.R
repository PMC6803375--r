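#' Multichannel time-lapse movie
#'
#' Container for a multichannel 3D+time fluorescence stack together with its
#' physical metadata.  Each channel is a 4D array with dimensions
#' (y, x, z, frame); all channels must share one shape.  Intensities are kept
#' in raw detector units and are never rescaled on input; any normalisation
#' is explicit in downstream operations.
#'
#' @param channels named list of 4D numeric/integer arrays (y, x, z, frame).
#'   3D arrays are promoted to a single z-plane movie, 2D to a single-plane
#'   single-frame image.
#' @param spacing named numeric vector `c(z=, y=, x=)`, voxel size in um.
#' @param frame_interval time between frames, seconds.
#' @param t0 acquisition start time in seconds (default 0).
#' @return an object of class `multichannel_movie`.
#' @export
multichannel_movie <- function(channels, spacing, frame_interval, t0 = 0) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)))
    stop("channels must be a non-empty named list of arrays")
  channels <- lapply(channels, function(a) {
    d <- dim(a)
    if (is.null(d)) stop("each channel must be an array")
    if (length(d) == 2L) dim(a) <- c(d, 1L, 1L)
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    if (length(dim(a)) != 4L) stop("channel arrays must have 2-4 dimensions")
    a
  })
  d0 <- dim(channels[[1]])
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), d0))
      stop("all channels must share identical shape (channel '", nm, "' differs)")
  }
  spacing <- .check_spacing(spacing)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(
    list(channels = channels, spacing = spacing,
         frame_interval = as.numeric(frame_interval), t0 = as.numeric(t0)),
    class = "multichannel_movie")
}

#' @export
print.multichannel_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("multichannel_movie:", paste(names(x$channels), collapse = ", "), "\n")
  cat(sprintf("  %d frame(s), %d z-plane(s), %d x %d pixels\n",
              d[4], d[3], d[1], d[2]))
  cat(sprintf("  spacing (z,y,x) = (%g, %g, %g) um; frame interval = %g s\n",
              x$spacing["z"], x$spacing["y"], x$spacing["x"],
              x$frame_interval))
  invisible(x)
}

#' @export
dim.multichannel_movie <- function(x) dim(x$channels[[1]])

#' Number of frames / z-planes of a movie
#' @param movie a `multichannel_movie`.
#' @export
n_frames <- function(movie) dim(movie$channels[[1]])[4]

#' @rdname n_frames
#' @export
n_z <- function(movie) dim(movie$channels[[1]])[3]

#' Time points of all frames (seconds)
#' @param movie a `multichannel_movie`.
#' @export
frame_times <- function(movie) {
  movie$t0 + (seq_len(n_frames(movie)) - 1) * movie$frame_interval
}

#' Extract one 3D volume
#' @param movie a `multichannel_movie`.
#' @param channel channel name.
#' @param frame 1-based frame index.
#' @return numeric array (y, x, z).
#' @export
movie_volume <- function(movie, channel, frame) {
  if (!channel %in% names(movie$channels))
    stop("unknown channel '", channel, "'")
  nt <- n_frames(movie)
  if (frame < 1 || frame > nt) stop("frame out of range [1, ", nt, "]")
  a <- movie$channels[[channel]][, , , frame, drop = FALSE]
  dim(a) <- dim(a)[1:3]
  a
}

# ---------------------------------------------------------------------------
# OME-XML metadata

#' Parse OME-XML pixel metadata
#'
#' Extracts the subset of an OME-XML document the pipeline needs: physical
#' voxel sizes, frame interval, array sizes, dimension order and channel
#' names.  Sizes are assumed to be in the OME default units (um for physical
#' sizes, s for TimeIncrement).
#'
#' @param xml a string containing an OME-XML document.
#' @return list with elements `spacing`, `frame_interval`, `sizes`
#'   (named integer vector x,y,z,c,t), `dimension_order`, `channel_names`.
#' @export
parse_ome_xml <- function(xml) {
  doc <- xml2::read_xml(xml)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) stop("no <Pixels> element in OME-XML")
  at <- function(a) xml2::xml_attr(px, a)
  num <- function(a) suppressWarnings(as.numeric(at(a)))
  spacing <- c(z = num("PhysicalSizeZ"), y = num("PhysicalSizeY"),
               x = num("PhysicalSizeX"))
  sizes <- c(x = as.integer(at("SizeX")), y = as.integer(at("SizeY")),
             z = as.integer(at("SizeZ")), c = as.integer(at("SizeC")),
             t = as.integer(at("SizeT")))
  chn <- xml2::xml_find_all(px, ".//*[local-name()='Channel']")
  channel_names <- xml2::xml_attr(chn, "Name")
  list(spacing = spacing,
       frame_interval = num("TimeIncrement"),
       sizes = sizes,
       dimension_order = at("DimensionOrder"),
       channel_names = channel_names)
}

# page index mapping: given dimension order (after XY) and sizes, return a
# data.frame of (z, c, t) for each page, 1-based
.page_index <- function(order, nz, nc, nt) {
  rest <- strsplit(sub("^XY", "", order), "")[[1]]
  if (!setequal(rest, c("Z", "C", "T")))
    stop("unsupported DimensionOrder '", order, "'")
  n <- c(Z = nz, C = nc, T = nt)
  grid <- do.call(expand.grid, lapply(rest, function(a) seq_len(n[[a]])))
  names(grid) <- rest
  grid[, c("Z", "C", "T")]
}

# ---------------------------------------------------------------------------
# Reading and writing stacks

#' Read a multichannel TIFF / OME-TIFF stack
#'
#' Reads a multi-page TIFF and assembles it into a [multichannel_movie()].
#' Metadata are taken from, in order of decreasing priority: explicit
#' arguments, an OME-XML ImageDescription embedded in the file, and a JSON
#' sidecar file (`<path>.meta.json`, as written by [write_stack()]).  Integer
#' pixel data are returned bit-exactly.
#'
#' @param path path to the TIFF file.
#' @param spacing optional named vector `c(z=, y=, x=)` um/voxel, overriding
#'   file metadata.
#' @param frame_interval optional frame interval (s), overriding metadata.
#' @param channel_names optional character vector of channel names.
#' @param shape optional list with `n_z`, `n_frames` (and optionally `n_c`)
#'   when the file carries no dimensional metadata.
#' @param dimension_order OME-style page order (default `"XYZCT"`), used when
#'   not given by metadata.
#' @param t0 acquisition start time (s).
#' @return a [multichannel_movie()].
#' @export
read_stack <- function(path, spacing = NULL, frame_interval = NULL,
                       channel_names = NULL, shape = NULL,
                       dimension_order = NULL, t0 = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)

  meta <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && nzchar(desc) && grepl("<", desc, fixed = TRUE)) {
    meta <- tryCatch(parse_ome_xml(desc), error = function(e) NULL)
  }
  sidecar <- paste0(path, ".meta.json")
  if (is.null(meta) && file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- list(
      spacing = unlist(sc$spacing_um)[c("z", "y", "x")],
      frame_interval = sc$frame_interval_s,
      sizes = c(x = NA, y = NA, z = sc$n_z, c = length(sc$channels),
                t = sc$n_frames),
      dimension_order = sc$dimension_order,
      channel_names = sc$channels)
    if (!is.null(sc$t0_s)) t0 <- sc$t0_s
  }

  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing) || any(is.na(spacing)))
    stop("missing-spacing: no voxel size in file metadata and no ",
         "`spacing` override supplied")
  spacing <- .check_spacing(spacing)
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval
  if (is.null(frame_interval) || is.na(frame_interval)) frame_interval <- 1
  if (is.null(dimension_order)) dimension_order <- meta$dimension_order
  if (is.null(dimension_order) || is.na(dimension_order))
    dimension_order <- "XYZCT"

  nz <- nc <- nt <- NA_integer_
  if (!is.null(meta)) {
    nz <- meta$sizes[["z"]]; nc <- meta$sizes[["c"]]; nt <- meta$sizes[["t"]]
  }
  if (!is.null(shape)) {
    if (!is.null(shape$n_z)) nz <- shape$n_z
    if (!is.null(shape$n_frames)) nt <- shape$n_frames
    if (!is.null(shape$n_c)) nc <- shape$n_c
  }
  if (is.na(nc) && !is.null(channel_names)) nc <- length(channel_names)
  # fill a single unknown from the page count
  known <- c(z = nz, c = nc, t = nt)
  if (sum(is.na(known)) == 1L) {
    known[is.na(known)] <- npages / prod(known, na.rm = TRUE)
  } else if (sum(is.na(known)) > 1L) {
    if (npages == 1L) known[is.na(known)] <- 1L
    else stop("axis-ambiguity: cannot infer (z, channel, frame) layout of ",
              npages, " pages; supply `shape`")
  }
  nz <- as.integer(known[["z"]]); nc <- as.integer(known[["c"]])
  nt <- as.integer(known[["t"]])
  if (nz * nc * nt != npages || nz < 1)
    stop("axis-ambiguity: page count ", npages, " does not factor into z=",
         nz, " x c=", nc, " x t=", nt)

  if (is.null(channel_names)) channel_names <- meta$channel_names
  if (is.null(channel_names) || length(channel_names) != nc ||
      any(is.na(channel_names)))
    channel_names <- paste0("ch", seq_len(nc))

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  pid <- .page_index(dimension_order, nz, nc, nt)
  channels <- setNames(vector("list", nc), channel_names)
  int_data <- all(vapply(pages, is.integer, logical(1)))
  for (ci in seq_len(nc)) {
    a <- array(if (int_data) NA_integer_ else NA_real_, c(ny, nx, nz, nt))
    sel <- which(pid$C == ci)
    for (p in sel) a[, , pid$Z[p], pid$T[p]] <- pages[[p]]
    channels[[ci]] <- a
  }
  multichannel_movie(channels, spacing, frame_interval, t0)
}

#' Write a movie as a multi-page TIFF with a metadata sidecar
#'
#' Pages are written in `XYZCT` order (z fastest, then channel, then frame).
#' Integer data in \[0, 65535\] are stored as 16-bit samples and round-trip
#' bit-exactly through [read_stack()]; other numeric data are stored as
#' 32-bit floats.  Physical metadata go to a JSON sidecar `<path>.meta.json`.
#'
#' @param movie a [multichannel_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path) {
  stopifnot(inherits(movie, "multichannel_movie"))
  d <- dim(movie$channels[[1]])
  vals_int <- all(vapply(movie$channels, function(a) {
    is.integer(a) || all(a == round(a))
  }, logical(1)))
  maxv <- max(vapply(movie$channels, max, numeric(1)))
  minv <- min(vapply(movie$channels, min, numeric(1)))
  as16 <- vals_int && maxv <= 65535 && minv >= 0
  pages <- vector("list", d[3] * length(movie$channels) * d[4])
  p <- 1L
  for (tt in seq_len(d[4])) {
    for (ch in movie$channels) {
      for (zz in seq_len(d[3])) {
        pg <- ch[, , zz, tt]
        pages[[p]] <- if (as16) pg / 65535 else pg
        p <- p + 1L
      }
    }
  }
  if (as16) tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "none")
  else tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                       compression = "none")
  jsonlite::write_json(
    list(spacing_um = as.list(movie$spacing),
         frame_interval_s = movie$frame_interval,
         t0_s = movie$t0,
         channels = names(movie$channels),
         n_z = d[3], n_frames = d[4],
         dimension_order = "XYZCT",
         bits = if (as16) 16L else 32L),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
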