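# Tabular artifacts
# -----------------
# Every stage of the pipeline communicates through typed CSV tables
# ("measurement tables").  Each table carries a schema name; the column set
# per schema is fixed here.  CSVs are RFC 4180 with a header row, UTF-8,
# '.' decimal; numeric columns round-trip at full double precision.

# schema registry: column name -> readr column shorthand
.schemas <- list(
  nuclei = c(frame = "i", label = "i", centroid_z_um = "d",
             centroid_y_um = "d", centroid_x_um = "d", volume_um3 = "d",
             solidity = "d", qc_flags = "c"),
  nucleus_intensity = c(frame = "i", label = "i", channel = "c",
                        mean_intensity = "d", sum_intensity = "d"),
  tracks = c(track_id = "i", frame = "i", label = "i"),
  corrections = c(action = "c", frame = "i", label = "i",
                  target_track = "i"),
  stages = c(frame = "i", n_interphase = "i", cycle_index = "i",
             stage_label = "c"),
  nc_ratio = c(embryo_id = "c", track_id = "i", frame = "i", time_s = "d",
               channel = "c", nuc_mean = "d", cyto_mean = "d",
               nc_ratio = "d", background = "d", n_cyto_voxels = "i",
               stage_label = "c"),
  nc_relative = c(embryo_id = "c", track_id = "i", frame = "i",
                  time_s = "d", channel = "c", nuc_mean = "d",
                  cyto_mean = "d", nc_ratio = "d", background = "d",
                  n_cyto_voxels = "i", stage_label = "c",
                  relative_nc = "d"),
  nc_aggregate = c(group = "c", channel = "c", n_embryos = "i",
                   mean = "d", sd = "d"),
  foci = c(embryo_id = "c", track_id = "i", frame = "i", time_s = "d",
           channel = "c", focus_index = "i", z_um = "d", y_um = "d",
           x_um = "d", z_plane = "i", roi_sum = "d", roi_mean = "d",
           nucleus_sum = "d", nucleus_mean = "d", ratio_mean = "d",
           ratio_sum = "d"),
  frap_curve = c(frame = "i", time_s = "d", roi_intensity = "d",
                 background = "d"),
  frap_fit = c(p1 = "d", k1 = "d", p2 = "d", k2 = "d", c = "d",
               t_half_s = "d", residual_rms = "d", n_points_fit = "i",
               fit_start_offset = "i", f_single_vs_double = "d",
               p_single_vs_double = "d"),
  static_intensity = c(label = "i", channel = "c", mean_intensity = "d",
                       n_voxels = "i"),
  gt_tracks = c(track_id = "i", frame = "i", label = "i",
                centroid_z_um = "d", centroid_y_um = "d",
                centroid_x_um = "d", phase = "c"),
  gt_nc = c(channel = "c", track_id = "i", frame = "i", nc_true = "d"),
  gt_foci = c(channel = "c", track_id = "i", frame = "i",
              focus_index = "i", z_um = "d", y_um = "d", x_um = "d",
              amplitude_frac = "d", peak_time_s = "d"),
  gt_stages = c(frame = "i", n_interphase = "i", stage_label = "c")
)

#' Known measurement-table schemas
#' @return character vector of schema names.
#' @export
table_schemas <- function() names(.schemas)

#' Construct a measurement table
#'
#' Validates a data.frame against a named schema and tags it, so that
#' [write_table()] / [read_table()] can enforce the column contract.
#'
#' @param df a data.frame holding at least the schema's columns (order is
#'   normalised; columns outside the schema are dropped).
#' @param schema_name one of [table_schemas()].
#' @return the validated data.frame with class `measurement_table`.
#' @export
measurement_table <- function(df, schema_name) {
  sch <- .schemas[[schema_name]]
  if (is.null(sch)) stop("unknown schema '", schema_name, "'")
  missing <- setdiff(names(sch), names(df))
  if (length(missing))
    stop("schema-mismatch for '", schema_name, "': missing columns: ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, names(sch), drop = FALSE]
  rownames(df) <- NULL
  structure(df, schema_name = schema_name,
            class = c("measurement_table", "data.frame"))
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("measurement_table [", attr(x, "schema_name"), "], ",
      nrow(x), " rows\n", sep = "")
  NextMethod()
}

#' Write / read a measurement table as CSV
#'
#' Numeric values are written with a shortest round-trip representation, so
#' `read_table(write_table(t)) == t` at full double precision.
#'
#' @param table a [measurement_table()].
#' @param path CSV path; conventionally the file name carries the schema
#'   name (e.g. `embryo1.nc_ratio.csv`).
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  readr::write_csv(as.data.frame(table), path, na = "")
  invisible(path)
}

#' @rdname write_table
#' @param schema_name expected schema of the file.
#' @return `read_table`: the validated [measurement_table()].
#' @export
read_table <- function(path, schema_name) {
  sch <- .schemas[[schema_name]]
  if (is.null(sch)) stop("unknown schema '", schema_name, "'")
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing <- setdiff(names(sch), hdr)
  if (length(missing))
    stop("schema-mismatch reading '", path, "' as '", schema_name,
         "': missing columns: ", paste(missing, collapse = ", "))
  coltypes <- do.call(readr::cols, lapply(sch, function(t) {
    switch(t, i = readr::col_integer(), d = readr::col_double(),
           c = readr::col_character())
  }))
  df <- readr::read_csv(path, col_types = coltypes, na = c("", "NA"),
                        show_col_types = FALSE)
  measurement_table(as.data.frame(df), schema_name)
}
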