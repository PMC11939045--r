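#' Export a volume to NIfTI
#'
#' Writes an `rca_volume` (or one frame of an IQ series magnitude) as a
#' NIfTI file with voxel sizes in millimetres, axis order (x, y, z) =
#' (column position, row position, depth).
#'
#' @param volume An `rca_volume`.
#' @param path Output file (`.nii` / `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "rca_volume"))
  g <- volume$grid
  sp <- c(if (length(g$x) > 1) diff(g$x[1:2]) else 1e-4,
          if (length(g$y) > 1) diff(g$y[1:2]) else 1e-4,
          if (length(g$z) > 1) diff(g$z[1:2]) else 1e-4) * 1e3
  img <- RNifti::asNifti(volume$values, reference = NULL)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file written by [write_volume_nifti()].
#' @param origin Physical coordinates of the first voxel in metres.
#' @return An `rca_volume`.
#' @export
read_volume_nifti <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3] / 1e3
  d <- dim(img)
  grid <- voxel_grid(origin[1] + (seq_len(d[1]) - 1) * sp[1],
                     origin[2] + (seq_len(d[2]) - 1) * sp[2],
                     origin[3] + (seq_len(d[3]) - 1) * sp[3])
  new_volume(array(as.numeric(img), d), grid)
}

#' Write a slow-time trace to CSV
#'
#' @param trace An `rca_pulse_trace`, or a data frame with `time`/`value`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- if (inherits(trace, "rca_pulse_trace")) {
    data.frame(time = trace$time, value = trace$values)
  } else as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ECG R-peak times from CSV
#'
#' Expects a column named `r_peak_time` (seconds) or a single column.
#'
#' @param path CSV path.
#' @return Numeric vector of R-peak times.
#' @export
read_rpeaks_csv <- function(path) {
  df <- utils::read.csv(path)
  col <- if ("r_peak_time" %in% names(df)) df$r_peak_time else df[[1]]
  sort(as.numeric(col))
}

#' Serialize a rigid transform to JSON
#'
#' @param transform An `rca_rigid`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(rotation_deg = transform$rotation_deg,
         translation_mm = transform$translation_m * 1e3,
         center_mm = transform$center * 1e3,
         convention = transform$convention),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(j$rotation_deg, j$translation_mm / 1e3, j$center_mm / 1e3)
}

#' Save / load channel data and IQ series
#'
#' Round-trips the containers through R serialization (no HDF5 library is
#' assumed); volumes intended for external tools go through
#' [write_volume_nifti()].
#'
#' @param x An `rca_channel_data` or `rca_iq_series`.
#' @param path Output `.rds` path.
#' @return The path (save) or the restored object (load).
#' @export
save_container <- function(x, path) {
  stopifnot(inherits(x, "rca_channel_data") || inherits(x, "rca_iq_series"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) readRDS(path)

#' Read / write a run configuration
#'
#' YAML round trip of the nested configuration list used by
#' [run_pipeline()].
#'
#' @param config Named list.
#' @param path YAML path.
#' @return The path / the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
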