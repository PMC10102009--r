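# Containers and on-disk interchange: volumetric stacks and TCSPC decay
# cubes as multi-page TIFF with a JSON sidecar, metric tables as CSV.

CHANNELS <- c("NADH", "FAD", "XLINK", "SHG", "OTHER")

#' Volumetric single-channel image
#'
#' A 3D intensity array in `(z, y, x)` order with physical voxel size and a
#' channel tag. After surface alignment, depth increases with `y`.
#'
#' @param intensities non-negative numeric array `(z, y, x)`; a matrix is
#'   promoted to `z = 1`.
#' @param voxel_size numeric length-3 voxel size in micrometers `(z, y, x)`.
#' @param channel one of `"NADH"`, `"FAD"`, `"XLINK"`, `"SHG"`, `"OTHER"`.
#' @param power incident laser power (arbitrary units) or `NA` if unrecorded.
#' @return object of class `volumetric_image`.
#' @export
volumetric_image <- function(intensities, voxel_size, channel = "OTHER",
                             power = NA_real_) {
  if (is.matrix(intensities)) intensities <- array(intensities, c(1L, dim(intensities)))
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  channel <- match.arg(channel, CHANNELS)
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 channel = channel, power = as.numeric(power),
                 power_normalized = FALSE),
            class = "volumetric_image")
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volumetric_image %s %dx%dx%d (z,y,x), voxel %.3gx%.3gx%.3g um%s>\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              if (isTRUE(x$power_normalized)) ", power-normalized" else ""))
  invisible(x)
}

#' TCSPC decay cube
#'
#' Per-pixel time-binned photon counts, `(time_bin, y, x)`.
#'
#' @param counts non-negative array `(t, y, x)`. Counts must be integers when
#'   `poisson = TRUE` (measured or Poisson-sampled data); noise-free expected
#'   decays may be non-integer.
#' @param bin_width time bin width, ns.
#' @param rep_period laser repetition period, ns (default 12.5).
#' @param channel channel tag.
#' @param poisson whether counts are photon counts (integer) as opposed to
#'   noise-free expectations.
#' @return object of class `decay_cube`.
#' @export
decay_cube <- function(counts, bin_width, rep_period = 12.5,
                       channel = "OTHER", poisson = TRUE) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (poisson && any(counts != round(counts)))
    stop("photon counts must be integers")
  stopifnot(bin_width > 0, rep_period > 0)
  if (dim(counts)[1] * bin_width > rep_period + 1e-9)
    stop("n_bins * bin_width exceeds the repetition period")
  channel <- match.arg(channel, CHANNELS)
  flag_empty <- all(counts == 0)
  structure(list(counts = counts, bin_width = bin_width,
                 rep_period = rep_period, channel = channel,
                 poisson = poisson, empty = flag_empty),
            class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_cube %s %d bins x %dx%d px, bin %.4g ns, period %.4g ns%s>\n",
              x$channel, d[1], d[2], d[3], x$bin_width, x$rep_period,
              if (x$empty) ", EMPTY" else ""))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a volumetric stack as multi-page TIFF + JSON sidecar
#'
#' The sidecar records voxel size, channel, power and normalization state;
#' round trips are exact (32-bit float storage of 32-bit-representable data).
#'
#' @param img a [volumetric_image()].
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `path` invisibly (write); a `volumetric_image` (read).
#' @export
write_stack <- function(img, path) {
  stopifnot(inherits(img, "volumetric_image"))
  write_tiff(img$intensities, path)
  meta <- list(kind = "stack", voxel_size_um = img$voxel_size,
               channel = img$channel, power = img$power,
               power_normalized = isTRUE(img$power_normalized))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing metadata: sidecar ", sp, " not found")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um))
    stop("missing metadata: voxel size absent from sidecar ", sp)
  arr <- read_tiff(path)
  img <- volumetric_image(arr, meta$voxel_size_um,
                          channel = if (is.null(meta$channel)) "OTHER" else meta$channel,
                          power = if (is.null(meta$power)) NA_real_ else meta$power)
  img$power_normalized <- isTRUE(meta$power_normalized)
  img
}

#' Write / read a decay cube as multi-page TIFF + JSON sidecar
#'
#' One TIFF page per time bin; the sidecar holds `bin_width_ns`,
#' `rep_period_ns` and the page count, which must match the TIFF.
#'
#' @param cube a [decay_cube()].
#' @param path TIFF path.
#' @return `path` invisibly (write); a `decay_cube` (read).
#' @export
write_decay_cube <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  write_tiff(cube$counts, path)
  meta <- list(kind = "decay_cube", bin_width_ns = cube$bin_width,
               rep_period_ns = cube$rep_period, channel = cube$channel,
               n_bins = dim(cube$counts)[1], poisson = cube$poisson)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata: sidecar ", sp, " not found")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  arr <- read_tiff(path)
  if (!is.null(meta$n_bins) && dim(arr)[1] != meta$n_bins)
    stop("bin count mismatch: TIFF has ", dim(arr)[1], " pages, sidecar says ",
         meta$n_bins)
  if (any(arr < 0)) stop("negative counts in decay cube")
  cube <- decay_cube(arr, meta$bin_width_ns, meta$rep_period_ns,
                     channel = if (is.null(meta$channel)) "OTHER" else meta$channel,
                     poisson = !isFALSE(meta$poisson))
  if (cube$empty) warning("decay cube is empty (all-zero counts)")
  cube
}

#' Normalize a stack by the square of the incident laser power
#'
#' Divides intensities by `power^2` and marks the image normalized; applying
#' it twice is an error.
#'
#' @param img a [volumetric_image()] with `power` recorded.
#' @return the normalized `volumetric_image`.
#' @export
normalize_power <- function(img) {
  stopifnot(inherits(img, "volumetric_image"))
  if (isTRUE(img$power_normalized))
    stop("image is already power-normalized")
  if (is.na(img$power)) stop("incident laser power not recorded")
  if (img$power <= 0) stop("incident laser power must be > 0")
  img$intensities <- img$intensities / img$power^2
  img$power_normalized <- TRUE
  img
}

METRIC_COLS <- c("variance", "xlink_density", "xlink_llif",
                 "redox", "nadh_llif", "beta")
KEY_COLS <- c("specimen", "group", "time_point", "zone", "field_id")

#' Assemble a per-field metric table
#'
#' Rows are imaging fields keyed by `(specimen, group, time_point, zone,
#' field_id)`; metric columns are the six optical metrics. Bounded metrics
#' (`variance`, `redox`, the two LLIFs) must lie in `[0, 1]`.
#'
#' @param df data.frame containing the key and metric columns.
#' @return validated data.frame of class `metric_table`.
#' @export
metric_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c(KEY_COLS, METRIC_COLS), names(df))
  if (length(missing_cols))
    stop("metric table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, c(KEY_COLS, METRIC_COLS)]
  for (m in METRIC_COLS) {
    bad <- !is.finite(df[[m]])
    if (any(bad))
      stop("non-finite values in metric '", m, "' at rows ",
           paste(which(bad), collapse = ", "))
  }
  for (m in c("variance", "redox", "xlink_llif", "nadh_llif")) {
    if (any(df[[m]] < 0 | df[[m]] > 1))
      stop("metric '", m, "' outside [0, 1]")
  }
  key <- interaction(df$field_id, df$zone, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (field_id, zone) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  class(df) <- c("metric_table", "data.frame")
  df
}

#' Write / read a metric table as CSV
#'
#' Fixed column order, lossless round trip.
#'
#' @param table a [metric_table()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `metric_table` (read).
#' @export
write_metrics <- function(table, path) {
  table <- metric_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  metric_table(df)
}

#' Load an analysis configuration file
#'
#' JSON natively; YAML when the optional yaml package is installed. Returned
#' as a named list merged over the package defaults (angular tolerance,
#' endplate factor, nucleus/lipofuscin percentiles, window sizes, phasor
#' harmonic and repetition period, clone-stamp tile size and repeats).
#'
#' @param path config file (`.json`, `.yaml`/`.yml`) or `NULL` for defaults.
#' @return named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    angle_tol_deg = 25, endplate_factor = 0.2,
    nucleus_percentile = 20, lipofuscin_percentile = 98,
    orientation_window_um = c(5, 5.3, 5.3),   # (z, y, x)
    variance_window_um = c(5, 5.3, 5.3),
    harmonic = 1L, rep_period_ns = 12.5, min_photons = 10,
    tile_px = 16L, clone_stamp_repeats = 20L,
    coverage_quantile = 0.75, delta_style = "fractional"
  )
  if (is.null(path)) return(defaults)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package not installed; use JSON config")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(defaults, cfg)
}
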