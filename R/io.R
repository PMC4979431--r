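# CSV writers emit '#'-prefixed header comments (tool version, config hash,
# seed) and %.17g-formatted numerics so that write -> read round-trips
# reproduce doubles exactly.

cells_columns <- c("x_px", "y_px", "x_mm", "y_mm", "area_um2",
                   "mean_intensity", "circularity", "equivalent_diameter_um")
sectors_columns <- c("ring", "quadrant", "cell_count", "area_mm2",
                     "density_per_mm2", "mean_nnd_um", "ri")
series_columns <- c("ring", "quadrant", "day", "density")

write_table_commented <- function(df, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(list(tool = paste0("rgcmosaic ",
                               as.character(utils::packageVersion("rgcmosaic")))),
            meta)
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_checked <- function(path, required, what) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file %s lacks required column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and write pipeline tables
#'
#' Lossless CSV round-trips for the three pipeline tables: detected cells,
#' per-sector statistics, and longitudinal density series. Comma-separated,
#' `.` decimal, UTF-8, header row; `#`-prefixed comment lines carry run
#' metadata and are ignored on read. Doubles are written with 17 significant
#' digits so values survive a write/read cycle bit-exactly.
#'
#' @param cells,sectors,series Data frames with the documented columns.
#' @param path File path.
#' @param meta Named list of metadata written as `# key: value` comments.
#' @return Readers return the data frame; writers return the path,
#'   invisibly. Schema violations (missing columns) are errors naming the
#'   column.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_cells <- function(cells, path, meta = list()) {
  write_table_commented(cells, path, meta)
}

#' @rdname table_io
#' @export
read_cells <- function(path) read_table_checked(path, cells_columns, "cells")

#' @rdname table_io
#' @export
write_sectors <- function(sectors, path, meta = list()) {
  write_table_commented(sectors, path, meta)
}

#' @rdname table_io
#' @export
read_sectors <- function(path) {
  read_table_checked(path, sectors_columns, "sectors")
}

#' @rdname table_io
#' @export
write_series <- function(series, path, meta = list()) {
  write_table_commented(series, path, meta)
}

#' @rdname table_io
#' @export
read_series <- function(path) read_table_checked(path, series_columns,
                                                 "series")

#' Read and write 8-bit single-channel TIFF images
#'
#' Images are handled as integer matrices (rows = y, cols = x) with grey
#' levels 0-255.
#'
#' @param path File path.
#' @param image Integer matrix of grey levels.
#' @return `read_image_tiff` returns the integer matrix; `write_image_tiff`
#'   the path, invisibly.
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8)
  invisible(path)
}

# Polynomial rolling hash (mod 2^31 - 1) of the deparsed config, for
# provenance comments; not cryptographic, just a fingerprint.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pipeline_config_keys <- c(
  "image", "cells", "mask", "series", "out_dir",
  "pixel_size_um", "onh_x", "onh_y", "eye", "superior_up",
  "intensity_threshold", "min_diameter_um", "max_diameter_um",
  "min_circularity", "highpass_scale_um", "mask_threshold_high",
  "watershed_tolerance",
  "ring_width_mm", "n_rings",
  "fit_mode", "t_half_fast_days", "t_half_slow_days",
  "synthetic", "field_radius_mm", "target_density_per_mm2",
  "exclusion_radius_um", "density_gradient", "soma_diameter_um",
  "peak_intensity", "background_sd",
  "seed", "log_level")

#' Read a flat pipeline configuration file
#'
#' A flat key-value YAML file; unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to the YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Run the whole analysis pipeline
#'
#' Executes detect, segment and mosaic statistics (and, when a longitudinal
#' series is supplied, the kinetics fits) end to end, writing `cells.csv`,
#' `sectors.csv`, `summary.yaml` (and `fits.csv`) into `out_dir`. Every CSV
#' carries `#` header comments with the tool version, a configuration hash,
#' and the seed, and a rerun with an identical configuration is
#' bit-identical for the deterministic stages. The input is either a TIFF
#' image (`image`, with `pixel_size_um`, `onh_x`, `onh_y` in pixels) or a
#' synthetic retina (`synthetic: true` plus generator keys). A stage failure
#' aborts with the stage named and removes partial outputs.
#'
#' @param config Named list (see [read_config()]) or path to a YAML config.
#' @return Invisibly, a list with the cells, sector table, summary and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out_dir <- config$out_dir %||% stop("out_dir is required", call. = FALSE)
  synthetic <- isTRUE(config$synthetic)
  if (!synthetic) {
    if (is.null(config$image)) {
      stop("configuration error: image path required unless synthetic: true",
           call. = FALSE)
    }
    if (is.null(config$onh_x) || is.null(config$onh_y)) {
      stop("configuration error: optic-nerve-head coordinates (onh_x, onh_y) required",
           call. = FALSE)
    }
    if (is.null(config$pixel_size_um)) {
      stop("configuration error: pixel_size_um calibration required",
           call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  result <- tryCatch({
    params <- detection_params(
      intensity_threshold = config$intensity_threshold %||% 130,
      min_diameter_um = config$min_diameter_um %||% 7,
      max_diameter_um = config$max_diameter_um %||% 21,
      min_circularity = config$min_circularity %||% 0.7,
      highpass_scale_um = config$highpass_scale_um %||% 63,
      mask_threshold_high = config$mask_threshold_high %||% 5,
      watershed_tolerance = config$watershed_tolerance %||% 1)
    # fingerprint of the analysis parameters, not the output destination
    hash <- config_hash(config[setdiff(names(config), "out_dir")])
    meta <- list(config_hash = hash, seed = config$seed %||% "none")

    stage <- "input"
    if (synthetic) {
      spec <- mosaic_spec(
        field_radius_mm = config$field_radius_mm %||% 1,
        target_density_per_mm2 = config$target_density_per_mm2 %||% 1695,
        exclusion_radius_um = config$exclusion_radius_um %||% 12,
        density_gradient = config$density_gradient %||% 0,
        seed = config$seed)
      ret <- simulate_retina(
        spec,
        pixel_size_um = config$pixel_size_um %||% 2,
        soma_diameter_um = config$soma_diameter_um %||% 12,
        peak_intensity = config$peak_intensity %||% 200,
        background_sd = config$background_sd %||% 0,
        seed = if (is.null(config$seed)) NULL else config$seed + 1L)
      image <- ret$image
      geometry <- ret$geometry
    } else {
      image <- read_image_tiff(config$image)
      stage <- "mask"
      mask <- make_retina_mask(image, params)
      geometry <- retina_geometry(mask, config$pixel_size_um,
                                  c(config$onh_x, config$onh_y))
    }

    stage <- "detect"
    cells <- detect_cells(image, geometry, params)
    written <- c(written, write_cells(cells, file.path(out_dir, "cells.csv"),
                                      meta))

    stage <- "segment"
    orientation <- if (isTRUE(config$superior_up %||% TRUE)) 270 else 90
    grid <- sector_grid(onh_xy_mm = geometry$onh_xy_mm,
                        ring_width_mm = config$ring_width_mm %||% 0.3,
                        n_rings = config$n_rings %||% 15,
                        orientation_deg = orientation,
                        eye = config$eye %||% "left")

    stage <- "stats"
    nnd <- if (nrow(cells) >= 2) nearest_neighbour_distances(cells) else NULL
    sectors <- sector_table(cells, geometry, grid, nnd)
    written <- c(written, write_sectors(sectors,
                                        file.path(out_dir, "sectors.csv"),
                                        meta))
    summary <- count_summary(cells, geometry)
    summary$regularity_index <- if (!is.null(nnd) && length(nnd) >= 3) {
      regularity_index(nnd)
    } else NA
    summary$mean_nnd_um <- if (!is.null(nnd)) mean(nnd) else NA
    summary$config_hash <- hash
    spath <- file.path(out_dir, "summary.yaml")
    yaml::write_yaml(summary, spath)
    written <- c(written, spath)

    fits <- NULL
    if (!is.null(config$series)) {
      stage <- "fit"
      series <- read_series(config$series)
      fits <- sector_kinetics_map(
        series,
        t_half_fast_days = config$t_half_fast_days %||% 1.7,
        t_half_slow_days = config$t_half_slow_days %||% 16.3,
        grid = grid)
      fp <- file.path(out_dir, "fits.csv")
      write_table_commented(fits$table, fp, meta)
      written <- c(written, fp)
    }
    list(cells = cells, sectors = sectors, summary = summary,
         fits = fits, paths = written)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
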