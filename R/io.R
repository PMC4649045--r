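# File formats: every artifact is plain text (CSV + JSON sidecars) except
# section label maps, which are PNG with the 16-bit ray id split across
# the red (high byte) and green (low byte) 8-bit channels.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

assert_columns <- function(df, schema, path) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    rlang::abort(sprintf(
      "%s: missing column(s): %s", path, paste(missing, collapse = ", ")
    ))
  }
  for (col in names(schema)) {
    ok <- switch(schema[[col]],
      numeric = is.numeric(df[[col]]),
      integer = is.numeric(df[[col]]) && all(df[[col]] == round(df[[col]]) | is.na(df[[col]])),
      character = is.character(df[[col]]),
      logical = is.logical(df[[col]])
    )
    if (!ok) {
      bad <- which(!is.na(df[[col]]))[1]
      rlang::abort(sprintf(
        "%s: column '%s' is not %s (see row %s)", path, col, schema[[col]],
        if (is.na(bad)) "?" else bad
      ))
    }
  }
  invisible(df)
}

#' Write and read a wood model
#'
#' The model is stored as a ray table (`rays.csv`, one row per ray with
#' coordinates rounded to 1e-4 mm) plus a JSON sidecar (`model.json`)
#' echoing the configuration, seed, ring borders, latewood onsets and year
#' factors.  The round trip is lossless to the declared precision.
#'
#' @param model A [generate_wood()] model.
#' @param dir Directory (created if needed).
#' @return `write_wood_model()` returns the paths invisibly;
#'   `read_wood_model()` returns a `wood_model`.
#' @export
write_wood_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rays <- dplyr::mutate(model$rays, dplyr::across(
    c("t_center", "z_center", "r_init", "r_term"), ~ round(.x, 4)
  ))
  rays <- dplyr::mutate(rays, dplyr::across(c("height_um", "width_um"), ~ round(.x, 2)))
  csv <- file.path(dir, "rays.csv")
  readr::write_csv(rays, csv)
  meta <- file.path(dir, "model.json")
  write_json_file(
    list(
      format = "raypar_wood_model_v1",
      config = unclass(model$config),
      ring_borders = model$ring_borders,
      latewood_onsets = model$latewood_onsets,
      year_factors = model$year_factors
    ),
    meta
  )
  invisible(c(rays = csv, meta = meta))
}

model_ray_schema <- c(
  id = "integer", t_center = "numeric", z_center = "numeric",
  r_init = "numeric", r_term = "numeric", height_um = "numeric",
  width_um = "numeric", lens_exponent = "numeric"
)

#' @rdname write_wood_model
#' @export
read_wood_model <- function(dir) {
  csv <- file.path(dir, "rays.csv")
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(csv) || !file.exists(meta_path)) {
    rlang::abort(sprintf("%s does not contain rays.csv + model.json", dir))
  }
  rays <- readr::read_csv(csv, show_col_types = FALSE)
  assert_columns(rays, model_ray_schema, csv)
  rays$id <- as.integer(rays$id)
  if (!"origin" %in% names(rays)) rays$origin <- "base"
  if (!"ring_init" %in% names(rays)) rays$ring_init <- NA_integer_
  if (!"zone_init" %in% names(rays)) rays$zone_init <- NA_character_
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- meta$config
  cfg$radial_extent <- if (is.null(cfg$radial_extent)) NULL else cfg$radial_extent
  cfg <- validate_wood_config(cfg)
  structure(
    list(
      config = cfg,
      ring_borders = as.numeric(meta$ring_borders),
      latewood_onsets = as.numeric(meta$latewood_onsets),
      year_factors = as.numeric(meta$year_factors),
      rays = tibble::as_tibble(rays)
    ),
    class = "wood_model"
  )
}

#' Write and read a section label map
#'
#' Label maps travel as PNG plus a JSON metadata sidecar.  Ray ids (16
#' bit, 0 = background) are encoded losslessly in the red (high byte) and
#' green (low byte) channels of an 8-bit RGB PNG; the sidecar records the
#' plane, section spec, pixel size, image origin, ring borders and
#' latewood onsets.  Externally produced label maps following the same
#' convention can be read back and fed to [extract_outlines()] and
#' friends.
#'
#' @param image A [cut_section()] image.
#' @param path_png,path_json Output paths (the JSON defaults to the PNG
#'   path with extension `.json`).
#' @return `write_section_image()` returns the paths invisibly;
#'   `read_section_image()` returns a `section_image`.
#' @export
write_section_image <- function(image, path_png, path_json = NULL) {
  stopifnot(inherits(image, "section_image"))
  if (is.null(path_json)) path_json <- sub("\\.png$", ".json", path_png)
  dir.create(dirname(path_png), showWarnings = FALSE, recursive = TRUE)
  if (max(image$labels) > 65535L) rlang::abort("more than 65535 ray ids; PNG encoding overflows")
  arr <- array(0, dim = c(image$ny, image$nx, 3L))
  arr[, , 1] <- (image$labels %/% 256L) / 255
  arr[, , 2] <- (image$labels %% 256L) / 255
  png::writePNG(arr, path_png)
  spec <- image$spec
  write_json_file(
    list(
      format = "raypar_section_image_v1",
      plane = image$plane,
      pixel_size_um = image$pixel_size_um,
      x0 = image$x0, y0 = image$y0, nx = image$nx, ny = image$ny,
      thickness_um = spec$thickness_um,
      offset = spec$offset,
      misalignment_deg = spec$misalignment_deg,
      ring_borders = image$ring_borders,
      latewood_onsets = image$latewood_onsets,
      overlap_px = image$overlap_px,
      id_encoding = "rgb8: id = 256 * R + G"
    ),
    path_json
  )
  invisible(c(png = path_png, json = path_json))
}

#' @rdname write_section_image
#' @export
read_section_image <- function(path_png, path_json = NULL) {
  if (is.null(path_json)) path_json <- sub("\\.png$", ".json", path_png)
  if (!file.exists(path_png) || !file.exists(path_json)) {
    rlang::abort(sprintf("missing %s or %s", path_png, path_json))
  }
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  need <- c("plane", "pixel_size_um", "x0", "y0", "nx", "ny")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    rlang::abort(sprintf(
      "%s: missing metadata field(s): %s", path_json, paste(missing, collapse = ", ")
    ))
  }
  arr <- png::readPNG(path_png)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2) {
    rlang::abort(sprintf("%s: expected an RGB label map", path_png))
  }
  labels <- matrix(
    as.integer(round(arr[, , 1] * 255)) * 256L + as.integer(round(arr[, , 2] * 255)),
    nrow = dim(arr)[1]
  )
  spec <- section_spec(
    plane = meta$plane,
    offset = if (is.null(meta$offset)) NULL else meta$offset,
    thickness_um = if (is.null(meta$thickness_um)) 15 else meta$thickness_um,
    misalignment_deg = if (is.null(meta$misalignment_deg)) 0 else meta$misalignment_deg,
    resolution_um = meta$pixel_size_um
  )
  structure(
    list(
      labels = labels,
      pixel_size_um = meta$pixel_size_um,
      plane = meta$plane,
      spec = spec,
      x0 = meta$x0, y0 = meta$y0,
      nx = as.integer(meta$nx), ny = as.integer(meta$ny),
      ring_borders = if (is.null(meta$ring_borders)) NULL else as.numeric(meta$ring_borders),
      latewood_onsets = if (is.null(meta$latewood_onsets)) NULL else as.numeric(meta$latewood_onsets),
      overlap_px = if (is.null(meta$overlap_px)) NA_integer_ else as.integer(meta$overlap_px),
      model_config = NULL
    ),
    class = "section_image"
  )
}

outline_schema <- c(
  section_id = "character", plane = "character", ray_id = "integer",
  area_um2 = "numeric", centroid_x_mm = "numeric", centroid_y_mm = "numeric",
  initiating = "logical", disappearing = "logical", edge_flag = "logical"
)

#' Write and read outline / metric / accuracy tables
#'
#' Thin CSV round trips with schema validation: missing or mistyped
#' columns raise an error naming the file, the column and the offending
#' row.  Outline tables follow the documented per-outline schema
#' (`section_id`, `plane`, `ray_id`, `ring_id`, `zone`, `area_um2`,
#' `height_um`, `length_um`, `width_um`, `centroid_x_mm`,
#' `centroid_y_mm`, `initiating`, `disappearing`, `edge_flag`), so tables
#' exported from other tools in the same layout import cleanly.
#'
#' @param outlines,metrics,curve Tibbles as produced by
#'   [extract_outlines()], [ring_metrics()], [bootstrap_accuracy()].
#' @param path CSV path.
#' @return Readers return validated tibbles.
#' @export
write_outlines <- function(outlines, path) {
  readr::write_csv(dplyr::mutate(outlines, dplyr::across(
    c("centroid_x_mm", "centroid_y_mm"), ~ round(.x, 4)
  )), path)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_outlines <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, outline_schema, path)
  df$ray_id <- as.integer(df$ray_id)
  if (!"ring_id" %in% names(df)) df$ring_id <- NA_integer_
  if (!"zone" %in% names(df)) df$zone <- NA_character_
  tibble::as_tibble(df)
}

ring_metric_schema <- c(
  ring = "integer", year = "integer", ring_width_mm = "numeric",
  perpar = "numeric", newray_count = "integer", disappearing_count = "integer"
)

#' @rdname write_outlines
#' @export
write_ring_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_ring_metrics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, ring_metric_schema, path)
  tibble::as_tibble(df)
}

#' @rdname write_outlines
#' @param n_samples Sample counts at which to tabulate [ci95()] columns.
#' @export
write_accuracy_curve <- function(curve, path, n_samples = c(5, 10, 15, 20)) {
  df <- tibble::as_tibble(curve)
  for (n in n_samples) df[[sprintf("ci95_n%d", n)]] <- ci95(df$cv, n)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_accuracy_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c(size = "integer", mean = "numeric", cv = "numeric"), path)
  structure(tibble::as_tibble(df), class = c("accuracy_curve", class(tibble::tibble())))
}

#' @rdname write_outlines
#' @param pool A [sample_windows()] pool.
#' @export
write_window_pool <- function(pool, path) {
  readr::write_csv(tibble::as_tibble(pool), path)
  invisible(path)
}

#' @rdname write_outlines
#' @export
read_window_pool <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(df, c(perpar = "numeric"), path)
  structure(tibble::as_tibble(df), class = c("window_pool", class(tibble::tibble())))
}
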