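#' Extract per-ray outlines from a section image
#'
#' Groups the label map by ray id and measures each outline: area,
#' axis-aligned extents, the plane-appropriate dimensions, centroid, and --
#' on cross-sections with ring borders -- initiation/disappearance flags
#' and ring/zone assignment.
#'
#' Dimension rules follow standard vectorized-micrograph practice: on
#' tangential sections the measured dimension is ray height (axial extent)
#' and ray width is derived as area divided by height; on cross and radial
#' sections the radial extent is the ray length (cross-sectional width is
#' derived as area / length).  Outlines touching the image boundary are
#' flagged (`edge_flag`) so that downstream dimension statistics can
#' exclude them, while they still count toward areal fractions.
#'
#' A ray is *initiating* in a ring when its pith-side (inner radial) end
#' lies strictly inside the ring -- more than one pixel from the ring's
#' inner border, so rasterization jitter cannot mint false initiations --
#' and it is assigned to the early/latewood zone containing that end.
#' Symmetrically, a ray whose bark-side end stops more than one pixel short
#' of the ring's outer border is *disappearing*.
#'
#' @param image A [cut_section()] image (or one read back with
#'   [read_section_image()]).
#' @param section_id Identifier copied into the output (defaults to "").
#' @return A tibble with one row per ray outline: `section_id`, `plane`,
#'   `ray_id`, `ring_id`, `zone`, `area_um2`, `height_um`, `length_um`,
#'   `width_um`, `centroid_x_mm`, `centroid_y_mm`, `initiating`,
#'   `disappearing`, `edge_flag`.  Empty image -> zero rows.
#' @export
extract_outlines <- function(image, section_id = "") {
  stopifnot(inherits(image, "section_image"))
  px <- image$pixel_size_um
  px_mm <- um_to_mm(px)
  idx <- nonzero_indices(image$labels)
  empty <- tibble::tibble(
    section_id = character(0), plane = character(0), ray_id = integer(0),
    ring_id = integer(0), zone = character(0), area_um2 = numeric(0),
    height_um = numeric(0), length_um = numeric(0), width_um = numeric(0),
    centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
    initiating = logical(0), disappearing = logical(0), edge_flag = logical(0)
  )
  if (!length(idx)) return(empty)
  ny <- image$ny
  ids <- image$labels[idx]
  i <- (idx - 1L) %% ny + 1L
  j <- (idx - 1L) %/% ny + 1L

  # group pixels by ray id via one radix sort; min/max/sum per contiguous
  # slice (fast path for the multi-megapixel label maps)
  ord <- order(ids)
  ids_s <- ids[ord]
  n_id <- length(ids_s)
  ends <- which(c(ids_s[-1L] != ids_s[-n_id], TRUE))
  starts <- c(1L, ends[-length(ends)] + 1L)
  n_by <- ends - starts + 1L
  uid <- ids_s[starts]
  slice_stats <- function(v) {
    vs <- v[ord]
    list(
      min = vapply(seq_along(starts), function(g) min(vs[starts[g]:ends[g]]), numeric(1)),
      max = vapply(seq_along(starts), function(g) max(vs[starts[g]:ends[g]]), numeric(1)),
      sum = vapply(seq_along(starts), function(g) sum(vs[starts[g]:ends[g]]), numeric(1))
    )
  }
  mi <- slice_stats(i)
  mj <- slice_stats(j)
  si <- tibble::tibble(ray_id = uid, min = mi$min, max = mi$max, sum = mi$sum, n = n_by)
  sj <- tibble::tibble(ray_id = uid, min = mj$min, max = mj$max, sum = mj$sum, n = n_by)

  n_px <- si$n
  area_um2 <- n_px * px^2
  y_extent_um <- (si$max - si$min + 1L) * px
  x_extent_um <- (sj$max - sj$min + 1L) * px
  centroid_x <- image$x0 + (sj$sum / n_px - 0.5) * px_mm
  centroid_y <- image$y0 + (si$sum / n_px - 0.5) * px_mm
  edge <- si$min == 1L | si$max == ny | sj$min == 1L | sj$max == image$nx

  out <- tibble::tibble(
    section_id = section_id,
    plane = image$plane,
    ray_id = as.integer(si$ray_id),
    ring_id = NA_integer_,
    zone = NA_character_,
    area_um2 = area_um2,
    height_um = NA_real_,
    length_um = NA_real_,
    width_um = NA_real_,
    centroid_x_mm = centroid_x,
    centroid_y_mm = centroid_y,
    initiating = FALSE,
    disappearing = FALSE,
    edge_flag = edge
  )

  if (image$plane == "tangential") {
    out$height_um <- y_extent_um
    out$width_um <- out$area_um2 / out$height_um
  } else if (image$plane == "cross") {
    out$length_um <- y_extent_um
    out$width_um <- out$area_um2 / out$length_um
  } else {
    out$length_um <- x_extent_um
    out$height_um <- y_extent_um
  }

  radial_axis <- switch(image$plane, cross = "y", radial = "x", NULL)
  if (!is.null(radial_axis) && !is.null(image$ring_borders)) {
    ext <- if (radial_axis == "y") si else sj
    origin <- if (radial_axis == "y") image$y0 else image$x0
    inner_mm <- origin + (ext$min - 0.5) * px_mm
    outer_mm <- origin + (ext$max - 0.5) * px_mm
    borders <- image$ring_borders
    onsets <- image$latewood_onsets
    ring_in <- ring_of(inner_mm, borders)
    out$ring_id <- as.integer(ring_in)
    tol <- px_mm
    out$initiating <- inner_mm - borders[ring_in] > tol &
      # inner end must also be clear of the image boundary
      ext$min > 1L
    ring_out <- ring_of(outer_mm, borders)
    out$disappearing <- borders[ring_out + 1L] - outer_mm > tol &
      ext$max < (if (radial_axis == "y") ny else image$nx)
    if (!is.null(onsets)) {
      out$zone <- ifelse(inner_mm >= onsets[ring_in], "late", "early")
    }
  }
  # per-row ray-pixel counts ride along so ring_metrics() can reuse the
  # single pixel scan
  attr(out, "row_ray_counts") <- tabulate(i, nbins = ny)
  out
}

#' Percentage of ray surface (PERPAR)
#'
#' The areal fraction of ray tissue on a section image, in percent:
#' `100 * ray pixels / total pixels` within the chosen region.  On unbiased
#' (tangential) sections this estimates the relative ray volume.
#'
#' @param image A [cut_section()] image.
#' @param region Optional sub-rectangle `c(xmin, xmax, ymin, ymax)` in mm
#'   (image coordinates).
#' @param zone Optional `"early"` or `"late"`: restrict to the radial zone
#'   (cross-sections with ring borders only); may be combined with
#'   `region`.
#' @return PERPAR in percent.
#' @export
compute_perpar <- function(image, region = NULL, zone = NULL) {
  stopifnot(inherits(image, "section_image"))
  px_mm <- um_to_mm(image$pixel_size_um)
  rows <- seq_len(image$ny)
  cols <- seq_len(image$nx)
  if (!is.null(region)) {
    if (length(region) != 4) abort_field("region", "must be c(xmin, xmax, ymin, ymax) in mm")
    xc <- image$x0 + (cols - 0.5) * px_mm
    yc <- image$y0 + (rows - 0.5) * px_mm
    cols <- cols[xc >= region[1] & xc <= region[2]]
    rows <- rows[yc >= region[3] & yc <= region[4]]
  }
  if (!is.null(zone)) {
    if (image$plane != "cross" || is.null(image$ring_borders)) {
      rlang::abort("`zone` requires a cross-section image with ring borders")
    }
    yc <- image$y0 + (rows - 0.5) * px_mm
    late <- in_latewood(yc, image$ring_borders, image$latewood_onsets)
    rows <- rows[if (zone == "late") late else if (zone == "early") !late else
      rlang::abort('`zone` must be "early" or "late"')]
  }
  if (!length(rows) || !length(cols)) {
    rlang::abort("selected region contains no pixels")
  }
  n_sel <- length(rows) * length(cols)
  if (length(cols) == image$nx) {
    # full-width selections scan the label map once without copying it
    idx <- nonzero_indices(image$labels)
    keep <- logical(image$ny)
    keep[rows] <- TRUE
    return(100 * sum(keep[(idx - 1L) %% image$ny + 1L]) / n_sel)
  }
  100 * sum(image$labels[rows, cols, drop = FALSE] != 0L) / n_sel
}

#' Per-ring ray statistics from a cross-section
#'
#' Computes, for every annual ring of a cross-sectional image: the
#' percentage of ray surface overall and split by early/latewood zone; the
#' number of initiating rays (NEWRAY), both raw and standardized; the
#' number of disappearing rays; and mean ray dimensions from outlines not
#' touching the image boundary.
#'
#' Standardizations:
#' * `newray_per_mm` -- initiating rays in the ring per mm of measured
#'   tangential width.
#' * `newray_early_per_mm`, `newray_late_per_mm` -- initiating rays
#'   assigned to the zone of their pith-side end, divided by the zone's
#'   radial extent in mm.  Early- and latewood occupy unequal radial shares
#'   of a ring, so dividing each zone's count by its own radial extent puts
#'   the two zones' initiation activity on a common scale (an equal-area
#'   correction); dividing by the common tangential width would leave the
#'   unequal zone contributions uncorrected.
#'
#' @param image A cross-plane [cut_section()] image with ring borders.
#' @param outlines Optional precomputed [extract_outlines()] table for this
#'   image.
#' @return A tibble with one row per ring: `ring`, `year`, `ring_width_mm`,
#'   `perpar`, `perpar_early`, `perpar_late`, `newray_count`,
#'   `newray_per_mm`, `newray_early_per_mm`, `newray_late_per_mm`,
#'   `disappearing_count`, `mean_ray_area_um2`, `mean_ray_length_um`,
#'   `mean_ray_width_um`, `n_outlines`.
#' @export
ring_metrics <- function(image, outlines = NULL) {
  stopifnot(inherits(image, "section_image"))
  if (image$plane != "cross") {
    rlang::abort(sprintf("ring_metrics() needs a cross-section image, not %s", image$plane))
  }
  if (is.null(image$ring_borders) || length(image$ring_borders) < 2) {
    rlang::abort("image carries no ring borders")
  }
  if (is.null(outlines)) outlines <- extract_outlines(image)
  px_mm <- um_to_mm(image$pixel_size_um)
  borders <- image$ring_borders
  onsets <- image$latewood_onsets
  k <- length(borders) - 1L
  width_mm <- image$nx * px_mm

  yc <- image$y0 + (seq_len(image$ny) - 0.5) * px_mm
  ring_row <- ring_of(yc, borders)
  late_row <- yc >= onsets[ring_row]
  ray_per_row <- attr(outlines, "row_ray_counts")
  if (is.null(ray_per_row)) {
    idx <- nonzero_indices(image$labels)
    ray_per_row <- tabulate((idx - 1L) %% image$ny + 1L, nbins = image$ny)
  }

  per_ring <- function(kk) {
    rows_e <- which(ring_row == kk & !late_row)
    rows_l <- which(ring_row == kk & late_row)
    n_e <- length(rows_e) * image$nx
    n_l <- length(rows_l) * image$nx
    c(
      perpar = 100 * (sum(ray_per_row[rows_e]) + sum(ray_per_row[rows_l])) /
        max(n_e + n_l, 1L),
      perpar_early = if (n_e) 100 * sum(ray_per_row[rows_e]) / n_e else NA_real_,
      perpar_late = if (n_l) 100 * sum(ray_per_row[rows_l]) / n_l else NA_real_
    )
  }
  pp <- vapply(seq_len(k), per_ring, numeric(3))

  init <- outlines[outlines$initiating, , drop = FALSE]
  disap <- outlines[outlines$disappearing, , drop = FALSE]
  count_by_ring <- function(df) tabulate(df$ring_id, nbins = k)
  newray <- count_by_ring(init)
  newray_e <- count_by_ring(init[!is.na(init$zone) & init$zone == "early", , drop = FALSE])
  newray_l <- count_by_ring(init[!is.na(init$zone) & init$zone == "late", , drop = FALSE])
  disappearing <- count_by_ring(disap)

  rw <- diff(borders)
  rw_e <- onsets - borders[-length(borders)]
  rw_l <- borders[-1] - onsets

  dims <- outlines[!outlines$edge_flag, , drop = FALSE]
  dims$ring_id <- ring_of(dims$centroid_y_mm, borders)
  mean_by_ring <- function(v, ring) {
    out <- rep(NA_real_, k)
    if (length(v)) {
      m <- tapply(v, factor(ring, levels = seq_len(k)), mean)
      out <- as.vector(m)
    }
    out
  }

  tibble::tibble(
    ring = seq_len(k),
    year = seq_len(k),
    ring_width_mm = rw,
    perpar = pp["perpar", ],
    perpar_early = pp["perpar_early", ],
    perpar_late = pp["perpar_late", ],
    newray_count = newray,
    newray_per_mm = newray / width_mm,
    newray_early_per_mm = newray_e / rw_e,
    newray_late_per_mm = newray_l / rw_l,
    disappearing_count = disappearing,
    mean_ray_area_um2 = mean_by_ring(dims$area_um2, dims$ring_id),
    mean_ray_length_um = mean_by_ring(dims$length_um, dims$ring_id),
    mean_ray_width_um = mean_by_ring(dims$width_um, dims$ring_id),
    n_outlines = tabulate(ring_of(outlines$centroid_y_mm, borders), nbins = k)
  )
}

#' Assemble an annual time series from ring metrics
#'
#' @param metrics A [ring_metrics()] tibble (rows may arrive unordered).
#' @param metric Name of the metric column to extract.
#' @return A tibble (`year`, `value`), year-ascending, with the metric name
#'   in the `metric` attribute.
#' @export
assemble_time_series <- function(metrics, metric = "perpar") {
  valid <- setdiff(names(metrics), c("ring", "year"))
  if (!metric %in% valid) {
    rlang::abort(sprintf(
      "unknown metric '%s'; valid metrics: %s", metric, paste(valid, collapse = ", ")
    ))
  }
  if (nrow(metrics) < 2) rlang::abort("need at least 2 rings for a time series")
  out <- tibble::tibble(year = metrics$year, value = metrics[[metric]])
  out <- dplyr::arrange(out, .data$year)
  attr(out, "metric") <- metric
  out
}

#' Simulate an annual ray-fraction series from a configuration
#'
#' Draws the per-ring lognormal year factors and propagates them through
#' the expected measured cross-sectional ray fraction, giving the
#' model-level annual PERPAR series (no rasterization or window-sampling
#' noise).  Used to study inter-annual variability statistics such as the
#' coefficient of variation and mean sensitivity.
#'
#' @param config A [wood_config()] with `interannual_cv > 0`.
#' @param n_years Series length (default: `config$n_rings`).
#' @param seed Seed for the year factors (default: `config$rng_seed`).
#' @param thickness_um Section thickness assumed for the measurement.
#' @return A tibble (`year`, `value`) of annual PERPAR percentages.
#' @export
simulate_annual_perpar <- function(config, n_years = config$n_rings,
                                   seed = config$rng_seed, thickness_um = 15) {
  check_number(n_years, "n_years", min = 2, integer = TRUE)
  s <- sqrt(log(1 + config$interannual_cv^2))
  g <- with_seed(seed, stats::rlnorm(n_years, meanlog = -s^2 / 2, sdlog = s))
  values <- vapply(
    g,
    function(gk) expected_perpar(config, "cross", thickness_um, width_factor = gk),
    numeric(1)
  )
  out <- tibble::tibble(year = seq_len(n_years), value = values)
  attr(out, "metric") <- "perpar"
  out
}
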