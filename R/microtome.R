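#' Specify a virtual section
#'
#' Describes one cut of the virtual microtome: the anatomical plane, the
#' slab position along its normal, the finite section thickness, an
#' optional misalignment of the slab normal, the raster resolution and the
#' in-plane extent to rasterize.
#'
#' Plane conventions (model axes r radial, t tangential, z axial):
#' * `"cross"` -- image x = t, y = r, slab normal z.  Misalignment tilts
#'   the slab about the tangential axis, so its axial position drifts with
#'   radius: rays slide in and out of the slab along the radius, producing
#'   apparent ray endings and initiations (the ending-ray artifact).
#' * `"tangential"` -- image x = t, y = z, slab normal r; tilt about the
#'   axial axis.
#' * `"radial"` -- image x = r, y = z, slab normal t; tilt about the axial
#'   axis.
#'
#' @param plane `"cross"`, `"tangential"` or `"radial"`.
#' @param offset Slab center along the plane normal, mm.  Defaults to the
#'   middle of the sector when cutting (resolved against the model).
#' @param thickness_um Slab thickness in um, within `[0, 50]`; 10-15 um is
#'   the usual microtome range.
#' @param misalignment_deg Rotation of the slab normal in degrees,
#'   `|angle| < 15`.
#' @param resolution_um Raster resolution, um per pixel, within
#'   `[0.5, 10]`.  The 2 um default resolves a 25 um ray width with about
#'   12 pixels.
#' @param extent Optional in-plane rectangle
#'   `list(x = c(lo, hi), y = c(lo, hi))` in mm; default is the full
#'   sector face.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(plane = c("cross", "tangential", "radial"),
                         offset = NULL,
                         thickness_um = 15,
                         misalignment_deg = 0,
                         resolution_um = 2,
                         extent = NULL) {
  plane <- match.arg(plane)
  if (!is.null(offset)) check_number(offset, "offset")
  check_number(thickness_um, "thickness_um", min = 0, max = 50)
  check_number(misalignment_deg, "misalignment_deg", min = -15, max = 15,
    strict_min = TRUE, strict_max = TRUE
  )
  check_number(resolution_um, "resolution_um", min = 0.5, max = 10)
  if (!is.null(extent)) {
    if (!is.list(extent) || !all(c("x", "y") %in% names(extent)) ||
      length(extent$x) != 2 || length(extent$y) != 2 ||
      extent$x[1] >= extent$x[2] || extent$y[1] >= extent$y[2]) {
      abort_field("extent", "must be list(x = c(lo, hi), y = c(lo, hi)) with lo < hi")
    }
  }
  structure(
    list(
      plane = plane, offset = offset, thickness_um = thickness_um,
      misalignment_deg = misalignment_deg, resolution_um = resolution_um,
      extent = extent
    ),
    class = "section_spec"
  )
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf(
    "<section_spec> %s, offset %s mm, thickness %g um, tilt %g deg, %g um/px\n",
    x$plane, if (is.null(x$offset)) "(center)" else format(x$offset),
    x$thickness_um, x$misalignment_deg, x$resolution_um
  ))
  invisible(x)
}

# Resolve plane axes, default offset and extent against a model.
resolve_spec <- function(model, spec) {
  cfg <- model$config
  r_outer <- max(model$ring_borders)
  full <- switch(spec$plane,
    cross = list(x = c(0, cfg$tangential_extent), y = c(0, r_outer), normal = c(0, cfg$axial_extent)),
    tangential = list(x = c(0, cfg$tangential_extent), y = c(0, cfg$axial_extent), normal = c(0, r_outer)),
    radial = list(x = c(0, r_outer), y = c(0, cfg$axial_extent), normal = c(0, cfg$tangential_extent))
  )
  ext <- if (is.null(spec$extent)) full[c("x", "y")] else spec$extent
  offset <- if (is.null(spec$offset)) mean(full$normal) else spec$offset
  tau <- um_to_mm(spec$thickness_um)
  tilt <- tan(spec$misalignment_deg * pi / 180)
  # reject a slab that misses the sector entirely (accounting for tilt drift
  # across the rasterized extent)
  drift_axis <- if (spec$plane == "tangential") ext$x else if (spec$plane == "cross") ext$y else ext$x
  drift <- abs(tilt) * diff(drift_axis) / 2
  lo <- offset - tau / 2 - drift
  hi <- offset + tau / 2 + drift
  if (hi < full$normal[1] || lo > full$normal[2]) {
    rlang::abort(sprintf(
      "slab [%g, %g] mm lies outside the sector's %s extent [%g, %g] mm",
      lo, hi, spec$plane, full$normal[1], full$normal[2]
    ))
  }
  list(ext = ext, offset = offset, tau = tau, tilt = tilt)
}

#' Cut a virtual section and rasterize its label map
#'
#' Cuts the model with a finite-thickness slab and rasterizes, for every
#' ray, the union of its outline over the slab depth (the maximum
#' projection through the section thickness -- what an observer perceives
#' through a transparent section).  A pixel is labeled with a ray's id when
#' its center falls inside that ray's projected outline; where projections
#' overlap the lowest id wins and the pixel is counted in the image's
#' `overlap_px` tally.  Ring borders and latewood onsets are carried along
#' for cross and radial planes.
#'
#' @param model A [generate_wood()] model.
#' @param spec A [section_spec()].
#' @return An object of class `section_image`: integer label matrix
#'   (`labels`, 0 = background, row = image y), `pixel_size_um`, image
#'   origin `x0`/`y0` (mm), `plane`, the resolved `spec`, `ring_borders`,
#'   `latewood_onsets`, `overlap_px` and the generating `model_config`.
#' @examples
#' m <- generate_wood(wood_config(n_rings = 2, tangential_extent = 1, axial_extent = 1))
#' img <- cut_section(m, section_spec("tangential", resolution_um = 4))
#' compute_perpar(img)
#' @export
cut_section <- function(model, spec) {
  stopifnot(inherits(model, "wood_model"), inherits(spec, "section_spec"))
  rs <- resolve_spec(model, spec)
  res <- um_to_mm(spec$resolution_um)
  x0 <- rs$ext$x[1]
  y0 <- rs$ext$y[1]
  nx <- max(1L, as.integer(round(diff(rs$ext$x) / res)))
  ny <- max(1L, as.integer(round(diff(rs$ext$y) / res)))
  labels <- matrix(0L, nrow = ny, ncol = nx)
  assigned <- 0L

  rays <- model$rays
  segs <- radial_segments(model)
  p <- model$config$lens_shape_exponent
  slope <- model$config$ray_height_slope
  f_max <- max(segs$factor)

  # quick vectorized visibility pre-filter (exact tests happen during
  # painting; this only discards rays that cannot touch the slab)
  visible <- if (nrow(rays) == 0) {
    logical(0)
  } else {
    h_all <- um_to_mm(rays$height_um + slope * pmax(rays$r_term - rays$r_init, 0))
    drift <- abs(rs$tilt) * switch(spec$plane,
      cross = diff(rs$ext$y), tangential = diff(rs$ext$x), radial = diff(rs$ext$x)
    ) / 2
    switch(spec$plane,
      cross = abs(rays$z_center - rs$offset) <= h_all / 2 + rs$tau / 2 + drift,
      tangential = {
        r_slab <- rs$offset + (rays$t_center - mean(rs$ext$x)) * rs$tilt
        rays$r_init <= r_slab + rs$tau / 2 & rays$r_term >= r_slab - rs$tau / 2
      },
      radial = abs(rays$t_center - rs$offset) <=
        (um_to_mm(rays$width_um) * f_max + rs$tau) / 2 + drift
    )
  }
  # paint in decreasing id order so that overlaps resolve to the lowest id
  ord <- which(visible)[order(rays$id[visible], decreasing = TRUE)]
  # segment index range per ray (avoids scanning all ring segments)
  seg_first <- pmax(findInterval(rays$r_init, segs$r_start, rightmost.closed = TRUE), 1L)
  seg_last <- pmin(
    findInterval(rays$r_term, segs$r_start, rightmost.closed = TRUE),
    nrow(segs)
  )

  cols_for <- function(lo, hi) {
    jlo <- pmax(1L, as.integer(ceiling((lo - x0) / res + 0.5)))
    jhi <- pmin(nx, as.integer(floor((hi - x0) / res + 0.5)))
    list(lo = jlo, hi = jhi)
  }
  rows_for <- function(lo, hi) {
    ilo <- pmax(1L, as.integer(ceiling((lo - y0) / res + 0.5)))
    ihi <- pmin(ny, as.integer(floor((hi - y0) / res + 0.5)))
    list(lo = ilo, hi = ihi)
  }

  if (spec$plane == "cross") {
    r_mid <- mean(rs$ext$y)
    yc_all <- y0 + (seq_len(ny) - 0.5) * res
    for (i in ord) {
      w_mm <- um_to_mm(rays$width_um[i])
      tc <- rays$t_center[i]
      for (s in seg_first[i]:seg_last[i]) {
        a <- max(rays$r_init[i], segs$r_start[s], rs$ext$y[1])
        b <- min(rays$r_term[i], segs$r_end[s], rs$ext$y[2])
        if (b <= a) next
        rw <- rows_for(a, b)
        if (rw$hi < rw$lo) next
        h_mm <- um_to_mm(rays$height_um[i] + slope * max((a + b) / 2 - rays$r_init[i], 0))
        w_seg <- w_mm * segs$factor[s]
        if (rs$tilt == 0) {
          delta <- abs(rays$z_center[i] - rs$offset)
          if (delta > h_mm / 2 + rs$tau / 2) next
          ustar <- max(0, (delta - rs$tau / 2) / (h_mm / 2))
          omega <- w_seg * profile_factor(ustar, p)
          if (omega <= 0) next
          cl <- cols_for(tc - omega / 2, tc + omega / 2)
          if (cl$hi < cl$lo) next
          labels[rw$lo:rw$hi, cl$lo:cl$hi] <- rays$id[i]
          assigned <- assigned + (rw$hi - rw$lo + 1L) * (cl$hi - cl$lo + 1L)
        } else {
          rows <- rw$lo:rw$hi
          yc <- yc_all[rows]
          delta <- abs(rays$z_center[i] - (rs$offset + (yc - r_mid) * rs$tilt))
          ustar <- pmax(0, (delta - rs$tau / 2) / (h_mm / 2))
          omega <- w_seg * profile_factor(ustar, p)
          cl <- cols_for(tc - omega / 2, tc + omega / 2)
          keep <- omega > 0 & cl$hi >= cl$lo
          if (!any(keep)) next
          counts <- cl$hi[keep] - cl$lo[keep] + 1L
          lin <- rep.int(rows[keep], counts) +
            (sequence(counts, from = cl$lo[keep]) - 1L) * ny
          labels[lin] <- rays$id[i]
          assigned <- assigned + length(lin)
        }
      }
    }
  } else if (spec$plane == "tangential") {
    t_mid <- mean(rs$ext$x)
    yc_all <- y0 + (seq_len(ny) - 0.5) * res
    r_outer <- max(model$ring_borders)
    for (i in ord) {
      tc <- rays$t_center[i]
      r_slab <- rs$offset + (tc - t_mid) * rs$tilt
      wlo <- max(r_slab - rs$tau / 2, rays$r_init[i], 0)
      whi <- min(r_slab + rs$tau / 2, rays$r_term[i], r_outer)
      if (whi < wlo) next
      ov <- pmin(segs$r_end, whi) >= pmax(segs$r_start, wlo)
      if (!any(ov)) next
      w_eff <- um_to_mm(rays$width_um[i]) * max(segs$factor[ov])
      h_mm <- um_to_mm(rays$height_um[i] +
        slope * max((wlo + whi) / 2 - rays$r_init[i], 0))
      rw <- rows_for(rays$z_center[i] - h_mm / 2, rays$z_center[i] + h_mm / 2)
      if (rw$hi < rw$lo) next
      rows <- rw$lo:rw$hi
      u <- 2 * (yc_all[rows] - rays$z_center[i]) / h_mm
      hw <- w_eff / 2 * profile_factor(u, p)
      cl <- cols_for(tc - hw, tc + hw)
      keep <- hw > 0 & cl$hi >= cl$lo
      if (!any(keep)) next
      counts <- cl$hi[keep] - cl$lo[keep] + 1L
      lin <- rep.int(rows[keep], counts) +
        (sequence(counts, from = cl$lo[keep]) - 1L) * ny
      labels[lin] <- rays$id[i]
      assigned <- assigned + length(lin)
    }
  } else { # radial
    r_mid <- mean(rs$ext$x)
    xc_all <- x0 + (seq_len(nx) - 0.5) * res
    for (i in ord) {
      w_mm <- um_to_mm(rays$width_um[i])
      for (s in seg_first[i]:seg_last[i]) {
        a <- max(rays$r_init[i], segs$r_start[s], rs$ext$x[1])
        b <- min(rays$r_term[i], segs$r_end[s], rs$ext$x[2])
        if (b <= a) next
        cw <- cols_for(a, b)
        if (cw$hi < cw$lo) next
        cols <- cw$lo:cw$hi
        h_mm <- um_to_mm(rays$height_um[i] + slope * max((a + b) / 2 - rays$r_init[i], 0))
        w_seg <- w_mm * segs$factor[s]
        delta <- abs(rays$t_center[i] - (rs$offset + (xc_all[cols] - r_mid) * rs$tilt))
        cc <- (delta - rs$tau / 2) / (w_seg / 2)
        umax <- ifelse(cc <= 0, 1, ifelse(cc >= 1, NA_real_,
          if (p == 0) 1 else sqrt(pmax(1 - pmax(cc, 0)^(1 / p), 0))
        ))
        zlo <- rays$z_center[i] - umax * h_mm / 2
        zhi <- rays$z_center[i] + umax * h_mm / 2
        ilo <- pmax(1L, as.integer(ceiling((zlo - y0) / res + 0.5)))
        ihi <- pmin(ny, as.integer(floor((zhi - y0) / res + 0.5)))
        keep <- !is.na(umax) & ihi >= ilo
        if (!any(keep)) next
        counts <- ihi[keep] - ilo[keep] + 1L
        lin <- sequence(counts, from = ilo[keep]) +
          (rep.int(cols[keep], counts) - 1L) * ny
        labels[lin] <- rays$id[i]
        assigned <- assigned + length(lin)
      }
    }
  }

  overlap_px <- assigned - count_nonzero(labels)
  structure(
    list(
      labels = labels,
      pixel_size_um = spec$resolution_um,
      plane = spec$plane,
      spec = spec,
      x0 = x0, y0 = y0,
      nx = nx, ny = ny,
      ring_borders = model$ring_borders,
      latewood_onsets = model$latewood_onsets,
      overlap_px = as.integer(overlap_px),
      model_config = model$config
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "<section_image> %s plane, %d x %d px at %g um/px (%.2f mm2), %d rays, %.2f%% ray surface\n",
    x$plane, x$nx, x$ny, x$pixel_size_um,
    x$nx * x$ny * um_to_mm(x$pixel_size_um)^2,
    length(setdiff(unique(as.vector(x$labels)), 0L)),
    100 * count_nonzero(x$labels) / (x$nx * x$ny)
  ))
  invisible(x)
}

#' Measured surface of a section image
#'
#' @param image A [cut_section()] image.
#' @return Surface in mm2 (pixel count times squared pixel size).
#' @export
section_surface_mm2 <- function(image) {
  image$nx * image$ny * um_to_mm(image$pixel_size_um)^2
}

#' Projected outline of a single ray
#'
#' The exact union-over-depth silhouette of one ray within a slab, in plane
#' coordinates -- the vector-geometry counterpart of what [cut_section()]
#' rasterizes.  Because the perceived contour is the maximum projection
#' through the section thickness, the outline can only be as large or
#' larger than a zero-thickness planar cut: a radial slab that merely
#' grazes a ray's tangential edge still yields a non-empty outline, and a
#' cross-sectional slab reports the widest lens level it contains.
#'
#' @param ray A single-row data frame with the `rays` columns of a
#'   [generate_wood()] model (`t_center`, `z_center`, `r_init`, `r_term`,
#'   `height_um`, `width_um`, `lens_exponent`).
#' @param spec A [section_spec()]; `offset` must be set.
#' @param model Optional model supplying ring-wise width modifiers; without
#'   it all modifiers are 1.
#' @param n Number of profile samples along the outline.
#' @return A tibble of boundary vertices (`x_mm`, `y_mm`), traversed
#'   counter-clockwise, with attributes `width_mm` and `height_mm` (the
#'   axis-aligned extents); zero rows when the ray misses the slab.
#' @export
projected_outline <- function(ray, spec, model = NULL, n = 201) {
  stopifnot(inherits(spec, "section_spec"))
  if (is.null(spec$offset)) rlang::abort("spec$offset must be set for projected_outline()")
  tau <- um_to_mm(spec$thickness_um)
  p <- ray$lens_exponent
  h <- um_to_mm(ray$height_um)
  w <- um_to_mm(ray$width_um)
  empty <- tibble::tibble(x_mm = numeric(0), y_mm = numeric(0))
  factor_at <- function(r) {
    if (is.null(model)) return(rep(1, length(r)))
    segs <- radial_segments(model)
    idx <- pmin(pmax(findInterval(r, segs$r_start, rightmost.closed = TRUE), 1L), nrow(segs))
    segs$factor[idx]
  }
  close_poly <- function(x_right, y, x_left) {
    tibble::tibble(
      x_mm = c(x_right, rev(x_left)),
      y_mm = c(y, rev(y))
    )
  }
  out <- if (spec$plane == "tangential") {
    wlo <- max(spec$offset - tau / 2, ray$r_init)
    whi <- min(spec$offset + tau / 2, ray$r_term)
    if (whi < wlo) return(empty)
    f <- max(factor_at(seq(wlo, whi, length.out = 9)))
    u <- seq(-1, 1, length.out = n)
    hw <- w * f / 2 * profile_factor(u, p)
    close_poly(ray$t_center + hw, ray$z_center + u * h / 2, ray$t_center - hw)
  } else if (spec$plane == "cross") {
    delta <- abs(ray$z_center - spec$offset)
    if (delta > h / 2 + tau / 2) return(empty)
    ustar <- max(0, (delta - tau / 2) / (h / 2))
    r <- seq(ray$r_init, ray$r_term, length.out = n)
    hw <- w * factor_at(r) / 2 * profile_factor(ustar, p)
    close_poly(ray$t_center + hw, r, ray$t_center - hw)
  } else {
    r <- seq(ray$r_init, ray$r_term, length.out = n)
    delta <- abs(ray$t_center - spec$offset)
    cc <- (delta - tau / 2) / (w * factor_at(r) / 2)
    umax <- ifelse(cc <= 0, 1, ifelse(cc >= 1, NA_real_,
      if (p == 0) 1 else sqrt(pmax(1 - pmax(cc, 0)^(1 / p), 0))
    ))
    if (all(is.na(umax))) return(empty)
    keep <- !is.na(umax)
    tibble::tibble(
      x_mm = c(r[keep], rev(r[keep])),
      y_mm = c(
        ray$z_center + (umax * h / 2)[keep],
        rev(ray$z_center - (umax * h / 2)[keep])
      )
    )
  }
  if (nrow(out)) {
    attr(out, "width_mm") <- diff(range(out$x_mm))
    attr(out, "height_mm") <- diff(range(out$y_mm))
  }
  out
}
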