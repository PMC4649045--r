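#' Generate a synthetic 3D stem sector with uniseriate rays
#'
#' Builds a Cartesian stem-sector model from a [wood_config()]: annual ring
#' borders with early/latewood onsets, per-ring lognormal year factors, and
#' a table of fusiform uniseriate rays placed by a seeded point process in
#' the tangential (t, z) plane.  Persistent rays span the full radial
#' extent; ring-initiated rays start at a uniform radial position inside
#' their zone and terminate at a later ring border with the configured
#' per-border probability (otherwise they reach the bark-side boundary).
#' Identical configuration and seed give a bit-identical model.
#'
#' @param config A [wood_config()].
#' @return An object of class `wood_model`: a list with elements `config`,
#'   `ring_borders` (mm, strictly increasing, starting at 0),
#'   `latewood_onsets` (per ring, mm), `year_factors` (per ring,
#'   multiplicative, mean 1) and `rays`, a tibble with one row per ray
#'   (`id`, `t_center`, `z_center`, `r_init`, `r_term` in mm; `height_um`,
#'   `width_um`; `lens_exponent`; `origin`, `ring_init`, `zone_init`).
#' @examples
#' m <- generate_wood(wood_config(n_rings = 3, tangential_extent = 2, axial_extent = 2))
#' nrow(m$rays)
#' @export
generate_wood <- function(config) {
  config <- validate_wood_config(config)
  with_seed(config$rng_seed, generate_wood_impl(config))
}

generate_wood_impl <- function(cfg) {
  k <- cfg$n_rings
  widths <- if (cfg$ring_width_cv > 0) {
    s <- sqrt(log(1 + cfg$ring_width_cv^2))
    stats::rlnorm(k, meanlog = log(cfg$ring_width_mean) - s^2 / 2, sdlog = s)
  } else {
    rep(cfg$ring_width_mean, k)
  }
  if (!is.null(cfg$radial_extent)) widths <- widths * cfg$radial_extent / sum(widths)
  borders <- c(0, cumsum(widths))
  onsets <- borders[-length(borders)] + (1 - cfg$latewood_fraction) * widths

  year_factors <- if (cfg$interannual_cv > 0) {
    s <- sqrt(log(1 + cfg$interannual_cv^2))
    stats::rlnorm(k, meanlog = -s^2 / 2, sdlog = s)
  } else {
    rep(1, k)
  }

  # Ray centers are placed on a dilated (t, z) window so that coverage is
  # stationary up to the sector faces (no edge deficit inside the sector);
  # intensities refer to unit area, so counts scale with the dilated area.
  mt <- 5 * um_to_mm(cfg$ray_width_mean)
  mz <- 2.5 * um_to_mm(cfg$ray_height_mean)
  t_range <- c(-mt, cfg$tangential_extent + mt)
  z_range <- c(-mz, cfg$axial_extent + mz)
  area <- diff(t_range) * diff(z_range)
  r_outer <- borders[length(borders)]

  draw_pool <- function(n, r_init, ring_init, zone_init) {
    if (n == 0L) {
      return(tibble::tibble(
        t_center = numeric(0), z_center = numeric(0), r_init = numeric(0),
        r_term = numeric(0), height_um = numeric(0), width_um = numeric(0),
        origin = character(0), ring_init = integer(0), zone_init = character(0)
      ))
    }
    t_center <- stats::runif(n, t_range[1], t_range[2])
    z_center <- stats::runif(n, z_range[1], z_range[2])
    height <- if (cfg$ray_height_cv > 0) {
      s <- sqrt(log(1 + cfg$ray_height_cv^2))
      stats::rlnorm(n, meanlog = log(cfg$ray_height_mean) - s^2 / 2, sdlog = s)
    } else {
      rep(cfg$ray_height_mean, n)
    }
    tibble::tibble(
      t_center = t_center, z_center = z_center,
      r_init = r_init, r_term = r_outer,
      height_um = height, width_um = rep(cfg$ray_width_mean, n),
      origin = if (is.na(ring_init)) "base" else "ring",
      ring_init = rep(as.integer(ring_init), n),
      zone_init = rep(zone_init, n)
    )
  }

  n_base <- stats::rpois(1, cfg$ray_density * area)
  pools <- list(draw_pool(n_base, r_init = 0, ring_init = NA, zone_init = NA_character_))

  if (cfg$initiation_density > 0) {
    for (kk in seq_len(k)) {
      rw_e <- onsets[kk] - borders[kk]
      rw_l <- borders[kk + 1] - onsets[kk]
      n_e <- stats::rpois(1, cfg$initiation_density * rw_e * area)
      n_l <- stats::rpois(
        1,
        cfg$initiation_density * cfg$latewood_initiation_multiplier * rw_l * area
      )
      p_e <- draw_pool(n_e, r_init = 0, ring_init = kk, zone_init = "early")
      if (n_e > 0) p_e$r_init <- stats::runif(n_e, borders[kk], onsets[kk])
      p_l <- draw_pool(n_l, r_init = 0, ring_init = kk, zone_init = "late")
      if (n_l > 0) p_l$r_init <- stats::runif(n_l, onsets[kk], borders[kk + 1])
      pools <- c(pools, list(p_e), list(p_l))
    }
  }
  rays <- dplyr::bind_rows(pools)

  # true terminations: survive each subsequent ring border with prob (1 - q)
  q <- cfg$termination_probability
  if (q > 0 && nrow(rays) > 0) {
    ring_rows <- which(rays$origin == "ring")
    for (i in ring_rows) {
      kk <- rays$ring_init[i]
      term <- r_outer
      for (b in seq(kk + 1L, k + 1L)) {
        if (stats::runif(1) < q) {
          term <- borders[b]
          break
        }
        if (b == k + 1L) term <- r_outer
      }
      rays$r_term[i] <- term
    }
  }

  if (cfg$placement == "hardcore" && nrow(rays) > 1) {
    rays <- thin_hardcore(rays)
  }

  if (nrow(rays) > 0) {
    # ids order rays by increasing radial span: where projections overlap,
    # the lowest id wins the pixel, and priority for short-lived rays
    # preserves the most information (a long band keeps its identity
    # through its remaining pixels; a fully contained short ray would not)
    rays <- rays[order(rays$r_term - rays$r_init, rays$t_center, rays$z_center), ]
    rays <- dplyr::mutate(rays,
      id = dplyr::row_number(),
      lens_exponent = cfg$lens_shape_exponent
    )
    rays <- dplyr::select(
      rays, "id", "t_center", "z_center", "r_init", "r_term",
      "height_um", "width_um", "lens_exponent", "origin", "ring_init", "zone_init"
    )
  } else {
    rays <- tibble::tibble(
      id = integer(0), t_center = numeric(0), z_center = numeric(0),
      r_init = numeric(0), r_term = numeric(0), height_um = numeric(0),
      width_um = numeric(0), lens_exponent = numeric(0), origin = character(0),
      ring_init = integer(0), zone_init = character(0)
    )
  }

  structure(
    list(
      config = cfg, ring_borders = borders, latewood_onsets = onsets,
      year_factors = year_factors, rays = rays
    ),
    class = "wood_model"
  )
}

# Simple sequential inhibition: keep rays in order, dropping any whose
# tangential gap to an already-kept, radially and axially co-occurring ray
# is smaller than one ray width (edge-to-edge), i.e. center distance
# < 2 * width.  Prevents apparent biseriate pairs.
thin_hardcore <- function(rays) {
  n <- nrow(rays)
  keep <- logical(n)
  for (i in seq_len(n)) {
    prev <- which(keep)
    ok <- TRUE
    if (length(prev)) {
      dt <- abs(rays$t_center[prev] - rays$t_center[i])
      min_gap <- 2 * um_to_mm((rays$width_um[prev] + rays$width_um[i]) / 2)
      dz <- abs(rays$z_center[prev] - rays$z_center[i])
      z_overlap <- dz < um_to_mm(rays$height_um[prev] + rays$height_um[i]) / 2
      r_overlap <- rays$r_init[prev] < rays$r_term[i] & rays$r_term[prev] > rays$r_init[i]
      ok <- !any(dt < min_gap & z_overlap & r_overlap)
    }
    keep[i] <- ok
  }
  rays[keep, , drop = FALSE]
}

#' @export
print.wood_model <- function(x, ...) {
  cat("<wood_model>\n")
  cat(sprintf(
    "  %d rays in a %.2f x %.2f x %.2f mm sector (r x t x z), %d rings\n",
    nrow(x$rays), max(x$ring_borders), x$config$tangential_extent,
    x$config$axial_extent, x$config$n_rings
  ))
  cat(sprintf(
    "  true ray volume fraction: %.3f %%\n",
    true_volume_fraction(x, mc_points = 20000)
  ))
  invisible(x)
}

# Piecewise-constant local width modifiers along the radial axis: one
# segment per ring x zone, carrying the year factor and the latewood width
# multiplier.  Returned as a data frame ordered by radius.
radial_segments <- function(model) {
  cfg <- model$config
  k <- cfg$n_rings
  borders <- model$ring_borders
  onsets <- model$latewood_onsets
  tibble::tibble(
    ring = rep(seq_len(k), each = 2L),
    zone = rep(c("early", "late"), k),
    r_start = as.vector(rbind(borders[-length(borders)], onsets)),
    r_end = as.vector(rbind(onsets, borders[-1])),
    factor = as.vector(rbind(
      model$year_factors,
      model$year_factors * cfg$latewood_perpar_multiplier
    ))
  )
}

# Local width (mm) of ray `i` at radial positions r (vectorized over r).
local_width_mm <- function(model, i, r) {
  segs <- radial_segments(model)
  idx <- findInterval(r, segs$r_start, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(segs))
  um_to_mm(model$rays$width_um[i]) * segs$factor[idx]
}

# Does a 3D point lie inside ray `i`?  Vectorized over points.
point_in_ray <- function(model, i, r, t, z) {
  ray <- model$rays[i, ]
  h_mm <- um_to_mm(ray$height_um + model$config$ray_height_slope * pmax(r - ray$r_init, 0))
  u <- 2 * (z - ray$z_center) / h_mm
  inside_rz <- r >= ray$r_init & r <= ray$r_term & abs(u) <= 1
  hw <- local_width_mm(model, i, r) / 2 * profile_factor(u, ray$lens_exponent)
  inside_rz & abs(t - ray$t_center) <= hw
}

# (1 - u^2)^p on |u| <= 1, 0 outside; handles p = 0 (rectangular sheet).
profile_factor <- function(u, p) {
  f <- pmax(1 - u^2, 0)
  out <- ifelse(abs(u) <= 1, if (p == 0) 1 else f^p, 0)
  out
}

#' True ray volume fraction of a model
#'
#' Analytic ray volume percentage of the sector.  Each ray's volume is its
#' lens cross-area integrated along its radial span, with the local width
#' modifiers (year factors, latewood multiplier) applied segment by
#' segment.  When ray bounding boxes overlap, the double-counted volume is
#' subtracted via a Monte-Carlo estimate confined to the overlapping
#' regions (deterministic given the model seed); with no overlaps the
#' result is exact.
#'
#' @param model A [generate_wood()] model.
#' @param mc_points Number of Monte-Carlo points for the overlap
#'   correction.
#' @return Volume fraction in percent.
#' @export
true_volume_fraction <- function(model, mc_points = 200000) {
  rays <- model$rays
  if (nrow(rays) == 0) return(0)
  cfg <- model$config
  segs <- radial_segments(model)
  bp <- lens_breadth_factor(cfg$lens_shape_exponent)
  r_outer <- max(model$ring_borders)
  sector_vol <- r_outer * cfg$tangential_extent * cfg$axial_extent

  # exact sum of individual volumes (piecewise over ring/zone segments);
  # rays protruding through the sector faces are clipped numerically
  seg_len <- outer(rays$r_term, segs$r_end, pmin) - outer(rays$r_init, segs$r_start, pmax)
  seg_len[seg_len < 0] <- 0
  h_mm <- um_to_mm(rays$height_um)
  w_mm <- um_to_mm(rays$width_um)
  f_max <- max(segs$factor)
  inside <- rays$t_center - f_max * w_mm / 2 >= 0 &
    rays$t_center + f_max * w_mm / 2 <= cfg$tangential_extent &
    rays$z_center - h_mm / 2 >= 0 &
    rays$z_center + h_mm / 2 <= cfg$axial_extent
  eff_width <- w_mm %o% segs$factor
  vol_sum <- sum(seg_len[inside, , drop = FALSE] * eff_width[inside, , drop = FALSE] *
    h_mm[inside] * bp)
  for (i in which(!inside)) {
    zs <- seq(
      max(rays$z_center[i] - h_mm[i] / 2, 0),
      min(rays$z_center[i] + h_mm[i] / 2, cfg$axial_extent),
      length.out = 201
    )
    if (length(zs) < 2 || zs[1] >= zs[length(zs)]) next
    u <- 2 * (zs - rays$z_center[i]) / h_mm[i]
    hw0 <- w_mm[i] / 2 * profile_factor(u, rays$lens_exponent[i])
    for (s in seq_len(nrow(segs))) {
      if (seg_len[i, s] <= 0) next
      lo <- pmax(rays$t_center[i] - hw0 * segs$factor[s], 0)
      hi <- pmin(rays$t_center[i] + hw0 * segs$factor[s], cfg$tangential_extent)
      widths <- pmax(hi - lo, 0)
      cross_area <- sum((widths[-1] + widths[-length(widths)]) / 2 * diff(zs))
      vol_sum <- vol_sum + seg_len[i, s] * cross_area
    }
  }

  overcount <- overlap_overcount(model, mc_points)
  100 * (vol_sum - overcount) / sector_vol
}

# Monte-Carlo estimate of the volume counted more than once when rays
# overlap: integral of (k - 1)+ over space, k = number of rays covering a
# point.  Sampling is confined to the union of pairwise bounding-box
# intersections (outside them k <= 1); boxes overlapping each other are
# handled by weighting each point by 1 / (number of boxes containing it).
overlap_overcount <- function(model, mc_points) {
  rays <- model$rays
  n <- nrow(rays)
  if (n < 2) return(0)
  w_max <- um_to_mm(rays$width_um) *
    max(model$year_factors) * max(1, model$config$latewood_perpar_multiplier)
  h_mm <- um_to_mm(rays$height_um + model$config$ray_height_slope *
    pmax(rays$r_term - rays$r_init, 0))
  boxes <- list()
  ord <- order(rays$t_center)
  tc <- rays$t_center[ord]
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (tc[b] - tc[a] > (w_max[i] + w_max[j]) / 2) break
      zlo <- max(rays$z_center[i] - h_mm[i] / 2, rays$z_center[j] - h_mm[j] / 2)
      zhi <- min(rays$z_center[i] + h_mm[i] / 2, rays$z_center[j] + h_mm[j] / 2)
      rlo <- max(rays$r_init[i], rays$r_init[j])
      rhi <- min(rays$r_term[i], rays$r_term[j])
      tlo <- max(rays$t_center[i] - w_max[i] / 2, rays$t_center[j] - w_max[j] / 2)
      thi <- min(rays$t_center[i] + w_max[i] / 2, rays$t_center[j] + w_max[j] / 2)
      # clip to the sector (the volume fraction refers to inside it)
      zlo <- max(zlo, 0); zhi <- min(zhi, model$config$axial_extent)
      tlo <- max(tlo, 0); thi <- min(thi, model$config$tangential_extent)
      if (zhi > zlo && rhi > rlo && thi > tlo) {
        boxes[[length(boxes) + 1]] <- c(rlo, rhi, tlo, thi, zlo, zhi)
      }
    }
  }
  if (!length(boxes)) return(0)
  bx <- do.call(rbind, boxes)
  vols <- (bx[, 2] - bx[, 1]) * (bx[, 4] - bx[, 3]) * (bx[, 6] - bx[, 5])
  total_vol <- sum(vols)
  npts <- pmax(100, round(mc_points * vols / total_vol))
  est <- with_seed(sub_seed(model$config$rng_seed, "overlap_mc"), {
    acc <- 0
    for (b in seq_len(nrow(bx))) {
      np <- npts[b]
      r <- stats::runif(np, bx[b, 1], bx[b, 2])
      t <- stats::runif(np, bx[b, 3], bx[b, 4])
      z <- stats::runif(np, bx[b, 5], bx[b, 6])
      # candidate rays: bounding boxes containing this sample box
      cand <- which(
        rays$t_center - w_max / 2 < bx[b, 4] & rays$t_center + w_max / 2 > bx[b, 3] &
          rays$r_init < bx[b, 2] & rays$r_term > bx[b, 1] &
          rays$z_center - h_mm / 2 < bx[b, 6] & rays$z_center + h_mm / 2 > bx[b, 5]
      )
      k_cover <- rep(0L, np)
      for (i in cand) k_cover <- k_cover + point_in_ray(model, i, r, t, z)
      # weight: 1 / number of sample boxes containing the point
      n_boxes <- rep(0L, np)
      for (bb in seq_len(nrow(bx))) {
        n_boxes <- n_boxes + (r >= bx[bb, 1] & r <= bx[bb, 2] &
          t >= bx[bb, 3] & t <= bx[bb, 4] &
          z >= bx[bb, 5] & z <= bx[bb, 6])
      }
      acc <- acc + vols[b] * mean(pmax(k_cover - 1L, 0) / pmax(n_boxes, 1L))
    }
    acc
  })
  est
}
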