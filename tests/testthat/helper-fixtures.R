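# Shared fixtures: small configurations and hand-built models with known
# geometry, so closed-form expectations can be asserted exactly.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_rings = 3, tangential_extent = 2, axial_extent = 2,
    ring_width_mean = 0.8, ring_width_cv = 0, rng_seed = 42L
  )
  do.call(wood_config, utils::modifyList(defaults, args))
}

# A wood_model built by hand around an explicit ray table (no randomness):
# rings of equal width, no modifiers.
manual_model <- function(rays, n_rings = 1, ring_width = NULL,
                         tangential_extent = 1, axial_extent = 1,
                         radial_extent = 1, latewood_fraction = 0.3,
                         lens_exponent = 1) {
  if (is.null(ring_width)) ring_width <- radial_extent / n_rings
  borders <- seq(0, radial_extent, by = ring_width)
  onsets <- borders[-length(borders)] + (1 - latewood_fraction) * ring_width
  rays$id <- seq_len(nrow(rays))
  if (!"lens_exponent" %in% names(rays)) rays$lens_exponent <- lens_exponent
  if (!"origin" %in% names(rays)) rays$origin <- "base"
  if (!"ring_init" %in% names(rays)) rays$ring_init <- NA_integer_
  if (!"zone_init" %in% names(rays)) rays$zone_init <- NA_character_
  cfg <- wood_config(
    tangential_extent = tangential_extent, axial_extent = axial_extent,
    radial_extent = radial_extent, n_rings = length(borders) - 1L,
    ring_width_mean = ring_width, ring_width_cv = 0,
    latewood_fraction = latewood_fraction,
    lens_shape_exponent = lens_exponent, rng_seed = 1L
  )
  structure(
    list(
      config = cfg, ring_borders = borders, latewood_onsets = onsets,
      year_factors = rep(1, length(borders) - 1L),
      rays = tibble::as_tibble(rays)
    ),
    class = "wood_model"
  )
}

one_ray <- function(t = 0.5, z = 0.5, r0 = 0, r1 = 1, h = 180, w = 25) {
  tibble::tibble(
    t_center = t, z_center = z, r_init = r0, r_term = r1,
    height_um = h, width_um = w
  )
}

# Independent voxel membership test for the brute-force volume oracle:
# written from the lens definition, not shared with package internals.
voxel_volume_fraction <- function(model, voxel_um = 2) {
  cfg <- model$config
  v <- voxel_um / 1000
  r_outer <- max(model$ring_borders)
  rs <- seq(v / 2, r_outer - v / 2, by = v)
  ts <- seq(v / 2, cfg$tangential_extent - v / 2, by = v)
  zs <- seq(v / 2, cfg$axial_extent - v / 2, by = v)
  total <- length(rs) * length(ts) * length(zs)
  occupied <- array(FALSE, dim = c(length(rs), length(ts), length(zs)))
  for (k in seq_len(nrow(model$rays))) {
    ray <- model$rays[k, ]
    ri <- which(rs >= ray$r_init & rs <= ray$r_term)
    zi <- which(abs(zs - ray$z_center) <= ray$height_um / 2000)
    if (!length(ri) || !length(zi)) next
    u <- 2 * (zs[zi] - ray$z_center) / (ray$height_um / 1000)
    hw <- (ray$width_um / 2000) * (1 - u^2)^ray$lens_exponent
    for (a in seq_along(zi)) {
      ti <- which(abs(ts - ray$t_center) <= hw[a])
      if (length(ti)) occupied[ri, ti, zi[a]] <- TRUE
    }
  }
  100 * sum(occupied) / total
}
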