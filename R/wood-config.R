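#' Configuration of a synthetic stem-sector model
#'
#' Defines the geometry and ray demography of a Cartesian stem sector with
#' annual rings (early/latewood zones) and fusiform uniseriate rays, the
#' synthetic ground truth from which virtual sections are cut.  Coordinates
#' are in mm (`r` radial, increasing pith to bark; `t` tangential; `z`
#' axial), cell-scale dimensions in um, and areal ray fractions in percent.
#'
#' Rays come from two pools:
#' * a persistent base population (`ray_density` rays per mm2 of tangential
#'   plane) spanning the whole radial extent -- rays that keep their
#'   connection to the cambium;
#' * ring-initiated rays (`initiation_density` per mm2 of tangential plane
#'   per mm of radial growth) that appear within a ring and may truly end at
#'   a later ring border with probability `termination_probability` per
#'   border.
#'
#' @param tangential_extent,axial_extent Sector size in mm along the
#'   tangential and axial axes.  The tangential default (6.69 mm) is a
#'   typical measured cross-section width for 10-mm increment cores.
#' @param radial_extent Optional radial extent in mm; when supplied, the
#'   simulated ring widths are rescaled to fit it exactly.  By default the
#'   radial extent is the sum of the simulated ring widths.
#' @param n_rings Number of annual rings (>= 1).
#' @param ring_width_mean,ring_width_cv Lognormal ring-width distribution
#'   (arithmetic mean in mm; coefficient of variation).  The default mean of
#'   1.047 mm is a typical mature Scots pine ring width.
#' @param latewood_fraction Fraction (0-1) of each ring's radial width
#'   occupied by latewood (outer zone).
#' @param ray_density Persistent rays per mm2 of tangential plane.
#' @param initiation_density Ring-initiated rays per mm2 of tangential plane
#'   per mm of radial growth, in earlywood; latewood initiation intensity is
#'   this value times `latewood_initiation_multiplier`.
#' @param ray_height_mean,ray_height_cv Lognormal ray height distribution
#'   (arithmetic mean, um).  Heights and widths are placeholders typical of
#'   uniseriate conifer rays, not measured values.
#' @param ray_width_mean Maximum tangential width of the uniseriate sheet
#'   (um); constant across rays.
#' @param ray_height_slope Optional linear increase of ray height with
#'   radial distance from initiation (um per mm); 0 keeps height constant.
#' @param lens_shape_exponent Exponent `p >= 0` of the fusiform tangential
#'   profile: at normalized axial offset `u = 2(z - z_center)/h` the ray
#'   half-width is `(width/2) * (1 - u^2)^p`.  `p = 1` is a pointed spindle,
#'   `p = 0` a rectangular sheet.
#' @param latewood_initiation_multiplier Multiplier (>= 0) on the
#'   per-radial-mm initiation intensity inside latewood.
#' @param latewood_perpar_multiplier Multiplier (>= 0) on local ray width
#'   inside latewood radial zones (models wider parenchyma cells near the
#'   ring border).
#' @param interannual_cv Coefficient of variation of the multiplicative
#'   lognormal year factor applied to ray widths ring by ring (year-to-year
#'   modulation of the ray fraction).
#' @param termination_probability Probability that a ring-initiated ray
#'   truly ends at each ring border it reaches (0 = all rays persist to the
#'   bark-side boundary).
#' @param placement `"poisson"` (independent ray centers; default) or
#'   `"hardcore"` (simple sequential inhibition with a minimum tangential
#'   gap of one ray width between co-occurring rays).
#' @param rng_seed Integer seed; identical configurations and seeds yield
#'   bit-identical models.
#'
#' @return An object of class `wood_config` (a validated named list).
#' @seealso [generate_wood()], [calibrate_volume_fraction()],
#'   [calibrate_cross_sections()]
#' @examples
#' cfg <- wood_config(n_rings = 5, tangential_extent = 2, axial_extent = 2)
#' cfg$ray_density
#' @export
wood_config <- function(tangential_extent = 6.69,
                        axial_extent = 4,
                        radial_extent = NULL,
                        n_rings = 20,
                        ring_width_mean = 1.047,
                        ring_width_cv = 0.2,
                        latewood_fraction = 0.3,
                        ray_density = 15,
                        initiation_density = 0,
                        ray_height_mean = 180,
                        ray_height_cv = 0.25,
                        ray_width_mean = 25,
                        ray_height_slope = 0,
                        lens_shape_exponent = 1,
                        latewood_initiation_multiplier = 1,
                        latewood_perpar_multiplier = 1,
                        interannual_cv = 0,
                        termination_probability = 0,
                        placement = c("poisson", "hardcore"),
                        rng_seed = 1L) {
  placement <- match.arg(placement)
  cfg <- list(
    tangential_extent = tangential_extent,
    axial_extent = axial_extent,
    radial_extent = radial_extent,
    n_rings = n_rings,
    ring_width_mean = ring_width_mean,
    ring_width_cv = ring_width_cv,
    latewood_fraction = latewood_fraction,
    ray_density = ray_density,
    initiation_density = initiation_density,
    ray_height_mean = ray_height_mean,
    ray_height_cv = ray_height_cv,
    ray_width_mean = ray_width_mean,
    ray_height_slope = ray_height_slope,
    lens_shape_exponent = lens_shape_exponent,
    latewood_initiation_multiplier = latewood_initiation_multiplier,
    latewood_perpar_multiplier = latewood_perpar_multiplier,
    interannual_cv = interannual_cv,
    termination_probability = termination_probability,
    placement = placement,
    rng_seed = rng_seed
  )
  validate_wood_config(cfg)
}

validate_wood_config <- function(cfg) {
  check_number(cfg$tangential_extent, "tangential_extent", min = 0, strict_min = TRUE)
  check_number(cfg$axial_extent, "axial_extent", min = 0, strict_min = TRUE)
  if (!is.null(cfg$radial_extent)) {
    check_number(cfg$radial_extent, "radial_extent", min = 0, strict_min = TRUE)
  }
  check_number(cfg$n_rings, "n_rings", min = 1, integer = TRUE)
  cfg$n_rings <- as.integer(cfg$n_rings)
  check_number(cfg$ring_width_mean, "ring_width_mean", min = 0, strict_min = TRUE)
  check_number(cfg$ring_width_cv, "ring_width_cv", min = 0)
  check_number(cfg$latewood_fraction, "latewood_fraction",
    min = 0, max = 1, strict_min = TRUE, strict_max = TRUE
  )
  check_number(cfg$ray_density, "ray_density", min = 0)
  check_number(cfg$initiation_density, "initiation_density", min = 0)
  check_number(cfg$ray_height_mean, "ray_height_mean", min = 0, strict_min = TRUE)
  check_number(cfg$ray_height_cv, "ray_height_cv", min = 0)
  check_number(cfg$ray_width_mean, "ray_width_mean", min = 0, strict_min = TRUE)
  check_number(cfg$ray_height_slope, "ray_height_slope", min = 0)
  check_number(cfg$lens_shape_exponent, "lens_shape_exponent", min = 0)
  check_number(cfg$latewood_initiation_multiplier, "latewood_initiation_multiplier", min = 0)
  check_number(cfg$latewood_perpar_multiplier, "latewood_perpar_multiplier", min = 0)
  check_number(cfg$interannual_cv, "interannual_cv", min = 0)
  check_number(cfg$termination_probability, "termination_probability", min = 0, max = 1)
  check_number(cfg$rng_seed, "rng_seed", integer = TRUE)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  if (cfg$ray_height_mean <= cfg$ray_width_mean) {
    abort_field("ray_height_mean", "must exceed ray_width_mean (sheet-like ray geometry)")
  }
  structure(cfg, class = "wood_config")
}

#' @export
print.wood_config <- function(x, ...) {
  cat("<wood_config>\n")
  cat(sprintf(
    "  sector: %s x %.2f x %.2f mm (r x t x z), %d rings (mean %.3f mm, latewood %.0f%%)\n",
    if (is.null(x$radial_extent)) "[sum of rings]" else sprintf("%.2f", x$radial_extent),
    x$tangential_extent, x$axial_extent, x$n_rings, x$ring_width_mean,
    100 * x$latewood_fraction
  ))
  cat(sprintf(
    "  rays: %.3g /mm2 persistent + %.3g /mm3 initiated, h %.0f um (cv %.2f), w %.1f um, p = %g\n",
    x$ray_density, x$initiation_density, x$ray_height_mean, x$ray_height_cv,
    x$ray_width_mean, x$lens_shape_exponent
  ))
  cat(sprintf(
    "  modifiers: latewood init x%.3g, latewood width x%.3g, interannual cv %.3g, termination %.3g\n",
    x$latewood_initiation_multiplier, x$latewood_perpar_multiplier,
    x$interannual_cv, x$termination_probability
  ))
  cat(sprintf("  placement: %s, seed %d\n", x$placement, x$rng_seed))
  invisible(x)
}

#' Breadth factor of the fusiform lens profile
#'
#' The tangential outline of a ray of height `h` and maximum width `w` with
#' profile exponent `p` has area `w * h * B(p)` where
#' `B(p) = (1/2) * integral of (1 - u^2)^p over [-1, 1]`.
#' In closed form `B(p) = sqrt(pi)/2 * gamma(p + 1) / gamma(p + 3/2)`;
#' `B(0) = 1` (rectangle), `B(1) = 2/3` (pointed spindle).
#'
#' @param p Profile exponent (>= 0), vectorized.
#' @return Dimensionless breadth factor in (0, 1].
#' @export
lens_breadth_factor <- function(p) {
  if (any(!is.finite(p) | p < 0)) abort_field("lens_shape_exponent", "must be >= 0")
  sqrt(pi) / 2 * gamma(p + 1) / gamma(p + 1.5)
}

# Mean tangential lens area of one ray, mm^2.
mean_lens_area_mm2 <- function(cfg) {
  um_to_mm(cfg$ray_width_mean) * um_to_mm(cfg$ray_height_mean) *
    lens_breadth_factor(cfg$lens_shape_exponent)
}

# Per-ring expected initiation intensities (per mm^2 of tangential plane):
# nu_E over the earlywood zone, nu_L over the latewood zone, for a ring of
# expected width `ring_width_mean`.
expected_initiations <- function(cfg) {
  rw_e <- cfg$ring_width_mean * (1 - cfg$latewood_fraction)
  rw_l <- cfg$ring_width_mean * cfg$latewood_fraction
  list(
    nu_e = cfg$initiation_density * rw_e,
    nu_l = cfg$initiation_density * cfg$latewood_initiation_multiplier * rw_l
  )
}

# Mean standing ray density (per mm^2 of tangential plane) in the early and
# latewood zones, averaged over rings.  Ring-initiated rays reside from
# their initiation point to the border where they terminate; survival per
# border is (1 - q).  Exact for q in {0, 1} and for the geometric-survival
# case in between (mean over the K rings).
standing_density <- function(cfg) {
  nu <- expected_initiations(cfg)
  q <- cfg$termination_probability
  k <- seq_len(cfg$n_rings)
  # carry-over from earlier rings, alive at ring k (any zone of ring k)
  carry <- vapply(k, function(kk) {
    j <- seq_len(kk - 1L)
    if (!length(j)) return(0)
    sum((nu$nu_e + nu$nu_l) * (1 - q)^(kk - j))
  }, numeric(1))
  d_early <- cfg$ray_density + carry + 0.5 * nu$nu_e
  d_late <- cfg$ray_density + carry + nu$nu_e + 0.5 * nu$nu_l
  list(early = mean(d_early), late = mean(d_late))
}

#' Expected measured ray fraction of a virtual section
#'
#' Closed-form expectation of the areal ray fraction (PERPAR, %) measured on
#' a rasterized maximum-projection section of thickness `thickness_um`, for
#' a Poisson ray process.  Coverage follows the Boolean-model form
#' `100 * (1 - exp(-eta))` where `eta` is the expected projected ray area
#' per unit section area.  For tangential sections rays are prisms along the
#' slab normal, so the thickness drops out and the expectation equals the
#' true relative ray volume (Delesse principle).  For cross-sections the
#' finite thickness adds the projection through the tapering ray
#' extremities, `eta = d * w * (h * B(p) + thickness)`, the radial
#' overestimation artifact in its weak cross-sectional form.
#'
#' @param config A [wood_config()].
#' @param plane `"tangential"` or `"cross"`.
#' @param thickness_um Section thickness in um.
#' @param zone For `plane = "cross"`: `NULL` (whole ring), `"early"` or
#'   `"late"`.
#' @param width_factor Optional multiplier on ray widths (used to propagate
#'   year factors).
#' @return Expected PERPAR in percent.
#' @export
expected_perpar <- function(config, plane = c("tangential", "cross"),
                            thickness_um = 15, zone = NULL, width_factor = 1) {
  plane <- match.arg(plane)
  check_number(thickness_um, "thickness_um", min = 0)
  w_mm <- um_to_mm(config$ray_width_mean) * width_factor
  h_mm <- um_to_mm(config$ray_height_mean)
  bp <- lens_breadth_factor(config$lens_shape_exponent)
  d <- standing_density(config)
  if (plane == "tangential") {
    if (!is.null(zone)) {
      rlang::abort("`zone` applies to cross-sections only")
    }
    # projected-area intensity averaged over the sector (area-weighted over
    # zones; the latewood width multiplier scales the lens area there)
    eta <- w_mm * h_mm * bp *
      ((1 - config$latewood_fraction) * d$early +
        config$latewood_fraction * d$late * config$latewood_perpar_multiplier)
    return(100 * (1 - exp(-eta)))
  }
  kappa <- w_mm * (h_mm * bp + um_to_mm(thickness_um))
  eta_e <- d$early * kappa
  eta_l <- d$late * kappa * config$latewood_perpar_multiplier
  cov_e <- 1 - exp(-eta_e)
  cov_l <- 1 - exp(-eta_l)
  if (is.null(zone)) {
    100 * ((1 - config$latewood_fraction) * cov_e + config$latewood_fraction * cov_l)
  } else if (zone == "early") {
    100 * cov_e
  } else if (zone == "late") {
    100 * cov_l
  } else {
    rlang::abort('`zone` must be NULL, "early" or "late"')
  }
}

#' Expected standardized number of initiating rays
#'
#' Expectation of the per-ring standardized NEWRAY statistic measured on a
#' cross-section of thickness `thickness_um`: initiating rays counted over
#' the full section width, divided by the radial extent (mm) of the zone
#' they initiate in.  A ray initiating at axial position `z` is visible when
#' its axial span intersects the slab, an `E[h] + thickness` window.
#'
#' @inheritParams expected_perpar
#' @return A list with elements `early` and `late` (rays per mm of zone
#'   radial extent).
#' @export
expected_newray <- function(config, thickness_um = 15) {
  check_number(thickness_um, "thickness_um", min = 0)
  window_mm <- um_to_mm(config$ray_height_mean) + um_to_mm(thickness_um)
  base <- config$initiation_density * config$tangential_extent * window_mm
  list(early = base, late = base * config$latewood_initiation_multiplier)
}

#' Calibrate the generator to a target relative ray volume
#'
#' Scales the persistent ray density so that the analytic expected ray
#' volume fraction of the generated model (Boolean coverage
#' `1 - exp(-d * a)` with `a` the mean tangential lens area) equals
#' `target_vf` percent.  Idempotent: recalibrating a calibrated
#' configuration returns it unchanged.
#'
#' @param config A [wood_config()] (ring-initiated pools are untouched; the
#'   configuration should normally have `initiation_density = 0`).
#' @param target_vf Target true ray volume fraction in percent (0 to 50).
#' @return The configuration with `ray_density` rescaled.
#' @examples
#' cfg <- calibrate_volume_fraction(wood_config(), 4.92)
#' expected_perpar(cfg, "tangential")
#' @export
calibrate_volume_fraction <- function(config, target_vf) {
  check_number(target_vf, "target_vf", min = 0, max = 50, strict_max = TRUE)
  if (target_vf == 0) {
    config$ray_density <- 0
    return(validate_wood_config(config))
  }
  if (config$initiation_density > 0) {
    rlang::warn("calibrating the persistent pool while initiation_density > 0; the ring-initiated contribution is not rescaled")
  }
  config$ray_density <- -log(1 - target_vf / 100) / mean_lens_area_mm2(config)
  validate_wood_config(config)
}

#' Calibrate the generator to measured cross-sectional zone statistics
#'
#' Solves the persistent density, ring-initiation intensity, latewood
#' initiation multiplier and latewood width multiplier so that the expected
#' *measured* values on cross-sections of the given thickness equal the
#' supplied targets: mean early/latewood PERPAR (percent) and standardized
#' early/latewood NEWRAY (initiating rays per mm of zone radial extent,
#' counted over the section width).  Ring-initiated rays are given
#' `termination_probability = 1` (they end at the next ring border), which
#' keeps the standing density stationary ring over ring, so every ring is
#' statistically identical.
#'
#' @param config A [wood_config()] supplying geometry and ray dimensions.
#' @param perpar_early,perpar_late Target zone PERPAR means, percent.
#' @param newray_early,newray_late Target standardized NEWRAY, rays per mm
#'   of zone radial extent.
#' @param thickness_um Section thickness the targets were measured at.
#' @return A recalibrated `wood_config`.  Errors when the targets are
#'   jointly infeasible under the configured ray dimensions (the implied
#'   persistent density or width multiplier would be non-positive).
#' @export
calibrate_cross_sections <- function(config,
                                     perpar_early, perpar_late,
                                     newray_early, newray_late,
                                     thickness_um = 15) {
  check_number(perpar_early, "perpar_early", min = 0, max = 100, strict_min = TRUE)
  check_number(perpar_late, "perpar_late", min = 0, max = 100, strict_min = TRUE)
  check_number(newray_early, "newray_early", min = 0, strict_min = TRUE)
  check_number(newray_late, "newray_late", min = 0, strict_min = TRUE)
  window_mm <- um_to_mm(config$ray_height_mean) + um_to_mm(thickness_um)
  config$initiation_density <- newray_early / (config$tangential_extent * window_mm)
  config$latewood_initiation_multiplier <- newray_late / newray_early
  config$termination_probability <- 1
  nu <- expected_initiations(config)
  w_mm <- um_to_mm(config$ray_width_mean)
  h_mm <- um_to_mm(config$ray_height_mean)
  kappa <- w_mm * (h_mm * lens_breadth_factor(config$lens_shape_exponent) +
    um_to_mm(thickness_um))
  eta_e <- -log(1 - perpar_early / 100)
  eta_l <- -log(1 - perpar_late / 100)
  base <- eta_e / kappa - 0.5 * nu$nu_e
  if (base <= 0) {
    rlang::abort(paste(
      "infeasible calibration: the NEWRAY targets imply more standing rays",
      "in earlywood than the PERPAR target allows (persistent density <= 0)"
    ))
  }
  config$ray_density <- base
  d_late <- base + nu$nu_e + 0.5 * nu$nu_l
  config$latewood_perpar_multiplier <- eta_l / (kappa * d_late)
  validate_wood_config(config)
}
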