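test_that("outline dimensions follow the area-over-height rule", {
  # rectangular sheet (lens exponent 0), 150 um axial x 20 um tangential
  rays <- one_ray(t = 0.5004, z = 0.5004, h = 150, w = 20)
  m <- manual_model(rays, lens_exponent = 0)
  img <- cut_section(m, section_spec("tangential", offset = 0.5, resolution_um = 1))
  o <- extract_outlines(img)
  expect_identical(nrow(o), 1L)
  expect_equal(o$area_um2, 150 * 20)
  expect_equal(o$height_um, 150)
  expect_equal(o$width_um, 20)

  # pointed lens, h = 150, w = 30: derived width = (2/3) * 30 = 20 um
  m2 <- manual_model(one_ray(t = 0.5004, z = 0.5004, h = 150, w = 30), lens_exponent = 1)
  o2 <- extract_outlines(cut_section(m2, section_spec("tangential", offset = 0.5, resolution_um = 0.5)))
  expect_equal(o2$height_um, 150, tolerance = 0.01)
  expect_equal(o2$width_um, 20, tolerance = 0.02)

  # empty image -> empty collection
  o0 <- extract_outlines(cut_section(
    generate_wood(small_config(ray_density = 0)),
    section_spec("tangential", resolution_um = 4)
  ))
  expect_identical(nrow(o0), 0L)
})

test_that("ray fraction trivia: empty, full and half images", {
  m0 <- generate_wood(small_config(ray_density = 0))
  expect_equal(compute_perpar(cut_section(m0, section_spec("cross", resolution_um = 4))), 0)

  # one rectangular sheet spanning the full image height and half its width
  rays <- one_ray(t = 0.25, z = 0.5, h = 1200, w = 500)
  rays$height_um <- 2000 # covers the whole axial extent
  m <- manual_model(rays, lens_exponent = 0)
  img <- cut_section(m, section_spec(
    "cross", offset = 0.5, resolution_um = 2,
    extent = list(x = c(0, 1), y = c(0, 1))
  ))
  expect_equal(compute_perpar(img), 50, tolerance = 0.5)
  expect_equal(compute_perpar(img, region = c(0, 0.5, 0, 1)), 100, tolerance = 1e-9)
  expect_error(compute_perpar(img, region = c(2, 3, 2, 3)), "no pixels")
})

test_that("ring metrics count and standardize initiating rays as specified", {
  # hand-built geometry: 2 rings of 1 mm, image 2 mm wide; three rays
  # initiating inside ring 1 (two early, one late), one ray initiating in
  # ring 2 early, one persistent ray
  rw <- list(
    one_ray(t = 0.30, z = 0.50, r0 = 0.0, r1 = 2, h = 600, w = 30), # persistent
    one_ray(t = 0.60, z = 0.45, r0 = 0.20, r1 = 2, h = 600, w = 30), # ring 1 early
    one_ray(t = 0.95, z = 0.55, r0 = 0.35, r1 = 2, h = 600, w = 30), # ring 1 early
    one_ray(t = 1.30, z = 0.50, r0 = 0.80, r1 = 2, h = 600, w = 30), # ring 1 late
    one_ray(t = 1.70, z = 0.48, r0 = 1.30, r1 = 1.85, h = 600, w = 30) # ring 2 early, disappearing
  )
  m <- manual_model(dplyr::bind_rows(rw),
    n_rings = 2, radial_extent = 2,
    tangential_extent = 2, latewood_fraction = 0.3, lens_exponent = 0
  )
  img <- cut_section(m, section_spec("cross", offset = 0.5, resolution_um = 2))
  met <- ring_metrics(img)

  expect_identical(met$newray_count, c(3L, 1L))
  expect_equal(met$newray_per_mm, c(1.5, 0.5)) # 3 initiating over 2 mm width
  expect_equal(met$newray_early_per_mm, c(2 / 0.7, 1 / 0.7))
  expect_equal(met$newray_late_per_mm, c(1 / 0.3, 0))
  expect_identical(met$disappearing_count, c(0L, 1L))
  # zone counts add up to the ring count
  expect_equal(met$newray_early_per_mm * 0.7 + met$newray_late_per_mm * 0.3,
    as.numeric(met$newray_count))

  # whole-image fraction equals the ring-area-weighted mean of ring values
  w <- met$ring_width_mm / sum(met$ring_width_mm)
  expect_equal(sum(w * met$perpar), compute_perpar(img), tolerance = 0.01)

  expect_error(ring_metrics(cut_section(m, section_spec("tangential"))), "cross")
})

test_that("aligned sections of persistent models report no disappearing rays", {
  cfg <- calibrate_volume_fraction(small_config(n_rings = 5, ring_width_mean = 0.8), 5)
  for (s in 1:3) {
    cfg$rng_seed <- s
    img <- cut_section(generate_wood(cfg), section_spec("cross", resolution_um = 3))
    expect_identical(sum(ring_metrics(img)$disappearing_count), 0L)
  }
})

test_that("latewood multipliers raise latewood values over many simulated rings", {
  cfg <- calibrate_cross_sections(
    wood_config(tangential_extent = 4, axial_extent = 2),
    perpar_early = 5.77, perpar_late = 6.18,
    newray_early = 21.82 * 4 / 6.69, newray_late = 23.75 * 4 / 6.69
  )
  mets <- purrr::map_dfr(1:3, function(s) {
    cfg$rng_seed <- s
    img <- cut_section(generate_wood(cfg), section_spec("cross", offset = 1))
    ring_metrics(img)
  })
  expect_gte(nrow(mets), 40)
  expect_gt(mean(mets$perpar_late), mean(mets$perpar_early))
})

test_that("time series assemble year-ordered and consistent with ring values", {
  met <- tibble::tibble(
    ring = c(2L, 1L, 3L), year = c(2L, 1L, 3L), ring_width_mm = 1,
    perpar = c(5, 4, 6), perpar_early = 1, perpar_late = 1,
    newray_count = 0L, newray_per_mm = 0, newray_early_per_mm = 0,
    newray_late_per_mm = 0, disappearing_count = 0L,
    mean_ray_area_um2 = NA_real_, mean_ray_length_um = NA_real_,
    mean_ray_width_um = NA_real_, n_outlines = 0L
  )
  ts <- assemble_time_series(met, "perpar")
  expect_equal(ts$year, 1:3)
  expect_equal(ts$value, c(4, 5, 6))
  expect_error(assemble_time_series(met, "no_such"), "valid metrics")
  expect_error(assemble_time_series(met[1, ], "perpar"), "at least 2")

  # series values equal the per-ring recomputation from the image
  m <- generate_wood(calibrate_volume_fraction(small_config(rng_seed = 4), 5))
  img <- cut_section(m, section_spec("cross", resolution_um = 3))
  met2 <- ring_metrics(img)
  ts2 <- assemble_time_series(met2, "perpar")
  for (k in c(1L, nrow(met2))) {
    direct <- compute_perpar(img, region = c(
      img$x0, img$x0 + img$nx * img$pixel_size_um / 1000,
      m$ring_borders[k], m$ring_borders[k + 1]
    ))
    expect_equal(ts2$value[k], direct, tolerance = 0.05)
  }
})

test_that("ray density times mean area matches the areal fraction", {
  m <- generate_wood(calibrate_volume_fraction(
    small_config(tangential_extent = 4, axial_extent = 4, rng_seed = 12), 5
  ))
  img <- cut_section(m, section_spec("tangential", resolution_um = 2))
  o <- extract_outlines(img)
  density <- nrow(o) / section_surface_mm2(img)
  mean_area_mm2 <- mean(o$area_um2) * 1e-6
  expect_equal(
    density * mean_area_mm2, compute_perpar(img) / 100,
    tolerance = 0.03
  )
})
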