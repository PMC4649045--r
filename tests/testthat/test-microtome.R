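test_that("section specs are validated and empty models cut to background", {
  expect_error(section_spec("cross", thickness_um = 60), "thickness_um")
  expect_error(section_spec("cross", misalignment_deg = 15), "misalignment_deg")
  expect_error(section_spec("cross", resolution_um = 0.1), "resolution_um")
  expect_error(section_spec("oblique"))

  m0 <- generate_wood(small_config(ray_density = 0))
  img <- cut_section(m0, section_spec("tangential", resolution_um = 4))
  expect_true(all(img$labels == 0L))
  expect_equal(compute_perpar(img), 0)

  expect_error(
    cut_section(m0, section_spec("cross", offset = 50)),
    "outside the sector"
  )
})

test_that("thin tangential sections satisfy the Delesse principle", {
  # areal fraction on zero-thickness tangential cuts estimates the true
  # volume fraction without bias (averaged over replicate models)
  cfg <- calibrate_volume_fraction(
    small_config(n_rings = 3, ring_width_mean = 1, tangential_extent = 3,
      axial_extent = 3),
    5
  )
  meas <- truth <- numeric(30)
  for (s in 1:30) {
    cfg$rng_seed <- s
    m <- generate_wood(cfg)
    img <- cut_section(m, section_spec("tangential", thickness_um = 0, resolution_um = 3))
    meas[s] <- compute_perpar(img)
    truth[s] <- true_volume_fraction(m, mc_points = 50000)
  }
  # paired per-model comparison removes the dominant ray-count noise
  expect_lt(abs(mean(meas - truth)), 0.08)
  expect_lt(abs(mean(meas) - 5) / 5, 0.05)
})

test_that("projected outlines obey the closed-form lens geometry", {
  ray <- one_ray(t = 0.5, z = 0.5, r0 = 0, r1 = 1, h = 180, w = 25)[1, ]
  ray$lens_exponent <- 1

  # planar tangential cut: the full lens, height h and width w
  po <- projected_outline(ray, section_spec("tangential", offset = 0.5, thickness_um = 0))
  expect_equal(attr(po, "height_mm") * 1000, 180, tolerance = 1e-6)
  expect_equal(attr(po, "width_mm") * 1000, 25, tolerance = 1e-6)

  # cross slab away from the lens equator: the projected width equals the
  # lens width at the widest level inside the slab, wider than the planar cut
  h <- 0.18
  tau <- 15
  off <- 0.5 + h / 4
  po_c <- projected_outline(ray, section_spec("cross", offset = off, thickness_um = tau))
  ustar <- (h / 4 - tau / 2000) / (h / 2)
  expect_equal(attr(po_c, "width_mm") * 1000, 25 * (1 - ustar^2), tolerance = 1e-6)
  planar_width <- 25 * (1 - (h / 4 / (h / 2))^2)
  expect_gt(attr(po_c, "width_mm") * 1000, planar_width)

  # radial slab grazing the ray's tangential edge: non-empty at finite
  # thickness although the zero-thickness plane misses the ray entirely
  graze <- 0.5 + 25 / 2000 + 0.003
  po_r0 <- projected_outline(ray, section_spec("radial", offset = graze, thickness_um = 0))
  po_r <- projected_outline(ray, section_spec("radial", offset = graze, thickness_um = 15))
  expect_identical(nrow(po_r0), 0L)
  expect_gt(nrow(po_r), 0L)
})

test_that("image ray fraction is non-decreasing in slab thickness on every plane", {
  m <- generate_wood(calibrate_volume_fraction(small_config(rng_seed = 11), 5))
  for (plane in c("cross", "tangential", "radial")) {
    pp <- vapply(c(0, 5, 15, 30, 50), function(tau) {
      compute_perpar(cut_section(m, section_spec(plane, thickness_um = tau, resolution_um = 3)))
    }, numeric(1))
    expect_true(all(diff(pp) >= 0), info = plane)
  }
})

test_that("perfectly aligned cross-sections lose no rays; tilted ones do, increasingly", {
  cfg <- calibrate_volume_fraction(
    small_config(n_rings = 6, ring_width_mean = 1, tangential_extent = 4,
      axial_extent = 3, rng_seed = 31),
    6
  )
  m <- generate_wood(cfg)
  n_disappear <- vapply(c(0, 1.5, 3), function(ang) {
    img <- cut_section(m, section_spec("cross", misalignment_deg = ang, resolution_um = 3))
    sum(extract_outlines(img)$disappearing)
  }, numeric(1))
  expect_identical(n_disappear[1], 0)
  expect_true(all(diff(n_disappear) >= 0))
  expect_gt(n_disappear[3], 0)
})

test_that("rasterized ray fraction converges with grid refinement", {
  # sections need enough rays for the per-ray quantization phases to
  # average out: a wide cross-section and a full tangential face
  m <- generate_wood(calibrate_volume_fraction(
    small_config(n_rings = 4, ring_width_mean = 1, tangential_extent = 10,
      axial_extent = 3, rng_seed = 7),
    5
  ))
  for (plane in c("cross", "tangential")) {
    p4 <- compute_perpar(cut_section(m, section_spec(plane, resolution_um = 4)))
    p1 <- compute_perpar(cut_section(m, section_spec(plane, resolution_um = 1)))
    expect_lt(abs(p4 - p1) / p1, 0.02)
  }
})

test_that("overlapping projections resolve to the lowest id and are tallied", {
  rays <- dplyr::bind_rows(
    one_ray(t = 0.500, z = 0.5, h = 200, w = 30),
    one_ray(t = 0.508, z = 0.52, h = 200, w = 30)
  )
  m <- manual_model(rays)
  img <- cut_section(m, section_spec("cross", offset = 0.5, resolution_um = 1))
  expect_gt(img$overlap_px, 0)
  # contested pixels belong to ray 1
  mid_col <- round((0.504 - img$x0) / 0.001)
  owners <- unique(img$labels[, mid_col])
  expect_true(1L %in% owners)
  expect_false(2L %in% owners)
  # both rays keep some pixels
  expect_setequal(setdiff(unique(as.vector(img$labels)), 0L), c(1L, 2L))
})

test_that("label maps round trip through PNG + JSON sidecars", {
  m <- generate_wood(small_config())
  img <- cut_section(m, section_spec("cross", resolution_um = 4))
  png <- withr::local_tempfile(fileext = ".png")
  write_section_image(img, png)
  img2 <- read_section_image(png)
  expect_identical(img$labels, img2$labels)
  expect_equal(img$ring_borders, img2$ring_borders)
  expect_equal(img$pixel_size_um, img2$pixel_size_um)
  expect_identical(extract_outlines(img)$area_um2, extract_outlines(img2)$area_um2)
})
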