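test_that("brain mask voxel count matches the analytic ellipsoid volume", {
  # ellipsoid that needs a taller FOV than the default grid provides
  cfg <- subject_config(seed = 1, semiaxes = c(80, 95, 75), cavities = list(),
                        fov = c(220, 250, 170), mask_margin_mm = 0)
  mk <- make_brain_mask(cfg)
  vol_analytic <- 4 / 3 * pi * 80 * 95 * 75
  vol_voxels <- sum(mk$data) * prod(cfg$spacing)
  expect_lt(abs(vol_voxels - vol_analytic) / vol_analytic, 0.02)
})

test_that("a cavity carved inside the ellipsoid removes about its volume", {
  base <- subject_config(seed = 1, semiaxes = c(80, 95, 75),
                         cavities = list(), fov = c(220, 250, 170),
                         mask_margin_mm = 0)
  with_cav <- subject_config(seed = 1, semiaxes = c(80, 95, 75),
                             cavities = list(cavity_spec(c(0, 0, 0), 12)),
                             fov = c(220, 250, 170), mask_margin_mm = 0)
  n0 <- sum(make_brain_mask(base)$data)
  n1 <- sum(make_brain_mask(with_cav)$data)
  expected_drop <- 4 / 3 * pi * 12^3 / prod(base$spacing)
  expect_lt(abs((n0 - n1) - expected_drop) / expected_drop, 0.05)
})

test_that("degenerate or oversized ellipsoids are rejected", {
  expect_error(subject_config(semiaxes = c(0, 50, 50)), "positive")
  too_big <- subject_config(semiaxes = c(80, 95, 75))  # default 120 mm z-FOV
  expect_error(make_brain_mask(too_big), "fit")
})

test_that("cavity dipole field matches the closed form", {
  geom <- field_map(array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
                    origin = c(0, 0, 20))  # single voxel on the +z axis
  cav <- cavity_spec(c(0, 0, 0), radius = 10, delta_chi_ppm = 9.4)
  f0 <- 42.577e6 * 3
  expected_axis <- f0 * (9.4e-6 / 3) * (10 / 20)^3 * 2
  got <- cavity_dipole_field(cav, geom, b0_tesla = 3)$data[1]
  expect_equal(got, expected_axis, tolerance = 1e-12)
  expect_equal(got, 100.06, tolerance = 1e-3)  # ~100 Hz at 2 radii on axis

  # equatorial point at the same distance: angular factor -1, half magnitude
  geom_eq <- field_map(array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
                       origin = c(20, 0, 0))
  got_eq <- cavity_dipole_field(cav, geom_eq, b0_tesla = 3)$data[1]
  expect_equal(got_eq, -expected_axis / 2, tolerance = 1e-12)

  # far-field decay to zero
  geom_far <- field_map(array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
                        origin = c(0, 0, 2000))
  expect_lt(abs(cavity_dipole_field(cav, geom_far, 3)$data[1]), 1e-3)

  expect_error(cavity_dipole_field(cav, geom, b0_tesla = 0), "b0")
})

test_that("dipole field is trace-free: near-zero mean over a thick shell", {
  cav <- cavity_spec(c(0, 0, 0), radius = 10)
  geom <- grid_geometry_for_test(spacing = c(2, 2, 2), fov = c(160, 160, 160))
  f <- cavity_dipole_field(cav, geom, 3)
  p <- voxel_centers_for_test(geom)
  r <- sqrt(rowSums(p^2))
  shell <- r > 20 & r < 60
  vals <- as.vector(f$data)[shell]
  expect_lt(abs(mean(vals)), 0.01 * max(abs(vals)))
})

test_that("cavity fields superpose linearly", {
  c1 <- cavity_spec(c(-20, 0, 0), radius = 8)
  c2 <- cavity_spec(c(25, 5, -10), radius = 6)
  geom <- grid_geometry_for_test(spacing = c(4, 4, 4), fov = c(120, 120, 120))
  f1 <- cavity_dipole_field(c1, geom, 3)$data
  f2 <- cavity_dipole_field(c2, geom, 3)$data
  cfg <- subject_config(seed = 1, cavities = list(c1, c2),
                        background_poly = setNames(rep(0, 10),
                                                   names(default_background_poly())),
                        background_sh_rms_hz = c(0, 0, 0),
                        noise_sd_hz = 0, spacing = c(4, 4, 4),
                        fov = c(120, 120, 120), semiaxes = c(40, 40, 40),
                        mask_margin_mm = 0)
  sub <- generate_subject(cfg)
  expect_equal(sub$field$data, f1 + f2, tolerance = 1e-12)
})

test_that("cavity-induced field mass is concentrated near the cavities", {
  cfg <- subject_config(seed = 1, noise_sd_hz = 0,
                        background_sh_rms_hz = c(0, 0, 0),
                        background_poly = setNames(rep(0, 10),
                                                   names(default_background_poly())))
  sub <- generate_subject(cfg)
  p <- voxel_centers_for_test(sub$field)
  near <- rep(FALSE, nrow(p))
  for (cav in cfg$cavities) {
    d <- sqrt((p[, 1] - cav$center[1])^2 + (p[, 2] - cav$center[2])^2 +
                (p[, 3] - cav$center[3])^2)
    near <- near | d < 3 * cav$radius
  }
  mass <- abs(as.vector(sub$field$data))
  expect_gt(sum(mass[near]) / sum(mass), 0.5)
})

test_that("subject generation is seeded and deterministic", {
  cfg <- coarse_config(seed = 11)
  s1 <- generate_subject(cfg)
  s2 <- generate_subject(cfg)
  expect_identical(s1$field$data, s2$field$data)
  expect_identical(s1$mask$data, s2$mask$data)

  # different seed -> different noise realisation
  s3 <- generate_subject(coarse_config(seed = 12))
  expect_false(identical(s1$field$data, s3$field$data))
})

test_that("a silent configuration produces an identically zero field", {
  cfg <- coarse_config(seed = 1, cavities = list(),
                       background_poly = setNames(rep(0, 10),
                                                  names(default_background_poly())),
                       background_sh_rms_hz = c(0, 0, 0),
                       noise_sd_hz = 0)
  sub <- generate_subject(cfg)
  expect_true(all(sub$field$data == 0))
  expect_equal(masked_stats(sub$field, sub$mask)$sd_hz, 0)
})

test_that("the default subject has a realistic pre-shim whole-brain SD", {
  sub <- generate_subject(subject_config(seed = 1))
  sd_hz <- masked_stats(sub$field, sub$mask)$sd_hz
  expect_gt(sd_hz, 20)
  expect_lt(sd_hz, 80)
})

test_that("ROI boxes are non-empty, inside the mask, and anatomically placed", {
  sub <- generate_subject(subject_config(seed = 3))
  expect_gt(sum(sub$roi_pfc$data), 0)
  expect_gt(sum(sub$roi_mtl$data), 0)
  expect_true(all(sub$mask$data[sub$roi_pfc$data]))
  expect_true(all(sub$mask$data[sub$roi_mtl$data]))
  # PFC anterior (mean y above brain mean), MTL inferior (mean z below)
  p_all <- voxel_centers_for_test(sub$mask, sub$mask$data)
  p_pfc <- voxel_centers_for_test(sub$mask, sub$roi_pfc$data)
  p_mtl <- voxel_centers_for_test(sub$mask, sub$roi_mtl$data)
  expect_gt(mean(p_pfc[, 2]), mean(p_all[, 2]))
  expect_lt(mean(p_mtl[, 3]), mean(p_all[, 3]))
})

test_that("cohort generation is reproducible and respects jitter", {
  base <- coarse_config(seed = 1)
  c1 <- generate_cohort(n = 3, base = base, master_seed = 99)
  c2 <- generate_cohort(n = 3, base = base, master_seed = 99)
  expect_identical(c1[[2]]$field$data, c2[[2]]$field$data)
  expect_identical(vapply(c1, function(s) s$field$subject_id, character(1)),
                   c("S01", "S02", "S03"))
  # subjects are distinct under default jitter
  expect_false(identical(c1[[1]]$field$data, c1[[2]]$field$data))

  # degenerate jitter + no per-subject randomness -> identical subjects
  base0 <- coarse_config(seed = 1, noise_sd_hz = 0,
                         background_sh_rms_hz = c(0, 0, 0))
  zero <- cohort_jitter(0, 0, 0, 0)
  c0 <- generate_cohort(n = 3, base = base0, master_seed = 5, jitter = zero)
  expect_identical(c0[[1]]$field$data, c0[[2]]$field$data)
  expect_identical(c0[[2]]$mask$data, c0[[3]]$mask$data)

  expect_error(generate_cohort(n = 1, base = base), ">= 2")
})

test_that("subjects round-trip through NIfTI + JSON sidecar", {
  dir <- withr::local_tempdir()
  sub <- generate_subject(coarse_config(seed = 4), subject_id = "S99")
  write_subject(sub, dir, prefix = "s99")
  f2 <- read_volume(file.path(dir, "s99_field.nii.gz"), "field")
  m2 <- read_volume(file.path(dir, "s99_mask.nii.gz"), "mask")
  expect_equal(f2$data, sub$field$data, tolerance = 1e-5)
  expect_identical(m2$data, sub$mask$data)
  cfg <- jsonlite::read_json(file.path(dir, "s99_config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$seed, sub$config$seed)
})
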