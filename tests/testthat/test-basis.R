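mu0 <- 4e-7 * pi
gamma_bar <- 42.577e6

test_that("loop field matches the elementary on-axis closed form", {
  lp <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 47.5)
  a <- 0.0475
  center_exact <- mu0 / (2 * a) * gamma_bar           # 563.198 Hz/A
  got <- loop_bz_numeric(lp, matrix(c(0, 0, 0), 1))
  expect_equal(got, center_exact, tolerance = 1e-3)
  expect_equal(got, 563.2, tolerance = 1e-3)
  # on-axis at z = a: factor 2^(-3/2)
  got_z <- loop_bz_numeric(lp, matrix(c(0, 0, 47.5), 1))
  expect_equal(got_z, center_exact / 2^1.5, tolerance = 1e-3)
})

test_that("a two-turn loop doubles the field everywhere", {
  set.seed(42)
  lp1 <- loop_spec(c(10, -5, 30), runit(), radius = 30, turns = 1L)
  lp2 <- loop_spec(lp1$center, lp1$normal, lp1$radius, turns = 2L)
  pts <- points_near_loop(50, lp1$center, 40, 150)
  expect_equal(loop_bz_numeric(lp2, pts), 2 * loop_bz_numeric(lp1, pts),
               tolerance = 1e-14)
})

test_that("the elliptic-integral field reduces to the on-axis formula", {
  lp <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 40)
  z <- c(5, 20, 60, 120)
  pts <- cbind(0, 0, z)
  a <- 0.040
  exact <- mu0 * a^2 / (2 * (a^2 + (z * 1e-3)^2)^1.5) * gamma_bar
  expect_equal(loop_bz_analytic(lp, pts), exact, tolerance = 1e-12)
})

test_that("the loop far field approaches the magnetic dipole limit", {
  lp <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 20)
  a <- 0.020
  # equatorial point at 10 radii: Bz = -mu0 m / (4 pi r^3), m = I pi a^2
  r <- 10 * a
  pt <- matrix(c(200, 0, 0), 1)
  dip <- -mu0 * pi * a^2 / (4 * pi * r^3) * gamma_bar
  expect_equal(loop_bz_analytic(lp, pt), dip, tolerance = 0.02)
})

test_that("polygonal Biot-Savart agrees with the elliptic-integral oracle", {
  set.seed(7)
  for (rep in 1:2) {
    lp <- loop_spec(rnorm(3, sd = 20), runit(), radius = runif(1, 20, 50))
    pts <- points_near_wire(100, lp)
    num <- loop_bz_numeric(lp, pts, n_segments = 512L)
    ana <- loop_bz_analytic(lp, pts)
    # error relative to the field scale, so zero crossings of Bz do not
    # inflate the ratio
    expect_lt(max(abs(num - ana)) / max(abs(ana)), 1e-3)
  }
})

test_that("discretisation error decreases monotonically in segment count", {
  set.seed(3)
  lp <- loop_spec(c(0, 0, 0), runit(), radius = 35)
  pts <- points_near_wire(40, lp, min_wire = 20, r_min = 25, r_max = 120)
  ana <- loop_bz_analytic(lp, pts)
  errs <- vapply(c(16L, 32L, 64L, 128L, 256L), function(ns) {
    max(abs(loop_bz_numeric(lp, pts, n_segments = ns) - ana))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("points on the wire and bad segment counts are rejected", {
  lp <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 30)
  on_wire <- matrix(c(30, 0, 0), 1)
  expect_error(loop_bz_numeric(lp, on_wire), "wire")
  expect_error(loop_bz_analytic(lp, on_wire), "wire")
  expect_error(loop_bz_numeric(lp, matrix(c(0, 0, 50), 1), n_segments = 4L),
               "n_segments")
})

test_that("SH term counts follow 2l + 1 per degree", {
  mask <- tiny_mask(dims = c(6, 6, 6), spacing = c(10, 10, 10))
  b2 <- sh_basis(mask, max_degree = 2)
  expect_identical(ncol(b2$values), 9L)             # 1 + 3 + 5
  b3 <- sh_basis(mask, max_degree = 3)
  expect_identical(ncol(b3$values) - ncol(b2$values), 7L)
  b5 <- sh_basis(mask, max_degree = 5)
  expect_identical(ncol(b5$values), 36L)
  # degree-k columns are a prefix of the degree-(k+1) basis: nested bases
  expect_identical(b3$channel_labels[1:9], b2$channel_labels)
})

test_that("the degree-1 m=0 solid harmonic is the linear z gradient", {
  set.seed(1)
  pts <- matrix(runif(90, -60, 60), ncol = 3)
  raw <- unicshim:::solid_harmonics(pts, 1, center = c(0, 0, 0))
  degs <- attr(raw, "degree"); ords <- attr(raw, "order")
  col_z <- raw[, degs == 1 & ords == 0]
  expect_equal(col_z, pts[, 3] / 100, tolerance = 1e-12)
})

test_that("every solid-harmonic column is numerically harmonic", {
  set.seed(5)
  pts <- matrix(runif(300 * 3, -70, 70), ncol = 3)
  h <- 0.5  # mm; FD step small enough that the h^2 truncation is negligible
  lap <- matrix(0, nrow(pts), 36)
  for (ax in 1:3) {
    for (s in c(-1, 1)) {
      shifted <- pts
      shifted[, ax] <- shifted[, ax] + s * h
      lap <- lap + unicshim:::solid_harmonics(shifted, 5, c(0, 0, 0))
    }
  }
  ctr <- unicshim:::solid_harmonics(pts, 5, c(0, 0, 0))
  lap <- (lap - 6 * ctr) / h^2
  rms <- sqrt(colMeans(ctr^2))
  worst <- apply(abs(lap), 2, max) / rms
  expect_lt(max(worst), 1e-6)
})

test_that("SH columns are near-orthogonal over a spherical mask", {
  cfg <- subject_config(seed = 1, semiaxes = c(50, 50, 50), cavities = list(),
                        spacing = c(4, 4, 4), fov = c(140, 140, 140),
                        mask_margin_mm = 0)
  mask <- make_brain_mask(cfg)
  b <- sh_basis(mask, max_degree = 3)
  g <- crossprod(b$values) / nrow(b$values)
  offdiag <- abs(g - diag(diag(g)))
  expect_lt(max(offdiag) / min(diag(g)), 0.01)
})

test_that("SH normalisation gives unit RMS and rejects degenerate masks", {
  mask <- tiny_mask(dims = c(5, 5, 5), spacing = c(8, 8, 8))
  b <- sh_basis(mask, max_degree = 4)
  expect_equal(unname(sqrt(colMeans(b$values^2))), rep(1, 25),
               tolerance = 1e-12)
  one <- brain_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)), c(1, 1, 1))
  expect_error(sh_basis(one, max_degree = 2, center = c(0, 0, 0)),
               "degenerate")
})

test_that("coil basis assembly yields one finite column per channel", {
  cfg <- coarse_config(seed = 2)
  sub <- generate_subject(cfg)
  lay <- layout_unic51()
  bas <- assemble_coil_basis(lay, sub$mask, n_segments = 64L)
  expect_identical(ncol(bas$values), 51L)
  expect_identical(nrow(bas$values), sum(sub$mask$data))
  expect_true(all(is.finite(bas$values)))
  expect_identical(bas$channel_labels[1], "large01")
  # superposition: matrix product equals the summed per-loop fields
  cvec <- rnorm(51)
  pts <- voxel_centers_for_test(sub$mask, sub$mask$data)
  direct <- 0
  for (j in c(1, 30, 45)) direct <- direct +
    cvec[j] * loop_bz_numeric(lay$loops[[j]], pts, n_segments = 64L)
  via_mat <- drop(bas$values[, c(1, 30, 45)] %*% cvec[c(1, 30, 45)])
  expect_equal(via_mat, direct, tolerance = 1e-10)
})

test_that("far-field column scale follows the dipole-moment area law", {
  pts <- matrix(c(0, 0, 400, 0, 300, 300), ncol = 3, byrow = TRUE)
  lp1 <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 10)
  lp2 <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 20)
  v1 <- loop_bz_numeric(lp1, pts)
  v2 <- loop_bz_numeric(lp2, pts)
  expect_equal(v2 / v1, c(4, 4), tolerance = 0.05)
})

test_that("a loop threading the mask volume is a geometry error", {
  mask <- tiny_mask(dims = c(10, 10, 10), spacing = c(4, 4, 4))
  inside <- loop_spec(c(18, 18, 18), c(0, 0, 1), radius = 10,
                      label = "bad")
  lay <- coil_layout("bad", list(inside))
  expect_error(assemble_coil_basis(lay, mask), "intersects")
})
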