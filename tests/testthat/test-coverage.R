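test_that("block partition reproduces the 125-pixel MRSI voxel", {
  g <- block_partition(c(2.4, 2.4, 2), c(12, 12, 10))
  expect_identical(g$block_dims, c(5L, 5L, 5L))
  expect_equal(prod(g$block_dims), 125)
  expect_equal(g$realized_cc, 1.44, tolerance = 1e-12)

  # high-resolution voxel: nearest-integer blocks, 0.092 cc realised
  g2 <- block_partition(c(2.4, 2.4, 2), c(4.5, 4.5, 4.5))
  expect_identical(g2$block_dims, c(2L, 2L, 2L))
  expect_equal(g2$realized_cc, 0.09216, tolerance = 1e-9)

  # requested voxel smaller than one pixel floors at one (and warns about
  # the large realised-volume deviation)
  expect_warning(g3 <- block_partition(c(2.4, 2.4, 2), c(1, 1, 1)), "15%")
  expect_identical(g3$block_dims, c(1L, 1L, 1L))

  # large realised-volume deviation warns but proceeds
  expect_warning(block_partition(c(2.4, 2.4, 2), c(4, 4, 4)), "15%")
})

test_that("voxel linewidth is the baseline plus the population SD", {
  m <- linewidth_model()
  expect_equal(voxel_linewidth(rep(5, 125), m), 9)
  expect_equal(voxel_linewidth(rep(c(6, -6), 10), m), 15)
  # SD exactly 9 Hz sits exactly at the 18 Hz cutoff
  expect_equal(voxel_linewidth(rep(c(9, -9), 10), m), 18)
  expect_error(voxel_linewidth(numeric(0), m), "empty")
  expect_error(linewidth_model(baseline_hz = 10, threshold_hz = 9),
               "exceed")
})

test_that("coverage counts usable brain voxels with a strict threshold", {
  # 10 x 5 x 5 grid of 2.4 x 2.4 x 2 mm pixels -> two 5x5x5 blocks
  dims <- c(10, 5, 5)
  mk <- brain_mask(array(TRUE, dims), spacing = c(2.4, 2.4, 2))
  v <- array(0, dims)
  v[1:5, , ] <- rep(c(5, -5), length.out = 125)    # SD 5 -> usable
  v[6:10, , ] <- rep(c(12, -12), length.out = 125) # SD 12 -> not usable
  fm <- field_map(v, spacing = c(2.4, 2.4, 2))
  cov <- compute_coverage(fm, mk, block_partition(c(2.4, 2.4, 2)))
  expect_identical(cov$n_brain_voxels, 2L)
  expect_identical(cov$n_usable, 1L)
  expect_equal(cov$coverage_pct, 50)
  # consistency identity
  expect_identical(sum(cov$blocks$is_brain & !cov$blocks$usable) +
                     cov$n_usable, cov$n_brain_voxels)

  # constant field: everything usable
  cov1 <- compute_coverage(field_map(array(3, dims), c(2.4, 2.4, 2)), mk,
                           block_partition(c(2.4, 2.4, 2)))
  expect_equal(cov1$coverage_pct, 100)

  # block SD exactly 9 -> linewidth exactly 18 -> NOT usable (strict <).
  # 124 in-mask pixels per block split evenly between +9 and -9 give a
  # population SD of exactly 9.
  block_vals <- array(c(0, rep(c(9, -9), 62)), c(5, 5, 5))
  v9 <- array(0, dims)
  v9[1:5, , ] <- block_vals
  v9[6:10, , ] <- block_vals
  m9 <- array(TRUE, dims)
  m9[1, 1, 1] <- FALSE   # first pixel of each block carries the odd zero
  m9[6, 1, 1] <- FALSE
  mk9 <- brain_mask(m9, c(2.4, 2.4, 2))
  cov9 <- compute_coverage(field_map(v9, c(2.4, 2.4, 2)), mk9,
                           block_partition(c(2.4, 2.4, 2)))
  expect_identical(cov9$blocks$n_inmask, c(124L, 124L))
  expect_equal(cov9$blocks$sd_hz, c(9, 9))
  expect_equal(cov9$blocks$linewidth_hz, c(18, 18))
  expect_equal(cov9$coverage_pct, 0)
})

test_that("coverage is invariant to a global frequency offset", {
  set.seed(8)
  dims <- c(15, 10, 10)
  mk <- brain_mask(array(runif(prod(dims)) > 0.2, dims), c(2.4, 2.4, 2))
  v <- array(rnorm(prod(dims), sd = 6), dims)
  g <- block_partition(c(2.4, 2.4, 2))
  c1 <- compute_coverage(field_map(v, c(2.4, 2.4, 2)), mk, g)
  c2 <- compute_coverage(field_map(v + 250, c(2.4, 2.4, 2)), mk, g)
  expect_equal(c1$coverage_pct, c2$coverage_pct)
  expect_equal(c1$blocks$sd_hz, c2$blocks$sd_hz, tolerance = 1e-9)
})

test_that("coverage never increases when the threshold tightens", {
  set.seed(9)
  dims <- c(20, 10, 10)
  mk <- brain_mask(array(TRUE, dims), c(2.4, 2.4, 2))
  v <- array(rnorm(prod(dims), sd = 8), dims)
  fm <- field_map(v, c(2.4, 2.4, 2))
  g <- block_partition(c(2.4, 2.4, 2))
  covs <- vapply(c(24, 18, 14, 11), function(th) {
    compute_coverage(fm, mk, g, linewidth_model(9, th))$coverage_pct
  }, numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("a block is brain only if most of its pixels are in-mask", {
  dims <- c(5, 5, 5)  # one block
  g <- block_partition(c(2.4, 2.4, 2))
  fm <- field_map(array(0, dims), c(2.4, 2.4, 2))
  m_in <- array(FALSE, dims); m_in[1:3, , ] <- TRUE    # 75 / 125 pixels
  cov <- compute_coverage(fm, brain_mask(m_in, c(2.4, 2.4, 2)), g)
  expect_identical(cov$n_brain_voxels, 1L)
  m_out <- array(FALSE, dims); m_out[1:2, , ] <- TRUE  # 50 / 125 pixels
  expect_error(compute_coverage(fm, brain_mask(m_out, c(2.4, 2.4, 2)), g),
               "no brain voxels")
})

test_that("trailing partial blocks obey the same majority rule", {
  dims <- c(7, 5, 5)  # one full block + a 2 x 5 x 5 partial block
  mk <- brain_mask(array(TRUE, dims), c(2.4, 2.4, 2))
  fm <- field_map(array(0, dims), c(2.4, 2.4, 2))
  cov <- compute_coverage(fm, mk, block_partition(c(2.4, 2.4, 2)))
  expect_identical(cov$n_brain_voxels, 2L)
  expect_identical(cov$blocks$n_pixels, c(125L, 50L))
})

test_that("region coverage restricts to ROI-majority brain voxels", {
  dims <- c(10, 5, 5)
  mk <- brain_mask(array(TRUE, dims), c(2.4, 2.4, 2))
  v <- array(0, dims)
  v[1:5, , ] <- rep(c(5, -5), length.out = 125)
  v[6:10, , ] <- rep(c(12, -12), length.out = 125)
  fm <- field_map(v, c(2.4, 2.4, 2))
  cov <- compute_coverage(fm, mk, block_partition(c(2.4, 2.4, 2)))

  # ROI = whole mask reproduces whole-brain coverage
  expect_equal(region_coverage(cov, mk), cov$coverage_pct)

  # ROI over the usable half only
  roi1 <- array(FALSE, dims); roi1[1:5, , ] <- TRUE
  expect_equal(region_coverage(cov, brain_mask(roi1, c(2.4, 2.4, 2))), 100)

  # ROI over the unusable half
  roi2 <- array(FALSE, dims); roi2[6:10, , ] <- TRUE
  expect_equal(region_coverage(cov, brain_mask(roi2, c(2.4, 2.4, 2))), 0)

  # ROI that misses the brain entirely
  expect_error(region_coverage(cov, brain_mask(array(FALSE, dims),
                                               c(2.4, 2.4, 2))),
               "no brain voxels")
})

test_that("the frontal ROI is harder to cover than the whole brain", {
  sub <- generate_subject(subject_config(seed = 1))
  cov <- compute_coverage(sub$field, sub$mask,
                          block_partition(sub$mask$spacing),
                          rois = list(pfc = sub$roi_pfc))
  pfc <- cov$roi_coverage$coverage_pct[cov$roi_coverage$roi == "pfc"]
  expect_lt(pfc, cov$coverage_pct)
})

test_that("coverage tidiers expose per-voxel rows and the summary", {
  dims <- c(5, 5, 5)
  mk <- brain_mask(array(TRUE, dims), c(2.4, 2.4, 2))
  fm <- field_map(array(1, dims), c(2.4, 2.4, 2))
  cov <- compute_coverage(fm, mk, block_partition(c(2.4, 2.4, 2)))
  expect_s3_class(tidy(cov), "tbl_df")
  gl <- glance(cov)
  expect_equal(gl$coverage_pct, 100)
  expect_equal(gl$voxel_cc, 1.44)
})
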