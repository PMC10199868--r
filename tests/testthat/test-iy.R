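test_that("region means are probability-weighted and match a loop oracle", {
  atlas <- half_space_atlas(8L)
  pm <- make_probability_maps(atlas)
  const <- volume_image(array(5, c(8, 8, 8)))
  expect_equal(unname(region_means(const, pm)), c(5, 5))

  halves <- array(1, c(8, 8, 8)); halves[5:8, , ] <- 3
  expect_equal(unname(region_means(volume_image(halves), pm)), c(1, 3))

  # random image, 3 binary regions: equals per-label arithmetic means
  set.seed(4)
  lab <- array(sample.int(3, 512, replace = TRUE), c(8, 8, 8))
  atl3 <- label_atlas(lab, c("a", "b", "c"))
  pm3 <- make_probability_maps(atl3)
  img <- rand_volume(8, seed = 8)
  got <- region_means(img, pm3)
  want <- vapply(1:3, function(j) mean(img$values[lab == j]), numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-12)

  # soft overlapping maps: weighted-mean oracle
  m1 <- array(runif(512, 0, 0.6), c(8, 8, 8))
  m2 <- array(runif(512, 0, 0.4), c(8, 8, 8))
  pms <- probability_maps(list(m1, m2), c("r1", "r2"))
  gm <- region_means(img, pms)
  expect_equal(gm[["r1"]], sum(img$values * m1) / sum(m1), tolerance = 1e-12)
  expect_equal(gm[["r2"]], sum(img$values * m2) / sum(m2), tolerance = 1e-12)
})

test_that("artificial_image is the weighted sum of means over maps", {
  atlas <- half_space_atlas(8L)
  pm <- make_probability_maps(atlas)
  fa <- artificial_image(c(2, 7), pm)
  expect_equal(unique(as.vector(fa[1:4, , ])), 2)
  expect_equal(unique(as.vector(fa[5:8, , ])), 7)
  # soft maps: explicit per-voxel weighted sum
  set.seed(2)
  m1 <- array(runif(512, 0, 0.5), c(8, 8, 8))
  m2 <- array(runif(512, 0, 0.5), c(8, 8, 8))
  pms <- probability_maps(list(m1, m2), c("r1", "r2"))
  expect_equal(artificial_image(c(1.5, -2), pms), 1.5 * m1 - 2 * m2,
               tolerance = 1e-14)
  expect_error(artificial_image(c(1, 2, 3), pm), "match")
})

test_that("one IY step matches the straight-line scalar oracle", {
  atlas <- half_space_atlas(8L)
  pm <- make_probability_maps(atlas)
  set.seed(31)
  truth <- array(1, c(8, 8, 8)); truth[5:8, , ] <- 4
  f <- volume_image(truth + array(runif(512, 0, 0.1), c(8, 8, 8)),
                    spacing = c(2, 2, 2))
  cfg <- iy_config(psf = psf_model(3.0))
  got <- iy_step(f, f, pm, cfg)$values
  want <- oracle_iy_step(f$values, f$values, pm$maps, cfg$psf$fwhm_mm,
                         f$spacing, cfg$ratio_epsilon,
                         cfg$psf$truncation_radius)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("IY is the identity for a delta PSF and for blur-invariant inputs", {
  atlas <- half_space_atlas(8L)
  pm <- make_probability_maps(atlas)
  f <- rand_volume(8, lo = 1, hi = 2, seed = 13)
  out <- iy_correct(f, pm, iy_config(psf = psf_delta(), iterations = 7))
  expect_identical(out$values, f$values)

  # single whole-grid region, constant image: constant f_a is blur-invariant
  whole <- label_atlas(array(1L, c(8, 8, 8)), "all")
  pmw <- make_probability_maps(whole)
  cf <- volume_image(array(2.5, c(8, 8, 8)))
  out2 <- iy_step(cf, cf, pmw, iy_config())
  expect_equal(out2$values, cf$values, tolerance = 1e-12)
})

test_that("IY recovers a blurred piecewise-constant phantom monotonically", {
  fx <- noiseless_phantom(seed = 42)
  cfg <- iy_config(record_trajectory = TRUE)
  out <- iy_correct(fx$blurred, fx$probmaps, cfg)
  traj <- attr(out, "trajectory")
  expect_length(traj, cfg$iterations + 1L)
  errs <- vapply(traj, function(e) rmse(e, fx$truth), numeric(1))
  expect_true(all(diff(errs) < 0))              # strict decrease 0 -> 10
  expect_lt(errs[11], 0.5 * errs[1])            # > 50% RMSE reduction
  expect_true(min(out$values) >= 0)             # non-negativity

  # region-mean consistency for a single whole-brain region
  whole <- label_atlas(array(1L, dim(fx$blurred$values)), "brain")
  pmw <- make_probability_maps(whole)
  outw <- iy_correct(fx$blurred, pmw, iy_config())
  m_in <- region_means(fx$blurred, pmw)[[1]]
  m_out <- region_means(outw, pmw)[[1]]
  expect_lt(abs(m_out - m_in) / m_in, 0.005)
})

test_that("IY defaults follow the standard clinical recipe", {
  cfg <- iy_config()
  expect_equal(cfg$iterations, 10L)
  expect_equal(cfg$psf$fwhm_mm, c(3, 3, 3))
  expect_error(iy_config(iterations = 0), ">= 1")
  expect_error(iy_config(ratio_epsilon = 0), "positive")
})
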