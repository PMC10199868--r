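test_that("FWHM/sigma conversion is the Gaussian closed form and round-trips", {
  expect_equal(fwhm_to_sigma(2.3548200450309493), 1.0, tolerance = 1e-12)
  expect_equal(fwhm_to_sigma(3.0), 3.0 / (2 * sqrt(2 * log(2))),
               tolerance = 1e-14)
  expect_equal(sigma_to_fwhm(fwhm_to_sigma(1.7)), 1.7, tolerance = 1e-12)
  expect_error(fwhm_to_sigma(0), "positive")
  expect_error(fwhm_to_sigma(-2), "positive")
})

test_that("gaussian_blur preserves constants exactly and is identity for delta PSF", {
  img <- volume_image(array(5, c(12, 12, 12)), spacing = c(2, 2, 2))
  out <- gaussian_blur(img, psf_model(6.0))
  expect_equal(out$values, img$values)   # replication boundary + unit kernel
  rnd <- rand_volume(10, seed = 1)
  expect_identical(gaussian_blur(rnd, psf_delta())$values, rnd$values)
})

test_that("separable blur equals dense 3D-kernel convolution", {
  set.seed(11)
  img <- rand_volume(16, spacing = c(1, 1, 1))
  psf <- psf_model(c(2.0, 3.0, 2.5))
  got <- gaussian_blur(img, psf)$values
  sigma_vox <- psf$fwhm_mm / (2 * sqrt(2 * log(2)))
  want <- oracle_dense_blur(img$values, sigma_vox, psf$truncation_radius)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("blurred impulse centre matches the normalized discrete Gaussian", {
  d <- c(33L, 33L, 33L)
  a <- array(0, d); a[17, 17, 17] <- 1
  img <- volume_image(a, spacing = c(1, 1, 1))
  got <- gaussian_blur(img, psf_model(2.3548200450309493))$values
  # independent 1D taps: sigma = 1 voxel, radius 4 sigmas
  offs <- -4:4
  w <- exp(-offs^2 / 2); w <- w / sum(w)
  expect_equal(got[17, 17, 17], w[5]^3, tolerance = 1e-12)
  expect_equal(got[18, 17, 17], w[6] * w[5]^2, tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-3)  # interior mass conserved
})

test_that("make_atlas builds the documented region layout deterministically", {
  spec <- phantom_spec(shape = c(48, 48, 48), n_sectors = 8, seed = 3)
  atlas <- make_atlas(spec)
  expect_equal(length(atlas$region_names), 12L)  # 8 sectors + WM + 2 deep + CSF
  counts <- tabulate(atlas$labels, 12L)
  expect_true(all(counts > 0L))
  expect_identical(atlas$labels, make_atlas(spec)$labels)
  expect_error(make_atlas(phantom_spec(shape = c(32, 32, 32),
                                       n_sectors = 10000)),
               "empty")
})

test_that("probability maps are binary indicators or smoothed partitions", {
  atlas <- half_space_atlas(8L)
  pm <- make_probability_maps(atlas)
  expect_true(pm$binary)
  expect_equal(pm$maps[[1]][2, 3, 4], 1)
  expect_equal(pm$maps[[2]][2, 3, 4], 0)
  tot <- Reduce(`+`, pm$maps)
  expect_true(max(tot) <= 1 + 1e-6)

  # smoothing a two-region half-space: symmetry pins the interface at 0.5
  atl2 <- half_space_atlas(16L)
  pm2 <- make_probability_maps(atl2, smoothing_fwhm_mm = 2,
                               spacing_mm = c(1, 1, 1))
  expect_false(pm2$binary)
  boundary_vals <- c(pm2$maps[[1]][8, 8, 8], pm2$maps[[1]][9, 8, 8])
  expect_equal(mean(boundary_vals), 0.5, tolerance = 0.01)
  tot2 <- Reduce(`+`, pm2$maps)
  expect_true(max(tot2) <= 1 + 1e-6)
  expect_equal(max(abs(tot2[atl2$labels > 0] - 1)), 0, tolerance = 1e-9)
})

test_that("assign_activities draws per-class ranges reproducibly", {
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 9)
  atlas <- make_atlas(spec)
  t1 <- assign_activities(atlas, spec)
  t2 <- assign_activities(atlas, spec)
  expect_identical(t1$values, t2$values)
  acts <- attr(t1, "region_activities")
  cls <- pvcbrain:::region_classes(atlas$region_names)
  # fdg-like: disjoint cortex (8-10) vs white (2-2.5) ranges
  expect_true(all(acts[cls == "cortex"] > max(acts[cls == "white"])))
  rng <- spec$activity_ranges
  for (k in unique(cls))
    expect_true(all(acts[cls == k] >= rng[[k]][1] &
                    acts[cls == k] <= rng[[k]][2]))
  # degenerate ranges give exactly piecewise-constant known values
  spec2 <- phantom_spec(shape = c(48, 48, 48), activity_ranges =
    list(cortex = c(4, 4), white = c(1, 1), deep = c(3, 3), csf = c(0.5, 0.5)))
  t3 <- assign_activities(make_atlas(spec2), spec2)
  expect_setequal(unique(as.vector(t3$values)), c(0, 4, 1, 3, 0.5))
  expect_error(phantom_spec(profile = "nope"), "valid profiles")
})

test_that("simulate_pet composes blur and mean-preserving pseudo-Poisson noise", {
  truth <- rand_volume(12, lo = 1, hi = 3, seed = 5)
  expect_identical(simulate_pet(truth, psf_delta(), 0)$values, truth$values)
  psf <- psf_model(4.0)
  expect_equal(simulate_pet(truth, psf, 0)$values,
               gaussian_blur(truth, psf)$values)
  # constant 100 image, delta PSF: sample mean within 3 SE of 100
  const <- volume_image(array(100, c(12, 12, 12)))
  noisy <- simulate_pet(const, psf_delta(), 0.05, seed = 2)
  se <- 0.05 * sqrt(100) / sqrt(length(const$values))
  expect_lt(abs(mean(noisy$values) - 100), 3 * se)
  expect_error(simulate_pet(truth, psf, -1), "non-negative")
})

test_that("make_dataset yields reproducible pairs with IY closer to truth", {
  spec <- phantom_spec(shape = c(32, 32, 32), n_sectors = 4,
                       noise_level = 0.02, psf = psf_model(6.0), seed = 21)
  ds1 <- make_dataset(3, spec, iy_config())
  ds2 <- make_dataset(3, spec, iy_config())
  for (i in 1:3) {
    expect_identical(ds1[[i]]$nonpvc$values, ds2[[i]]$nonpvc$values)
    expect_identical(ds1[[i]]$reference_pvc$values,
                     ds2[[i]]$reference_pvc$values)
    expect_gt(rmse(ds1[[i]]$nonpvc, ds1[[i]]$truth), 0)
    expect_lt(rmse(ds1[[i]]$reference_pvc, ds1[[i]]$truth),
              rmse(ds1[[i]]$nonpvc, ds1[[i]]$truth))
  }
  # distinct samples differ
  expect_gt(rmse(ds1[[1]]$truth, ds1[[2]]$truth), 0)
})
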