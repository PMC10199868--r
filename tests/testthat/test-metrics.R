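test_that("RMSE/PSNR closed forms hold", {
  a <- volume_image(array(1, c(8, 8, 8)))
  expect_equal(rmse(a, a), 0)
  # two-voxel hand case embedded in a flat background
  x <- array(0, c(8, 8, 8)); y <- array(0, c(8, 8, 8))
  y[1, 1, 1] <- 3; y[2, 1, 1] <- 4
  m <- array(FALSE, c(8, 8, 8)); m[1:2, 1, 1] <- TRUE
  expect_equal(rmse(x, y, mask = m), sqrt(12.5))
  set.seed(20)
  ra <- rand_volume(8, seed = 20); rb <- rand_volume(8, seed = 21)
  expect_equal(rmse(ra, rb), sqrt(mean((ra$values - rb$values)^2)))

  # PSNR: data_range 1, MSE 0.01 -> 20 dB
  b <- volume_image(array(1 + 0.1, c(8, 8, 8)))
  expect_equal(psnr(a, b, data_range = 1), 20, tolerance = 1e-10)
  expect_true(is.infinite(psnr(a, a)))
  c255 <- volume_image(array(255, c(8, 8, 8)))
  z <- volume_image(array(0, c(8, 8, 8)) + 1e-12)
  expect_equal(psnr(c255, z, data_range = 255), 0, tolerance = 1e-6)
})

test_that("SSIM is 1 on identity, symmetric, and matches a windowed oracle", {
  x <- rand_volume(12, seed = 30)
  expect_equal(ssim(x, x), 1)
  shifted <- with_values(x, x$values + 5)
  expect_lt(ssim(x, shifted, data_range = 1), 1)
  y <- rand_volume(12, seed = 31)
  expect_equal(ssim(x, y, data_range = 1), ssim(y, x, data_range = 1),
               tolerance = 1e-9)
  got <- ssim(x, y, data_range = 1)
  want <- oracle_ssim(x$values, y$values, data_range = 1)
  expect_equal(got, want, tolerance = 1e-6)
  expect_error(ssim(rand_volume(8), rand_volume(8)), "window")
})

test_that("joint histogram conserves counts and localizes structure", {
  x <- rand_volume(8, seed = 40)
  h <- joint_histogram(x, x, bins = 16, range = c(0, 1))
  expect_equal(sum(h), 512L)
  expect_equal(sum(diag(h)), 512L)  # identical images: diagonal only
  # constant shift of exactly one bin width lands on the first off-diagonal
  shift <- with_values(x, x$values + 2 / 32)
  h2 <- joint_histogram(x, shift, bins = 32, range = c(0, 2))
  expect_equal(sum(h2[cbind(1:31, 2:32)]), 512L)
  expect_error(joint_histogram(x, x, bins = 1), ">= 2")
})

test_that("Bland-Altman limits follow mean +/- 1.96 sample SD", {
  r <- bland_altman(c(1, 2, 3), c(1.1, 1.9, 3.0))
  expect_equal(r$mean_bias, 0, tolerance = 1e-12)
  expect_equal(r$sd_diff, 0.1, tolerance = 1e-12)
  expect_equal(r$loa_low, -0.196, tolerance = 1e-12)
  expect_equal(r$loa_high, 0.196, tolerance = 1e-12)
  same <- bland_altman(1:5, 1:5)
  expect_equal(c(same$mean_bias, same$loa_low, same$loa_high), c(0, 0, 0))
  off <- bland_altman(1:5, 1:5 + 0.02)
  expect_equal(off$mean_bias, 0.02)
  expect_equal(off$sd_diff, 0)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman recovers an injected bias at realistic region counts", {
  # 83 region pairs, bias 0.02 SUV, SD 0.15, 200 Monte-Carlo reps
  set.seed(77)
  n <- 83L; bias <- 0.02; s <- 0.15; reps <- 200L
  biases <- widths <- numeric(reps)
  for (r in seq_len(reps)) {
    ref <- runif(n, 1, 8)
    pred <- ref + bias + rnorm(n, 0, s)
    ba <- bland_altman(ref, pred)
    biases[r] <- ba$mean_bias
    widths[r] <- ba$loa_high - ba$loa_low
  }
  se <- s / sqrt(n)
  expect_lt(abs(mean(biases) - bias), 3 * se / sqrt(reps))
  expect_lt(abs(mean(widths) - 2 * 1.96 * s) / (2 * 1.96 * s), 0.15)
})

test_that("region SUV table reports exact per-label means and regression", {
  fx <- noiseless_phantom(seed = 14, shape = c(32, 32, 32))
  ref <- fx$truth
  r1 <- region_suv_table(ref, ref, fx$atlas)
  expect_equal(r1$fit$slope, 1, tolerance = 1e-9)
  expect_equal(r1$fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(r1$fit$rmse, 0, tolerance = 1e-12)
  doubled <- with_values(ref, 2 * ref$values)
  r2 <- region_suv_table(ref, doubled, fx$atlas)
  expect_equal(r2$fit$slope, 2, tolerance = 1e-9)
  # per-label loop oracle
  for (j in seq_along(fx$atlas$region_names)) {
    want <- mean(ref$values[fx$atlas$labels == j])
    expect_equal(r1$table$ref_mean[j], want, tolerance = 1e-12)
  }
})

test_that("metric_report aggregates mean and SD per metric", {
  refs <- list(rand_volume(12, seed = 1), rand_volume(12, seed = 2))
  preds <- lapply(refs, function(v) with_values(v, v$values + 0.01))
  rep <- metric_report(refs, preds)
  expect_equal(nrow(rep$per_pair), 2L)
  expect_equal(unname(rep$mean["rmse"]), 0.01, tolerance = 1e-9)
  expect_true(all(is.finite(rep$per_pair$psnr_db)))
})
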