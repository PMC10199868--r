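test_that("t statistics match a per-voxel loop oracle", {
  set.seed(12)
  ga <- lapply(1:4, function(i) rand_volume(8, seed = 100 + i))
  gb <- lapply(1:5, function(i) rand_volume(8, seed = 200 + i))
  res <- voxelwise_ttest(ga, gb, correction = "none", alpha = 0.05)
  want <- oracle_ttest_map(lapply(ga, `[[`, "values"),
                           lapply(gb, `[[`, "values"))
  expect_lt(max(abs(res$t_map - want)), 1e-10)
  expect_equal(res$df, 7)
})

test_that("duplicated groups give no significant voxels", {
  ga <- lapply(1:3, function(i) rand_volume(8, seed = i))
  res <- voxelwise_ttest(ga, ga, alpha = 0.05)
  expect_equal(sum(res$sig_over), 0L)
  expect_equal(sum(res$sig_under), 0L)
  expect_equal(max(abs(res$t_map)), 0)  # zero-variance voxels -> t = 0
})

test_that("a constructed block effect is detected with the right sign", {
  set.seed(33)
  d <- c(12, 12, 12)
  block <- array(FALSE, d); block[4:9, 4:9, 4:9] <- TRUE
  base <- array(10, d)
  make_group <- function(n, offset) {
    lapply(seq_len(n), function(i) {
      v <- base + rnorm(prod(d), 0, 0.05)
      v[block] <- v[block] + offset
      volume_image(array(v, d))
    })
  }
  ga <- make_group(10, 2)   # elevated inside the block
  gb <- make_group(10, 0)
  res <- voxelwise_ttest(ga, gb, alpha = 0.05)
  expect_true(all(res$sig_over[block]))       # whole block flagged
  expect_false(any(res$sig_under[block]))
  expect_lt(sum(res$sig_over[!block]), 5)     # essentially nothing outside
  expect_equal(res$summary$n_voxels[res$summary$direction ==
                                    "overestimation"], sum(res$sig_over))
  expect_true(res$summary$mean_t[1] > 0)
})

test_that("Bonferroni controls the family-wise error rate under the null", {
  # both groups from one phantom-noise distribution; 100 Monte-Carlo reps
  set.seed(2024)
  d <- c(22, 22, 22)                 # ~10^4 masked voxels
  mask <- array(TRUE, d)
  n_rep <- 100L
  any_sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    ga <- lapply(1:10, function(i) volume_image(array(rnorm(prod(d), 5, 0.3), d)))
    gb <- lapply(1:10, function(i) volume_image(array(rnorm(prod(d), 5, 0.3), d)))
    res <- voxelwise_ttest(ga, gb, mask = mask, alpha = 0.05)
    any_sig[r] <- (sum(res$sig_over) + sum(res$sig_under)) > 0
  }
  expect_lte(mean(any_sig), 0.07)
})

test_that("paired variant reduces to the classical paired t-test", {
  set.seed(91)
  ga <- lapply(1:6, function(i) rand_volume(8, seed = 300 + i))
  gb <- lapply(1:6, function(i) rand_volume(8, seed = 400 + i))
  res <- voxelwise_ttest(ga, gb, paired = TRUE, correction = "none")
  v <- c(3, 4, 5)
  xa <- sapply(ga, function(g) g$values[v[1], v[2], v[3]])
  xb <- sapply(gb, function(g) g$values[v[1], v[2], v[3]])
  want <- t.test(xa, xb, paired = TRUE)$statistic
  expect_equal(res$t_map[v[1], v[2], v[3]], unname(want), tolerance = 1e-10)
  expect_equal(res$df, 5)
})
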