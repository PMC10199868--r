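test_that("fixed-bin-number discretization maps ranges to levels 1..n", {
  d <- discretize(0:63, 64L)
  expect_identical(d$levels, 1:64)
  expect_false(d$degenerate)
  dc <- discretize(rep(2, 10), 64L)
  expect_true(dc$degenerate)
  expect_identical(unique(dc$levels), 1L)
  set.seed(1)
  dr <- discretize(runif(100), 64L)
  expect_equal(sum(tabulate(dr$levels, 64L)), 100L)
  expect_true(all(dr$levels >= 1L & dr$levels <= 64L))
})

test_that("conventional indices follow their closed forms", {
  img <- volume_image(array(2, c(10, 10, 10)), spacing = c(1, 1, 1))
  mask <- array(TRUE, c(10, 10, 10))
  f <- radiomics_features(img, mask)
  expect_equal(unname(f["suv_mean"]), 2)
  expect_equal(unname(f["suv_max"]), 2)
  expect_equal(unname(f["suv_std"]), 0)
  expect_equal(unname(f["tlg_ml"]), 2 * 1000 / 1000)  # mean x volume(mL)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["entropy_log2"]), 0)
  expect_equal(unname(f["entropy_log10"]), 0)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_dissimilarity"]), 0)
  expect_true(is.na(f["kurtosis"]))
  expect_true(attr(f, "degenerate"))

  # {1,1,2,2} pattern: median 1.5, two occupied bins -> uniformity 0.5
  vals2 <- array(0, c(8, 8, 8))
  vals2[1:2, 1:2, 1:2] <- rep(c(1, 1, 2, 2), 2)   # 4 ones, 4 twos
  img2 <- volume_image(vals2)
  mask2 <- array(FALSE, c(8, 8, 8)); mask2[1:2, 1:2, 1:2] <- TRUE
  f2 <- radiomics_features(img2, mask2)
  expect_equal(unname(f2["suv_q2"]), 1.5)
  expect_equal(unname(f2["uniformity"]), 0.5)
})

test_that("texture features equal brute-force enumeration on a 50-case battery", {
  set.seed(99)
  for (case in 1:50) {
    side <- sample(3:4, 1)
    n_bins <- sample(4:8, 1)
    p_in <- sample(c(1, 1, 0.8), 1)        # mix of full and partial masks
    lev <- rand_level_region(side, n_bins, p_in)
    got_glcm <- pvcbrain:::glcm_features(lev, n_bins)
    want_glcm <- oracle_glcm(lev, n_bins)
    expect_equal(unname(got_glcm["glcm_homogeneity"]),
                 unname(want_glcm["homogeneity"]), tolerance = 1e-12)
    expect_equal(unname(got_glcm["glcm_energy"]),
                 unname(want_glcm["energy"]), tolerance = 1e-12)
    expect_equal(unname(got_glcm["glcm_dissimilarity"]),
                 unname(want_glcm["dissimilarity"]), tolerance = 1e-12)
    expect_equal(pvcbrain:::glrlm_run_percentage(lev),
                 oracle_run_percentage(lev), tolerance = 1e-12)
    expect_equal(pvcbrain:::ngldm_contrast(lev, n_bins),
                 oracle_ngldm_contrast(lev, n_bins), tolerance = 1e-12)
    got_z <- pvcbrain:::glzlm_features(lev)
    want_z <- oracle_glzlm(lev)
    expect_equal(unname(got_z), unname(want_z), tolerance = 1e-12)
  }
})

test_that("histogram features and AUC-CSH match direct computation", {
  set.seed(55)
  img <- volume_image(array(runif(1000, 1, 5), c(10, 10, 10)))
  mask <- array(TRUE, c(10, 10, 10))
  f <- radiomics_features(img, mask, radiomics_settings(n_bins = 16))
  vals <- img$values[mask]
  lv <- pmin(floor((vals - min(vals)) / (max(vals) - min(vals)) * 16) + 1, 16)
  p <- as.vector(table(lv)) / 1000
  expect_equal(unname(f["uniformity"]), sum(p^2), tolerance = 1e-12)
  expect_equal(unname(f["entropy_log2"]), -sum(p * log2(p)), tolerance = 1e-12)
  expect_equal(unname(f["entropy_log10"]), -sum(p * log10(p)),
               tolerance = 1e-12)
  mu <- mean(vals); s2 <- mean((vals - mu)^2)
  expect_equal(unname(f["kurtosis"]), mean((vals - mu)^4) / s2^2,
               tolerance = 1e-12)
  # AUC-CSH of a uniform distribution: fraction >= t falls linearly -> ~0.5
  expect_equal(unname(f["auc_csh"]), 0.5, tolerance = 0.05)
  q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(unname(f[c("suv_q1", "suv_q2", "suv_q3")]), q)
})

test_that("GLCM features are invariant to axis permutation", {
  set.seed(7)
  lev <- rand_level_region(4, 5, 1)
  base <- pvcbrain:::glcm_features(lev, 5)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    got <- pvcbrain:::glcm_features(aperm(lev, perm), 5)
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("radiomics tables and relative-error heat maps behave", {
  fx <- noiseless_phantom(seed = 8, shape = c(32, 32, 32))
  img <- fx$truth
  noisy <- with_values(img, img$values * 1.1)
  rt <- radiomics_table(img, fx$atlas, radiomics_settings(n_bins = 16))
  expect_equal(nrow(rt), length(fx$atlas$region_names))
  expect_true(all(radiomics_feature_names() %in% names(rt)))

  hm0 <- relative_error_heatmap(rt, rt)
  expect_equal(max(abs(hm0), na.rm = TRUE), 0)
  rt2 <- rt
  for (fn in radiomics_feature_names()) rt2[[fn]] <- 1.1 * rt2[[fn]]
  hm <- relative_error_heatmap(rt, rt2)
  expect_equal(unique(round(as.vector(hm[!is.na(hm)]), 9)), 10)
  # zero reference flagged, not infinite
  rtz <- rt; rtz$suv_std[1] <- 0
  hmz <- relative_error_heatmap(rtz, rt2)
  expect_true(is.na(hmz[1, "suv_std"]))
  # left/right averaging collapses the deep-grey homologues
  hml <- relative_error_heatmap(rt, rt2, average_lr = TRUE)
  expect_true("deep_grey" %in% rownames(hml))
  expect_equal(nrow(hml), nrow(hm) - 1L)
})
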