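as_values <- function(x) if (is_volume_image(x)) x$values else x

#' Root mean squared error between two volumes
#'
#' @param a,b `volume_image`s or arrays on one grid.
#' @param mask optional logical array restricting the computation.
#' @return `sqrt(mean((a - b)^2))` over the mask (whole grid by default).
#' @export
rmse <- function(a, b, mask = NULL) {
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv))) stop("inputs must share one grid")
  d2 <- (av - bv)^2
  if (!is.null(mask)) {
    if (sum(mask) == 0) stop("mask is empty")
    d2 <- d2[mask]
  }
  sqrt(mean(d2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(data_range^2 / MSE)`. Identical inputs are flagged infinite
#' rather than erroring.
#'
#' @param a reference volume (supplies the default `data_range`).
#' @param b comparison volume.
#' @param data_range dynamic range; defaults to `max(a)`.
#' @param mask optional logical mask.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(a, b, data_range = NULL, mask = NULL) {
  av <- as_values(a); bv <- as_values(b)
  if (is.null(data_range)) data_range <- max(av)
  if (!is.finite(data_range) || data_range <= 0)
    stop("`data_range` must be positive")
  mse <- rmse(av, bv, mask)^2
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# separable Gaussian filtering of an array with sigma in voxels (isotropic)
ssim_filter <- function(a, sigma, radius) {
  offs <- seq.int(-radius, radius)
  w <- exp(-offs^2 / (2 * sigma^2)); w <- w / sum(w)
  taps <- list(weights = w, offsets = offs)
  for (axis in 1:3) a <- convolve_axis(a, taps, axis)
  a
}

#' Structural similarity index of two volumes
#'
#' Local-window SSIM with a Gaussian window (sigma 1.5 voxels, radius 5),
#' stabilizers `k1 = 0.01`, `k2 = 0.03`, averaged over the mask (whole grid
#' by default). Identical inputs give exactly 1.
#'
#' @param a,b `volume_image`s or arrays on one grid.
#' @param data_range dynamic range; defaults to `max(a) - min(a)` of the
#'   reference (or 1 when the reference is constant).
#' @param sigma Gaussian window standard deviation in voxels.
#' @param k1,k2 SSIM stabilizer constants.
#' @param mask optional logical mask for the average.
#' @return Mean SSIM over the mask.
#' @export
ssim <- function(a, b, data_range = NULL, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 mask = NULL) {
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv))) stop("inputs must share one grid")
  radius <- as.integer(round(3.5 * sigma))
  if (any(dim(av) < 2L * radius + 1L))
    stop("SSIM window (", 2L * radius + 1L,
         " voxels) is larger than the grid")
  if (is.null(data_range)) {
    data_range <- max(av) - min(av)
    if (data_range == 0) data_range <- 1
  }
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  mu_a <- ssim_filter(av, sigma, radius)
  mu_b <- ssim_filter(bv, sigma, radius)
  va <- ssim_filter(av * av, sigma, radius) - mu_a^2
  vb <- ssim_filter(bv * bv, sigma, radius) - mu_b^2
  cab <- ssim_filter(av * bv, sigma, radius) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
          ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  if (is.null(mask)) mean(smap) else {
    if (sum(mask) == 0) stop("mask is empty")
    mean(smap[mask])
  }
}

#' Joint intensity histogram of two volumes
#'
#' @param a,b volumes on one grid.
#' @param bins number of bins per axis (>= 2).
#' @param range intensity range `c(lo, hi)` shared by both axes; defaults
#'   to the pooled range of the two inputs.
#' @param mask optional logical mask.
#' @return `bins x bins` count matrix; rows index `a`, columns `b`. Total
#'   count equals the number of masked voxels.
#' @export
joint_histogram <- function(a, b, bins = 64L, range = NULL, mask = NULL) {
  if (bins < 2L) stop("`bins` must be >= 2")
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv))) stop("inputs must share one grid")
  if (!is.null(mask)) { av <- av[mask]; bv <- bv[mask] }
  if (is.null(range)) range <- range(c(av, bv))
  if (range[2] <= range[1]) range[2] <- range[1] + 1
  scale <- bins / (range[2] - range[1])
  ia <- pmin(pmax(floor((av - range[1]) * scale), 0), bins - 1) + 1
  ib <- pmin(pmax(floor((bv - range[1]) * scale), 0), bins - 1) + 1
  h <- matrix(0L, bins, bins)
  tab <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  h[] <- as.integer(tab)
  h
}

#' Bland-Altman agreement analysis of paired values
#'
#' Differences are `pred - ref`; limits of agreement are the mean difference
#' plus/minus 1.96 sample standard deviations.
#'
#' @param ref_vals,pred_vals equal-length numeric vectors (n >= 2).
#' @return List with `mean_bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(ref_vals, pred_vals) {
  if (length(ref_vals) != length(pred_vals))
    stop("paired value lists must have equal length")
  n <- length(ref_vals)
  if (n < 2L) stop("need at least 2 pairs")
  d <- pred_vals - ref_vals
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_bias = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = n),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, LoA [%.4g, %.4g], n = %d\n",
              x$mean_bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Region-wise SUV table with regression statistics
#'
#' Per-region mean SUV of a reference and a predicted volume under an atlas,
#' plus the ordinary least-squares fit of predicted on reference region
#' means (slope, intercept, R-squared) and the RMSE of the region means.
#'
#' @param ref,pred `volume_image`s on the atlas grid.
#' @param atlas a `label_atlas`.
#' @return List with `table` (data.frame: region, n_voxels, ref_mean,
#'   pred_mean) and `fit` (slope, intercept, r_squared, rmse).
#' @export
region_suv_table <- function(ref, pred, atlas) {
  check_same_grid(ref, pred)
  if (!identical(dim(ref$values), dim(atlas$labels)))
    stop("atlas must share the image grid")
  lab <- as.vector(atlas$labels)
  fg <- lab > 0L
  lv <- factor(lab[fg], levels = seq_along(atlas$region_names))
  nvox <- as.integer(table(lv))
  ref_m <- as.numeric(tapply(as.vector(ref$values)[fg], lv, mean))
  pred_m <- as.numeric(tapply(as.vector(pred$values)[fg], lv, mean))
  tabl <- data.frame(region = atlas$region_names, n_voxels = nvox,
                     ref_mean = ref_m, pred_mean = pred_m,
                     stringsAsFactors = FALSE)
  ok <- nvox > 0L
  fit <- stats::lm(pred_m[ok] ~ ref_m[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits are expected
  list(table = tabl,
       fit = list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r_squared = r2,
                  rmse = sqrt(mean((pred_m[ok] - ref_m[ok])^2))))
}

#' Aggregate similarity metrics over a test set
#'
#' @param refs,preds equal-length lists of `volume_image`s.
#' @param mask optional shared logical mask.
#' @return List with a per-pair data.frame (`ssim`, `psnr_db`, `rmse`) and
#'   aggregate mean/sd per metric.
#' @export
metric_report <- function(refs, preds, mask = NULL) {
  stopifnot(length(refs) == length(preds), length(refs) >= 1L)
  rows <- lapply(seq_along(refs), function(i) {
    data.frame(ssim = ssim(refs[[i]], preds[[i]], mask = mask),
               psnr_db = psnr(refs[[i]], preds[[i]], mask = mask),
               rmse = rmse(refs[[i]], preds[[i]], mask = mask))
  })
  per_pair <- do.call(rbind, rows)
  list(per_pair = per_pair,
       mean = vapply(per_pair, mean, numeric(1)),
       sd = vapply(per_pair, stats::sd, numeric(1)))
}
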