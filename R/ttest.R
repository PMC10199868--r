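#' Voxel-wise two-sample t-test with family-wise error control
#'
#' Pooled-variance two-sample t statistic at every masked voxel, comparing
#' `group_a` against `group_b` (positive t means `group_a` exceeds
#' `group_b`). Multiple testing across the masked voxels is controlled by
#' Bonferroni family-wise error correction at the given alpha; a paired
#' t-test variant is available but off by default. Voxels where the pooled
#' variance is zero get t = 0. The result mirrors a standard parametric
#' mapping summary: significant over-/under-estimation masks (disjoint by
#' construction), their voxel counts and percentages, and the mean and SD
#' of the significant |t| values.
#'
#' @param group_a,group_b lists of `volume_image`s (>= 2 each, equal length
#'   required only for `paired = TRUE`).
#' @param mask logical array of analysis voxels (default: whole grid).
#' @param alpha family-wise significance level (default 0.05).
#' @param correction `"bonferroni"` or `"none"`.
#' @param paired use a paired t-test on per-voxel differences.
#' @return List with `t_map` (array), `df`, `sig_over`, `sig_under`
#'   (logical arrays), `n_mask`, and a `summary` data.frame with counts,
#'   percentages, and mean/SD of significant t values per direction.
#' @export
voxelwise_ttest <- function(group_a, group_b, mask = NULL, alpha = 0.05,
                            correction = c("bonferroni", "none"),
                            paired = FALSE) {
  correction <- match.arg(correction)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 volumes")
  d <- dim(group_a[[1]]$values)
  for (im in c(group_a, group_b))
    if (!identical(dim(im$values), d)) stop("all volumes must share one grid")
  if (is.null(mask)) mask <- array(TRUE, d)
  if (sum(mask) == 0) stop("analysis mask is empty")

  stack <- function(group)
    matrix(vapply(group, function(im) im$values[mask],
                  numeric(sum(mask))), ncol = length(group))
  A <- stack(group_a); B <- stack(group_b)

  if (paired) {
    if (n1 != n2) stop("paired test requires equal group sizes")
    D <- A - B
    md <- rowMeans(D)
    sdd <- sqrt(rowSums((D - md)^2) / (n1 - 1))
    se <- sdd / sqrt(n1)
    tv <- ifelse(se == 0, 0, md / se)
    df <- n1 - 1
  } else {
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- rowSums((A - ma)^2) / (n1 - 1)
    vb <- rowSums((B - mb)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tv <- ifelse(se == 0, 0, (ma - mb) / se)
    df <- n1 + n2 - 2
  }

  m <- sum(mask)
  p <- 2 * stats::pt(-abs(tv), df)
  thr <- if (correction == "bonferroni") alpha / m else alpha
  sig <- p < thr

  t_map <- array(0, d); t_map[mask] <- tv
  over <- array(FALSE, d); over[mask] <- sig & tv > 0
  under <- array(FALSE, d); under[mask] <- sig & tv < 0

  summarize <- function(sel) {
    tt <- abs(tv[sel])
    data.frame(n_voxels = sum(sel), pct = 100 * sum(sel) / m,
               mean_t = if (any(sel)) mean(tt) else NA_real_,
               sd_t = if (sum(sel) > 1) stats::sd(tt) else NA_real_)
  }
  summary <- rbind(cbind(direction = "overestimation",
                         summarize(sig & tv > 0)),
                   cbind(direction = "underestimation",
                         summarize(sig & tv < 0)))
  list(t_map = t_map, df = df, sig_over = over, sig_under = under,
       n_mask = m, alpha = alpha, correction = correction,
       summary = summary)
}
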