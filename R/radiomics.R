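# The 13 unique 3D direction offsets (distance 1) shared by the GLCM and
# run-length computations; the full 26-neighbourhood is these and their
# negatives.
texture_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

all_neighbour_offsets <- function() {
  d <- texture_directions()
  rbind(d, -d)
}

#' Fixed-bin-number grey-level discretization
#'
#' Maps region values to integer levels 1..n_bins between the region
#' minimum and maximum; the maximum maps to level `n_bins`. A constant
#' region maps entirely to level 1 and is flagged degenerate.
#'
#' @param values numeric vector of region intensities.
#' @param n_bins number of grey levels (default 64).
#' @return List with `levels` (integers 1..n_bins), `n_bins`, and
#'   `degenerate` flag.
#' @export
discretize <- function(values, n_bins = 64L) {
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  lo <- min(values); hi <- max(values)
  if (hi <= lo)
    return(list(levels = rep(1L, length(values)), n_bins = as.integer(n_bins),
                degenerate = TRUE))
  lv <- pmin(as.integer(floor((values - lo) / (hi - lo) * n_bins)) + 1L,
             as.integer(n_bins))
  list(levels = lv, n_bins = as.integer(n_bins), degenerate = FALSE)
}

# shift a 3D array by integer offset, filling with NA
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(NA_integer_, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (off[k] >= 0) {
      src[[k]] <- seq_len(d[k] - off[k]) + off[k]
      dst[[k]] <- seq_len(d[k] - off[k])
    } else {
      src[[k]] <- seq_len(d[k] + off[k])
      dst[[k]] <- seq_len(d[k] + off[k]) - off[k]
    }
    if (length(src[[k]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# GLCM features: symmetric accumulation at distance 1, averaged over the 13
# directions that have at least one voxel pair inside the region.
glcm_features <- function(level_arr, n_bins) {
  dirs <- texture_directions()
  hom <- en <- dis <- c()
  for (r in seq_len(nrow(dirs))) {
    nb <- shift_array(level_arr, dirs[r, ])
    ok <- !is.na(level_arr) & !is.na(nb)
    if (!any(ok)) next
    i <- level_arr[ok]; j <- nb[ok]
    # symmetric: count both (i,j) and (j,i)
    counts <- tabulate(c((j - 1L) * n_bins + i, (i - 1L) * n_bins + j),
                       nbins = n_bins * n_bins)
    p <- counts / sum(counts)
    idx <- which(p > 0)
    pi_ <- ((idx - 1L) %% n_bins) + 1L
    pj_ <- ((idx - 1L) %/% n_bins) + 1L
    pv <- p[idx]
    hom <- c(hom, sum(pv / (1 + abs(pi_ - pj_))))
    en  <- c(en, sum(pv^2))
    dis <- c(dis, sum(pv * abs(pi_ - pj_)))
  }
  if (length(hom) == 0L)
    return(c(glcm_homogeneity = NA_real_, glcm_energy = NA_real_,
             glcm_dissimilarity = NA_real_))
  c(glcm_homogeneity = mean(hom), glcm_energy = mean(en),
    glcm_dissimilarity = mean(dis))
}

# Run percentage: maximal same-level runs along each of the 13 directions.
# A voxel starts a run in direction d iff its predecessor at x - d is
# outside the region or has a different level; the run count is the number
# of starts, and RP = runs / region voxels, averaged over directions.
glrlm_run_percentage <- function(level_arr) {
  dirs <- texture_directions()
  nvox <- sum(!is.na(level_arr))
  rp <- vapply(seq_len(nrow(dirs)), function(r) {
    prev <- shift_array(level_arr, -dirs[r, ])
    starts <- !is.na(level_arr) & (is.na(prev) | prev != level_arr)
    sum(starts) / nvox
  }, numeric(1))
  mean(rp)
}

# Neighbourhood grey-level difference contrast (IBSI NGTDM-style): the
# neighbourhood is the 26-neighbour mean level restricted to the region.
ngldm_contrast <- function(level_arr, n_bins) {
  offs <- all_neighbour_offsets()
  nbr_sum <- array(0, dim(level_arr))
  nbr_cnt <- array(0, dim(level_arr))
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(level_arr, offs[r, ])
    has <- !is.na(nb)
    nbr_sum[has] <- nbr_sum[has] + nb[has]
    nbr_cnt <- nbr_cnt + has
  }
  valid <- !is.na(level_arr) & nbr_cnt > 0
  nvc <- sum(valid)
  if (nvc == 0L) return(NA_real_)
  lv <- level_arr[valid]
  diff <- abs(lv - nbr_sum[valid] / nbr_cnt[valid])
  s_i <- tapply(diff, factor(lv, levels = 1:n_bins), sum)
  s_i[is.na(s_i)] <- 0
  n_i <- tabulate(lv, nbins = n_bins)
  p_i <- n_i / nvc
  occ <- which(p_i > 0)
  ngp <- length(occ)
  if (ngp < 2L) return(0)
  pij <- outer(p_i[occ], p_i[occ])
  dij2 <- outer(occ, occ, function(i, j) (i - j)^2)
  (sum(pij * dij2) / (ngp * (ngp - 1))) * (sum(s_i) / nvc)
}

# Zones: 26-connected components of constant grey level within the region.
# Returns a data.frame of (level, size) per zone.
glzlm_zones <- function(level_arr) {
  d <- dim(level_arr)
  offs <- all_neighbour_offsets()
  visited <- array(FALSE, d)
  inreg <- !is.na(level_arr)
  idx_all <- which(inreg)
  zones_level <- integer(0)
  zones_size <- integer(0)
  coord <- arrayInd(idx_all, d)
  pos_of <- array(0L, d); pos_of[idx_all] <- seq_along(idx_all)
  stack <- integer(length(idx_all))
  for (start in idx_all) {
    if (visited[start]) next
    lev <- level_arr[start]
    visited[start] <- TRUE
    stack[1L] <- start
    top <- 1L
    size <- 0L
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      size <- size + 1L
      cc <- coord[pos_of[cur], ]
      for (r in seq_len(nrow(offs))) {
        nc <- cc + offs[r, ]
        if (any(nc < 1L) || any(nc > d)) next
        ni <- nc[1] + (nc[2] - 1L) * d[1] + (nc[3] - 1L) * d[1] * d[2]
        if (!visited[ni] && inreg[ni] && level_arr[ni] == lev) {
          visited[ni] <- TRUE
          top <- top + 1L
          stack[top] <- ni
        }
      }
    }
    zones_level <- c(zones_level, lev)
    zones_size <- c(zones_size, size)
  }
  data.frame(level = zones_level, size = zones_size)
}

glzlm_features <- function(level_arr) {
  z <- glzlm_zones(level_arr)
  nz <- nrow(z)
  c(glzlm_sze = mean(1 / z$size^2),
    glzlm_lgze = mean(1 / z$level^2),
    glzlm_hgze = mean(z$level^2))
}

#' Area under the cumulative SUV-volume histogram
#'
#' Fraction of the region volume above each threshold, thresholds spanning
#' the region's intensity range, both axes normalized to [0, 1]; trapezoidal
#' integration over `n_thresholds` steps.
#'
#' @param values region intensities.
#' @param n_thresholds number of threshold steps (default 1000).
#' @return AUC in [0, 1], or `NA` for a constant region.
#' @export
auc_csh <- function(values, n_thresholds = 1000L) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(NA_real_)
  thr <- seq(lo, hi, length.out = n_thresholds + 1L)
  frac <- vapply(thr, function(t) mean(values >= t), numeric(1))
  x <- (thr - lo) / (hi - lo)
  sum(diff(x) * (frac[-1] + frac[-length(frac)]) / 2)
}

#' Radiomic feature settings
#'
#' @param n_bins grey levels for fixed-bin-number discretization.
#' @param n_thresholds steps of the cumulative SUV-volume histogram.
#' @return List of settings passed to [radiomics_features()].
#' @export
radiomics_settings <- function(n_bins = 64L, n_thresholds = 1000L) {
  list(n_bins = as.integer(n_bins), n_thresholds = as.integer(n_thresholds))
}

#' The 20-feature radiomic battery for one region
#'
#' Conventional indices (SUV mean/std/max, quartiles, TLG), first-order
#' histogram features (Pearson kurtosis, entropies, uniformity), AUC-CSH,
#' GLCM homogeneity/energy/dissimilarity, GLRLM run percentage, NGLDM
#' contrast, and GLZLM short-zone / low- and high-grey-level zone emphases.
#' Texture features use fixed-bin-number discretization (64 levels by
#' default), 13 symmetric 3D directions at distance 1 (features averaged
#' over directions), 26-connected zones, and a 26-neighbour-mean difference
#' for NGLDM. Constant regions return their closed-form values (uniformity
#' 1, entropies 0, homogeneity 1, SUV_std 0) with kurtosis and AUC-CSH
#' flagged `NA` and `degenerate = TRUE` attached.
#'
#' @param img a `volume_image`.
#' @param region_mask logical 3D array selecting the region (>= 8 voxels).
#' @param settings list from [radiomics_settings()].
#' @return Named numeric vector of 20 features, with attribute
#'   `"degenerate"`.
#' @export
radiomics_features <- function(img, region_mask,
                               settings = radiomics_settings()) {
  stopifnot(is_volume_image(img))
  if (!identical(dim(region_mask), dim(img$values)))
    stop("region mask must share the image grid")
  nvox <- sum(region_mask)
  if (nvox < 8L) stop("region must contain at least 8 voxels, got ", nvox)
  vals <- img$values[region_mask]
  vol_ml <- nvox * prod(img$spacing) / 1000

  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  conv <- c(suv_mean = mean(vals), suv_std = stats::sd(vals),
            suv_max = max(vals), suv_q1 = q[1], suv_q2 = q[2], suv_q3 = q[3],
            tlg_ml = mean(vals) * vol_ml)

  disc <- discretize(vals, settings$n_bins)
  p <- tabulate(disc$levels, nbins = disc$n_bins) / nvox
  occ <- p[p > 0]
  mu <- mean(vals); s2 <- mean((vals - mu)^2)
  kurt <- if (s2 > 0) mean((vals - mu)^4) / s2^2 else NA_real_
  histo <- c(kurtosis = kurt,
             entropy_log10 = -sum(occ * log10(occ)),
             entropy_log2 = -sum(occ * log2(occ)),
             uniformity = sum(occ^2),
             auc_csh = auc_csh(vals, settings$n_thresholds))

  level_arr <- array(NA_integer_, dim(img$values))
  level_arr[region_mask] <- disc$levels
  feats <- c(conv, histo,
             glcm_features(level_arr, disc$n_bins),
             glrlm_rp = glrlm_run_percentage(level_arr),
             ngldm_contrast = ngldm_contrast(level_arr, disc$n_bins),
             glzlm_features(level_arr))
  attr(feats, "degenerate") <- disc$degenerate
  feats
}

#' Region-by-feature radiomics table for an atlas
#'
#' @param img a `volume_image`.
#' @param atlas a `label_atlas` on the same grid.
#' @param settings list from [radiomics_settings()].
#' @param min_voxels regions smaller than this are returned as all-`NA`
#'   rows (flagged) rather than erroring.
#' @return data.frame: one row per region, 20 feature columns plus
#'   `region` and `degenerate`.
#' @export
radiomics_table <- function(img, atlas, settings = radiomics_settings(),
                            min_voxels = 8L) {
  rows <- lapply(seq_along(atlas$region_names), function(j) {
    m <- atlas$labels == j
    if (sum(m) < min_voxels) {
      f <- rep(NA_real_, 20)
      names(f) <- radiomics_feature_names()
      deg <- TRUE
    } else {
      f <- radiomics_features(img, m, settings)
      deg <- attr(f, "degenerate")
    }
    cbind(data.frame(region = atlas$region_names[j], degenerate = deg),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}

#' Names of the 20 radiomic features, in table order
#' @return Character vector of length 20.
#' @export
radiomics_feature_names <- function() {
  c("suv_mean", "suv_std", "suv_max", "suv_q1", "suv_q2", "suv_q3",
    "tlg_ml", "kurtosis", "entropy_log10", "entropy_log2", "uniformity",
    "auc_csh", "glcm_homogeneity", "glcm_energy", "glcm_dissimilarity",
    "glrlm_rp", "ngldm_contrast", "glzlm_sze", "glzlm_lgze", "glzlm_hgze")
}

#' Relative-error heat map between two radiomics tables
#'
#' Percent error `100 (pred - ref) / ref` per region and feature. Cells
#' with a zero reference are flagged `NA` rather than infinite. Optionally
#' averages homologous left/right regions (matched by a `_left` / `_right`
#' name suffix) into one row.
#'
#' @param ref_table,pred_table outputs of [radiomics_table()] on matching
#'   regions.
#' @param average_lr collapse left/right homologues into their mean row.
#' @return Matrix (regions x 20 features) of percent errors.
#' @export
relative_error_heatmap <- function(ref_table, pred_table,
                                   average_lr = FALSE) {
  if (!identical(ref_table$region, pred_table$region))
    stop("tables must cover identical regions in identical order")
  fn <- radiomics_feature_names()
  if (!all(fn %in% names(ref_table)) || !all(fn %in% names(pred_table)))
    stop("tables must contain the 20 standard feature columns")
  ref <- as.matrix(ref_table[, fn])
  pred <- as.matrix(pred_table[, fn])
  err <- ifelse(is.na(ref) | ref == 0, NA_real_, 100 * (pred - ref) / ref)
  rownames(err) <- ref_table$region
  if (average_lr) {
    base <- sub("_(left|right)$", "", rownames(err))
    grp <- factor(base, levels = unique(base))
    err <- apply(err, 2, function(col) tapply(col, grp, mean))
    rownames(err) <- levels(grp)
  }
  err
}
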