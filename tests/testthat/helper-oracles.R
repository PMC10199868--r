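# Independent oracle implementations used to validate the package's
# vectorized code paths. Everything here is deliberately written as plain
# nested loops over voxels, pairs, runs and zones, sharing no code with the
# implementations under test.

# dense (non-separable) 3D Gaussian convolution with edge replication
oracle_dense_blur <- function(a, sigma_vox, truncation_radius = 4) {
  d <- dim(a)
  r <- pmax(1L, as.integer(ceiling(truncation_radius * sigma_vox)))
  offs <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  w <- exp(-(offs$x^2 / (2 * sigma_vox[1]^2) +
             offs$y^2 / (2 * sigma_vox[2]^2) +
             offs$z^2 / (2 * sigma_vox[3]^2)))
  w <- w / sum(w)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (t in seq_len(nrow(offs))) {
      ii <- min(max(i + offs$x[t], 1L), d[1])
      jj <- min(max(j + offs$y[t], 1L), d[2])
      kk <- min(max(k + offs$z[t], 1L), d[3])
      acc <- acc + w[t] * a[ii, jj, kk]
    }
    out[i, j, k] <- acc
  }
  out
}

# scalar straight-line reimplementation of one Iterative Yang update
oracle_iy_step <- function(f, f_prev, maps, fwhm_mm, spacing,
                           ratio_epsilon = 1e-8, truncation_radius = 4) {
  R <- length(maps)
  A <- numeric(R)
  for (j in 1:R) {
    num <- 0; den <- 0
    for (v in seq_along(f)) {
      num <- num + f_prev[v] * maps[[j]][v]
      den <- den + maps[[j]][v]
    }
    A[j] <- num / den
  }
  fa <- array(0, dim(f))
  for (v in seq_along(fa))
    for (j in 1:R) fa[v] <- fa[v] + A[j] * maps[[j]][v]
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  fa_blur <- oracle_dense_blur(fa, sigma_vox, truncation_radius)
  guard <- ratio_epsilon * max(fa)
  out <- array(0, dim(f))
  for (v in seq_along(f)) {
    ratio <- if (fa_blur[v] < guard) 1 else fa[v] / fa_blur[v]
    out[v] <- f[v] * max(ratio, 0)
  }
  out
}

# direct per-window SSIM (Gaussian weights, replicated edges)
oracle_ssim <- function(a, b, data_range, sigma = 1.5, k1 = 0.01,
                        k2 = 0.03) {
  d <- dim(a)
  radius <- as.integer(round(3.5 * sigma))
  offs <- expand.grid(x = -radius:radius, y = -radius:radius,
                      z = -radius:radius)
  w <- exp(-(offs$x^2 + offs$y^2 + offs$z^2) / (2 * sigma^2))
  # separable normalization to match filtering per axis
  w1 <- exp(-(-radius:radius)^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  w <- w1[offs$x + radius + 1] * w1[offs$y + radius + 1] *
       w1[offs$z + radius + 1]
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  total <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- pmin(pmax(i + offs$x, 1L), d[1])
    jj <- pmin(pmax(j + offs$y, 1L), d[2])
    kk <- pmin(pmax(k + offs$z, 1L), d[3])
    av <- a[cbind(ii, jj, kk)]; bv <- b[cbind(ii, jj, kk)]
    mu_a <- sum(w * av); mu_b <- sum(w * bv)
    va <- sum(w * av^2) - mu_a^2; vb <- sum(w * bv^2) - mu_b^2
    cab <- sum(w * av * bv) - mu_a * mu_b
    total <- total + ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  }
  total / prod(d)
}

oracle_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

inside <- function(cc, d) all(cc >= 1L) && all(cc <= d)

# explicit pair counting -> GLCM features, one direction at a time
oracle_glcm <- function(lev, n_bins) {
  d <- dim(lev)
  dirs <- oracle_directions()
  hom <- en <- dis <- c()
  for (r in seq_len(nrow(dirs))) {
    M <- matrix(0, n_bins, n_bins)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (is.na(lev[i, j, k])) next
      nc <- c(i, j, k) + dirs[r, ]
      if (!inside(nc, d)) next
      lj <- lev[nc[1], nc[2], nc[3]]
      if (is.na(lj)) next
      li <- lev[i, j, k]
      M[li, lj] <- M[li, lj] + 1
      M[lj, li] <- M[lj, li] + 1
    }
    if (sum(M) == 0) next
    P <- M / sum(M)
    h <- e <- ds_ <- 0
    for (li in 1:n_bins) for (lj in 1:n_bins) {
      h <- h + P[li, lj] / (1 + abs(li - lj))
      e <- e + P[li, lj]^2
      ds_ <- ds_ + P[li, lj] * abs(li - lj)
    }
    hom <- c(hom, h); en <- c(en, e); dis <- c(dis, ds_)
  }
  c(homogeneity = mean(hom), energy = mean(en), dissimilarity = mean(dis))
}

# explicit run walking -> run percentage
oracle_run_percentage <- function(lev) {
  d <- dim(lev)
  dirs <- oracle_directions()
  nvox <- sum(!is.na(lev))
  rps <- numeric(nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    runs <- 0
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (is.na(lev[i, j, k])) next
      prev <- c(i, j, k) - dirs[r, ]
      same_prev <- inside(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
        lev[prev[1], prev[2], prev[3]] == lev[i, j, k]
      if (!same_prev) runs <- runs + 1   # this voxel starts a maximal run
    }
    rps[r] <- runs / nvox
  }
  mean(rps)
}

# explicit neighbourhood enumeration -> NGLDM/NGTDM contrast
oracle_ngldm_contrast <- function(lev, n_bins) {
  d <- dim(lev)
  s <- rep(0, n_bins); n <- rep(0, n_bins)
  nvc <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k])) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      cc <- c(i + dx, j + dy, k + dz)
      if (inside(cc, d) && !is.na(lev[cc[1], cc[2], cc[3]]))
        nb <- c(nb, lev[cc[1], cc[2], cc[3]])
    }
    if (length(nb) == 0) next
    nvc <- nvc + 1
    li <- lev[i, j, k]
    s[li] <- s[li] + abs(li - mean(nb))
    n[li] <- n[li] + 1
  }
  p <- n / nvc
  occ <- which(p > 0)
  if (length(occ) < 2) return(0)
  term1 <- 0
  for (a in occ) for (b in occ) term1 <- term1 + p[a] * p[b] * (a - b)^2
  term1 / (length(occ) * (length(occ) - 1)) * sum(s) / nvc
}

# recursive 26-connected region growing -> zone list -> GLZLM emphases
oracle_glzlm <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k]) || seen[i, j, k]) next
    target <- lev[i, j, k]
    members <- matrix(c(i, j, k), ncol = 3)
    seen[i, j, k] <- TRUE
    frontier <- members
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (f in seq_len(nrow(frontier))) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          cc <- frontier[f, ] + c(dx, dy, dz)
          if (!inside(cc, d)) next
          if (seen[cc[1], cc[2], cc[3]]) next
          lv <- lev[cc[1], cc[2], cc[3]]
          if (is.na(lv) || lv != target) next
          seen[cc[1], cc[2], cc[3]] <- TRUE
          nxt <- rbind(nxt, cc)
        }
      }
      if (is.null(nxt)) break
      members <- rbind(members, nxt)
      frontier <- nxt
    }
    zones[[length(zones) + 1]] <- c(level = target, size = nrow(members))
  }
  zl <- vapply(zones, `[[`, numeric(1), "level")
  zs <- vapply(zones, `[[`, numeric(1), "size")
  c(sze = mean(1 / zs^2), lgze = mean(1 / zl^2), hgze = mean(zl^2))
}

# direct per-voxel two-sample pooled t statistic
oracle_ttest_map <- function(group_a, group_b) {
  d <- dim(group_a[[1]])
  out <- array(0, d)
  n1 <- length(group_a); n2 <- length(group_b)
  for (v in seq_along(out)) {
    xa <- vapply(group_a, function(g) g[v], numeric(1))
    xb <- vapply(group_b, function(g) g[v], numeric(1))
    sp2 <- ((n1 - 1) * var(xa) + (n2 - 1) * var(xb)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    out[v] <- if (se == 0) 0 else (mean(xa) - mean(xb)) / se
  }
  out
}
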