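#' Blending specification for paired-sample augmentation
#'
#' @param levels Laplacian pyramid depth (>= 1; bounded by the grid size).
#' @param mask_mode one of `"hemisphere"` (smoothed left-right split),
#'   `"axial"` (smoothed inferior-superior split) or `"supplied"`.
#' @param seam_width_vox width in voxels of the smooth transition of the
#'   built-in masks.
#' @param seed integer seed for pair and mask draws.
#' @return An object of class `blend_spec`.
#' @export
blend_spec <- function(levels = 3L, mask_mode = c("hemisphere", "axial",
                                                  "supplied"),
                       seam_width_vox = 4, seed = 1L) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) stop("`levels` must be >= 1")
  mask_mode <- match.arg(mask_mode)
  structure(list(levels = levels, mask_mode = mask_mode,
                 seam_width_vox = seam_width_vox, seed = as.integer(seed)),
            class = "blend_spec")
}

# 5-tap binomial smoothing used by the pyramid (edge replication)
pyr_smooth <- function(a) {
  taps <- list(weights = c(1, 4, 6, 4, 1) / 16, offsets = -2:2)
  for (axis in 1:3) a <- convolve_axis(a, taps, axis)
  a
}

pyr_down <- function(a) {
  d <- dim(a)
  pyr_smooth(a)[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2),
                drop = FALSE]
}

pyr_up <- function(a, target_dim) {
  idx <- lapply(1:3, function(k) rep(seq_len(dim(a)[k]), each = 2L))
  up <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  stopifnot(identical(dim(up), as.integer(target_dim)))
  pyr_smooth(up)
}

check_pyramid_depth <- function(d, levels) {
  if (levels > 1L) {
    div <- 2^(levels - 1L)
    if (any(d %% div != 0))
      stop("grid ", paste(d, collapse = "x"), " is not divisible by 2^",
           levels - 1L, "; reduce `levels`")
    if (min(d / div) < 2)
      stop("`levels` = ", levels, " is too deep for grid ",
           paste(d, collapse = "x"))
  }
  invisible(TRUE)
}

#' Laplacian pyramid of a 3D array
#'
#' Band level k is the difference between Gaussian level k and the upsampled
#' Gaussian level k+1, so summed upsampling reconstructs the input exactly
#' (a telescoping identity). With `levels = 1` the "pyramid" is just the
#' image itself as residual.
#'
#' @param img a `volume_image` or raw 3D array.
#' @param levels pyramid depth.
#' @return List with `bands` (list of `levels - 1` arrays, finest first)
#'   and `residual` (coarsest Gaussian level).
#' @export
build_laplacian_pyramid <- function(img, levels = 3L) {
  a <- if (is_volume_image(img)) img$values else img
  check_pyramid_depth(dim(a), levels)
  bands <- vector("list", max(levels - 1L, 0L))
  g <- a
  for (k in seq_len(levels - 1L)) {
    nxt <- pyr_down(g)
    bands[[k]] <- g - pyr_up(nxt, dim(g))
    g <- nxt
  }
  list(bands = bands, residual = g)
}

#' Reconstruct an image from its Laplacian pyramid
#'
#' @param pyr output of [build_laplacian_pyramid()].
#' @return The reconstructed 3D array.
#' @export
reconstruct_laplacian_pyramid <- function(pyr) {
  g <- pyr$residual
  for (k in rev(seq_along(pyr$bands)))
    g <- pyr$bands[[k]] + pyr_up(g, dim(pyr$bands[[k]]))
  g
}

#' Built-in smooth blending masks
#'
#' A sigmoidal ramp across the mid-plane of the chosen axis: ~1 on one half,
#' ~0 on the other, transitioning over `seam_width_vox` voxels.
#'
#' @param shape grid dimensions.
#' @param axis split axis (1 = left-right hemisphere, 3 = axial).
#' @param seam_width_vox transition width in voxels.
#' @param flip if `TRUE` the halves are swapped.
#' @return A 3D array with values in [0, 1].
#' @export
split_mask <- function(shape, axis = 1L, seam_width_vox = 4, flip = FALSE) {
  d <- as.integer(shape)
  mid <- (d[axis] + 1) / 2
  ramp <- stats::plogis((seq_len(d[axis]) - mid) / (seam_width_vox / 4))
  if (flip) ramp <- 1 - ramp
  perm_dim <- c(d[axis], d[-axis])
  m <- array(ramp, perm_dim)
  aperm(m, order(c(axis, (1:3)[-axis])))
}

#' Laplacian blending of two volumes through a mask
#'
#' Each band of the composite pyramid is `M_k * A_k + (1 - M_k) * B_k`,
#' where `M_k` is the Gaussian pyramid of the mask; the composite is then
#' reconstructed. A mask of all ones returns image A, all zeros image B.
#'
#' @param img_a,img_b `volume_image`s on one grid.
#' @param mask 3D array in [0, 1] on the same grid.
#' @param levels pyramid depth.
#' @return Blended `volume_image`.
#' @export
blend <- function(img_a, img_b, mask, levels = 3L) {
  stopifnot(is_volume_image(img_a), is_volume_image(img_b))
  check_same_grid(img_a, img_b)
  if (!identical(dim(mask), dim(img_a$values)))
    stop("mask must share the image grid")
  if (min(mask) < -1e-9 || max(mask) > 1 + 1e-9)
    stop("mask values must lie in [0, 1]")
  pa <- build_laplacian_pyramid(img_a$values, levels)
  pb <- build_laplacian_pyramid(img_b$values, levels)
  m <- mask
  comp <- list(bands = vector("list", length(pa$bands)), residual = NULL)
  for (k in seq_along(pa$bands)) {
    comp$bands[[k]] <- m * pa$bands[[k]] + (1 - m) * pb$bands[[k]]
    m <- pyr_down(m)
  }
  comp$residual <- m * pa$residual + (1 - m) * pb$residual
  with_values(img_a, reconstruct_laplacian_pyramid(comp))
}

#' Augment a paired dataset by Laplacian blending
#'
#' Grows a list of paired samples to `n_target` by repeatedly drawing an
#' ordered pair of distinct parents and a blending mask, then blending the
#' two parents' uncorrected volumes and, with the SAME mask and depth, their
#' reference-corrected volumes, so each synthetic pair stays corresponding.
#' Blended samples carry no ground-truth activity (`truth = NULL`) and are
#' marked `synthetic` in their metadata.
#'
#' @param samples list of >= 2 `paired_sample`s on one grid.
#' @param n_target total dataset size wanted; if not larger than the input
#'   size the input is returned unchanged with a message.
#' @param spec a `blend_spec`.
#' @return List of `paired_sample`s of length `max(n_target, length(samples))`.
#' @export
augment_pairs <- function(samples, n_target, spec = blend_spec()) {
  if (length(samples) < 2L) stop("need at least 2 input samples")
  if (n_target <= length(samples)) {
    message("n_target (", n_target, ") does not exceed the input size (",
            length(samples), "); returning the input unchanged")
    return(samples)
  }
  n_new <- n_target - length(samples)
  d <- dim(samples[[1]]$nonpvc$values)
  out <- samples
  withr_seed(spec$seed, {
    for (i in seq_len(n_new)) {
      pair <- sample(length(samples), 2L)
      mode <- spec$mask_mode
      mask <- switch(mode,
        hemisphere = split_mask(d, 1L, spec$seam_width_vox,
                                flip = stats::runif(1) < 0.5),
        axial      = split_mask(d, 3L, spec$seam_width_vox,
                                flip = stats::runif(1) < 0.5),
        supplied   = stop("mask_mode 'supplied' requires calling blend() directly"))
      a <- samples[[pair[1]]]
      b <- samples[[pair[2]]]
      mask_id <- sum(mask * seq(0.5, 1.5, length.out = length(mask)))
      # clip at 0: band recombination can ring slightly negative, but the
      # blended channels remain SUV images
      clip0 <- function(img) with_values(img, pmax(img$values, 0))
      out[[length(samples) + i]] <- structure(list(
        truth = NULL,
        nonpvc = clip0(blend(a$nonpvc, b$nonpvc, mask, spec$levels)),
        reference_pvc = clip0(blend(a$reference_pvc, b$reference_pvc, mask,
                                    spec$levels)),
        atlas = a$atlas, probmaps = a$probmaps,
        metadata = list(profile = a$metadata$profile,
                        seed = spec$seed, synthetic = TRUE,
                        parents = pair, mask_mode = mode,
                        mask_checksum = mask_id, levels = spec$levels)),
        class = "paired_sample")
    }
  })
  out
}
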