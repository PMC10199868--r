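#' Tracer uptake profiles for phantom generation
#'
#' Four named parameter sets emulating the qualitative uptake patterns of
#' common brain PET tracers. Each profile assigns an activity range (in
#' arbitrary SUV-like units) to each structural class of the phantom:
#' cortical grey matter, white matter, deep grey nuclei, and CSF. Per-region
#' values are drawn uniformly from the class range, so "fdg-like" gives a
#' roughly 4:1 grey:white contrast while "dopa-like" concentrates uptake in
#' the deep grey (striatum-like) blobs.
#'
#' @return Named list of profiles, each a list of `c(lo, hi)` ranges.
#' @export
tracer_profiles <- function() {
  list(
    "fdg-like"     = list(cortex = c(8, 10),  white = c(2, 2.5),
                          deep = c(7, 9),     csf = c(0.2, 0.5)),
    "dopa-like"    = list(cortex = c(1.5, 2.5), white = c(1, 1.5),
                          deep = c(10, 14),   csf = c(0.1, 0.3)),
    "amyloid-like" = list(cortex = c(3, 7),   white = c(6, 8),
                          deep = c(4, 6),     csf = c(0.2, 0.5)),
    "tau-like"     = list(cortex = c(2, 6),   white = c(1.5, 2.5),
                          deep = c(2, 4),     csf = c(0.2, 0.5))
  )
}

#' Specification of a synthetic brain phantom
#'
#' @param shape grid dimensions (length 3, each >= 8; >= 32 for 8+ sectors).
#' @param spacing_mm voxel spacing in mm.
#' @param n_sectors number of angular cortical sectors.
#' @param profile tracer profile name, one of `names(tracer_profiles())`.
#' @param activity_ranges optional override of the profile's class ranges.
#' @param noise_level scale of the pseudo-Poisson noise term (>= 0).
#' @param psf `psf_model` used by the forward simulation (scanner-like
#'   resolution; defaults to 6 mm isotropic).
#' @param seed integer random seed making generation reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
                         n_sectors = 8, profile = "fdg-like",
                         activity_ranges = NULL, noise_level = 0.05,
                         psf = psf_model(6.0), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("`shape` must be 3 integers >= 8")
  profiles <- tracer_profiles()
  if (!profile %in% names(profiles))
    stop("unknown tracer profile '", profile, "'; valid profiles: ",
         paste(names(profiles), collapse = ", "))
  ranges <- if (is.null(activity_ranges)) profiles[[profile]] else activity_ranges
  for (cls in c("cortex", "white", "deep", "csf")) {
    r <- ranges[[cls]]
    if (is.null(r) || length(r) != 2L || any(r < 0) || r[2] < r[1])
      stop("activity range for class '", cls, "' must be non-negative c(lo, hi)")
  }
  if (!is.finite(noise_level) || noise_level < 0)
    stop("`noise_level` must be non-negative")
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 n_sectors = as.integer(n_sectors), profile = profile,
                 activity_ranges = ranges, noise_level = noise_level,
                 psf = psf, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the nested-ellipsoid brain atlas of a phantom
#'
#' Geometry (deterministic in the spec): an outer CSF shell, a cortical
#' grey-matter shell split into `n_sectors` angular sectors, a white-matter
#' core, and two deep-grey (striatum-like) ellipsoidal blobs. Region labels
#' partition the brain mask; background is 0 outside. Region order is
#' cortical sectors 1..S, then white matter, two deep-grey blobs, and CSF.
#'
#' @param spec a `phantom_spec`.
#' @return A `label_atlas` on the spec's grid.
#' @export
make_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  S <- spec$n_sectors
  if (S >= 8L && any(d < 32L))
    stop("grid must be >= 32 per axis for ", S, " cortical sectors")
  # normalized ellipsoidal radius; semi-axes at 45% of each extent
  cx <- (d + 1) / 2
  ax <- 0.45 * d
  gx <- (seq_len(d[1]) - cx[1]) / ax[1]
  gy <- (seq_len(d[2]) - cx[2]) / ax[2]
  gz <- (seq_len(d[3]) - cx[3]) / ax[3]
  X <- array(gx, d)
  Y <- array(rep(gy, each = d[1]), d)
  Z <- array(rep(gz, each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)

  lab <- array(0L, d)
  brain <- r <= 1
  lab[brain & r > 0.92] <- S + 4L                    # CSF shell
  cortical <- brain & r > 0.70 & r <= 0.92
  theta <- atan2(Y, X)                               # azimuthal sector split
  sec <- pmin(1L + as.integer(floor((theta + pi) / (2 * pi) * S)), S)
  lab[cortical] <- sec[cortical]
  core <- r <= 0.70
  lab[core] <- S + 1L                                # white matter
  # two deep-grey blobs, mirrored left/right
  for (side in c(-1, 1)) {
    blob <- ((X - side * 0.28) / 0.16)^2 + (Y / 0.14)^2 + (Z / 0.18)^2 <= 1
    lab[blob & core] <- if (side < 0) S + 2L else S + 3L
  }
  nm <- c(sprintf("cortical_sector_%02d", seq_len(S)),
          "white_matter", "deep_grey_left", "deep_grey_right", "csf")
  counts <- tabulate(lab, nbins = S + 4L)
  if (any(counts == 0L))
    stop("phantom parameters leave region(s) empty: ",
         paste(nm[counts == 0L], collapse = ", "),
         " (reduce n_sectors or enlarge the grid)")
  label_atlas(lab, nm)
}

#' Derive region probability maps from an atlas
#'
#' With `smoothing_fwhm_mm = 0` the maps are the binary region indicators.
#' With positive smoothing each indicator is Gaussian-blurred (edge
#' replication) and the maps are renormalized voxel-wise so their sum stays
#' 1 wherever the unsmoothed indicators summed to 1 (i.e. inside the brain
#' mask); elsewhere the blurred sum is already <= 1 and is left untouched.
#'
#' @param atlas a `label_atlas`.
#' @param smoothing_fwhm_mm non-negative smoothing FWHM in mm.
#' @param spacing_mm voxel spacing used to convert the FWHM (mm per axis).
#' @return A `probability_maps` object.
#' @export
make_probability_maps <- function(atlas, smoothing_fwhm_mm = 0,
                                  spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (!is.finite(smoothing_fwhm_mm) || smoothing_fwhm_mm < 0)
    stop("`smoothing_fwhm_mm` must be non-negative")
  R <- n_regions(atlas)
  maps <- lapply(seq_len(R), function(j) (atlas$labels == j) * 1.0)
  if (smoothing_fwhm_mm > 0) {
    sigma_vox <- smoothing_fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
    inside <- atlas$labels > 0L
    maps <- lapply(maps, blur_array, sigma_vox = sigma_vox)
    tot <- Reduce(`+`, maps)
    scale <- ifelse(inside & tot > 0, 1 / tot, 1)
    maps <- lapply(maps, function(m) pmin(m * scale, 1))
  }
  probability_maps(maps, atlas$region_names, binary = smoothing_fwhm_mm == 0)
}

# class of each region in the standard phantom layout
region_classes <- function(region_names) {
  cls <- rep("cortex", length(region_names))
  cls[region_names == "white_matter"] <- "white"
  cls[region_names %in% c("deep_grey_left", "deep_grey_right")] <- "deep"
  cls[region_names == "csf"] <- "csf"
  cls
}

#' Draw piecewise-constant ground-truth activity for an atlas
#'
#' One activity value per region, drawn uniformly from the activity range of
#' the region's structural class under the spec's tracer profile; background
#' stays 0. Same seed, same output.
#'
#' @param atlas a `label_atlas` from [make_atlas()].
#' @param spec the `phantom_spec` providing the profile and ranges.
#' @param seed integer seed (defaults to the spec's).
#' @return A `volume_image` of ground-truth activity, plus the per-region
#'   values in attribute `"region_activities"`.
#' @export
assign_activities <- function(atlas, spec, seed = spec$seed) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(spec, "phantom_spec"))
  cls <- region_classes(atlas$region_names)
  vals <- withr_seed(seed, {
    vapply(cls, function(k) {
      r <- spec$activity_ranges[[k]]
      stats::runif(1, r[1], r[2])
    }, numeric(1))
  })
  img <- array(0, dim(atlas$labels))
  fg <- atlas$labels > 0L
  img[fg] <- vals[atlas$labels[fg]]
  out <- volume_image(img, spec$spacing_mm)
  attr(out, "region_activities") <- stats::setNames(vals, atlas$region_names)
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Forward-simulate an uncorrected PET volume
#'
#' Blurs the ground truth with the scanner PSF, then adds zero-mean Gaussian
#' noise whose standard deviation scales as
#' `noise_level * sqrt(pmax(blurred, 0))` (a pseudo-Poisson surrogate for
#' count noise), and clips the result at 0. `noise_level = 0` is a pure blur.
#'
#' @param truth non-negative ground-truth `volume_image`.
#' @param psf scanner `psf_model`.
#' @param noise_level non-negative noise scale.
#' @param seed integer seed for the noise draw.
#' @return A `volume_image` of the simulated uncorrected PET.
#' @export
simulate_pet <- function(truth, psf, noise_level = 0, seed = 1L) {
  stopifnot(is_volume_image(truth))
  if (min(truth$values) < 0) stop("`truth` must be non-negative")
  if (!is.finite(noise_level) || noise_level < 0)
    stop("`noise_level` must be non-negative")
  blurred <- gaussian_blur(truth, psf)
  if (noise_level == 0) return(blurred)
  v <- blurred$values
  noisy <- withr_seed(seed, {
    v + noise_level * sqrt(pmax(v, 0)) * stats::rnorm(length(v))
  })
  with_values(blurred, array(pmax(noisy, 0), dim(v)))
}

#' Generate a reproducible paired phantom dataset
#'
#' Each sample bundles the ground-truth activity, the forward-simulated
#' uncorrected PET, the atlas and probability maps, and the Iterative Yang
#' reference correction computed with the recorded configuration. Per-sample
#' seeds are derived deterministically from the master seed.
#'
#' @param n number of samples (>= 1).
#' @param spec a `phantom_spec`; its seed acts as the master seed.
#' @param iy_config an [iy_config()] used to compute `reference_pvc`.
#' @param map_smoothing_fwhm_mm smoothing for the probability maps (mm).
#' @return List of `paired_sample` objects, each with fields `truth`,
#'   `nonpvc`, `reference_pvc`, `atlas`, `probmaps`, `metadata`.
#' @export
make_dataset <- function(n, spec, iy_config = iy_config(),
                         map_smoothing_fwhm_mm = 0) {
  if (n < 1) stop("`n` must be >= 1")
  atlas <- make_atlas(spec)
  probmaps <- make_probability_maps(atlas, map_smoothing_fwhm_mm,
                                    spec$spacing_mm)
  lapply(seq_len(n), function(i) {
    si <- (spec$seed + i * 7919L) %% .Machine$integer.max
    truth <- tryCatch(assign_activities(atlas, spec, seed = si),
                      error = function(e)
                        stop("sample ", i, ": ", conditionMessage(e)))
    nonpvc <- simulate_pet(truth, spec$psf, spec$noise_level,
                           seed = si + 1L)
    ref <- iy_correct(nonpvc, probmaps, iy_config)
    structure(list(truth = truth, nonpvc = nonpvc, reference_pvc = ref,
                   atlas = atlas, probmaps = probmaps,
                   metadata = list(profile = spec$profile, seed = si,
                                   iy = iy_config, synthetic = FALSE)),
              class = "paired_sample")
  })
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample> profile %s, seed %s%s\n",
              x$metadata$profile, x$metadata$seed,
              if (is.null(x$truth)) " (blended, no truth)" else ""))
  invisible(x)
}
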