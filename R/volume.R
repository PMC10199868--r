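#' 3D scalar volume with voxel spacing
#'
#' The universal image currency of the package: a 3D array of finite,
#' typically non-negative values (SUV-like units) plus the physical voxel
#' spacing in mm and a world-space origin. All operations in the package
#' consume and produce `volume_image` objects so that mm-based parameters
#' (PSF widths, smoothing) can be converted to voxel units consistently.
#'
#' @param values 3D numeric array; every axis must have at least 8 voxels.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world coordinate of the first voxel (mm).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 8L))
    stop("grid dimensions must be >= 8 per axis, got ",
         paste(dim(values), collapse = "x"))
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %dx%dx%d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$values)

is_volume_image <- function(x) inherits(x, "volume_image")

#' Construct a volume like an existing one but with new values
#'
#' @param template a `volume_image` supplying spacing and origin.
#' @param values replacement 3D array of the same shape.
#' @return A `volume_image`.
#' @export
with_values <- function(template, values) {
  stopifnot(is_volume_image(template))
  if (!identical(dim(values), dim(template$values)))
    stop("replacement values must match the template grid")
  volume_image(values, template$spacing, template$origin)
}

check_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(what, " must share one grid: ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  invisible(TRUE)
}

#' Integer region atlas on a volume grid
#'
#' Labels 0..R where 0 is background and 1..R index the foreground regions
#' named by `region_names`. Every foreground region must be non-empty.
#'
#' @param labels 3D integer array with values in `0:length(region_names)`.
#' @param region_names character vector of R region names.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, region_names) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  R <- length(region_names)
  if (R < 1L) stop("at least one foreground region is required")
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] > R)
    stop("labels must lie in [0, ", R, "]")
  counts <- tabulate(labels, nbins = R)
  if (any(counts == 0L))
    stop("empty region(s): ",
         paste(region_names[counts == 0L], collapse = ", "))
  structure(list(labels = labels, region_names = as.character(region_names)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s voxels, %d regions\n",
              paste(dim(x$labels), collapse = "x"), length(x$region_names)))
  invisible(x)
}

n_regions <- function(atlas) length(atlas$region_names)

#' Per-region membership probability maps
#'
#' One 3D map per foreground region with values in [0, 1]; at every voxel
#' the sum over regions is at most 1 (up to 1e-6). These play the role of
#' the anatomical prior driving region-based partial volume correction.
#'
#' @param maps list of 3D arrays, one per region, all the same shape.
#' @param region_names character vector naming the maps.
#' @param binary logical flag recording whether the maps are hard indicators.
#' @return An object of class `probability_maps`.
#' @export
probability_maps <- function(maps, region_names, binary = NA) {
  if (!is.list(maps) || length(maps) < 1L)
    stop("`maps` must be a non-empty list of 3D arrays")
  if (length(maps) != length(region_names))
    stop("one name per map is required")
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("all maps must share one grid")
    if (min(m) < -1e-9 || max(m) > 1 + 1e-9)
      stop("map values must lie in [0, 1]")
  }
  tot <- Reduce(`+`, maps)
  if (max(tot) > 1 + 1e-6)
    stop("per-voxel sum over regions exceeds 1 (max ", format(max(tot)), ")")
  structure(list(maps = maps, region_names = as.character(region_names),
                 binary = binary),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps> %d regions on %s grid%s\n",
              length(x$maps), paste(dim(x$maps[[1]]), collapse = "x"),
              if (isTRUE(x$binary)) " (binary)" else ""))
  invisible(x)
}

#' Gaussian point-spread-function model
#'
#' Scanner resolution surrogate: an axis-aligned 3D Gaussian described by
#' its FWHM in mm per axis. An FWHM of 0 on an axis means a delta (identity)
#' kernel along that axis, used to express the no-blur limit.
#'
#' @param fwhm_mm numeric length-1 or length-3 FWHM in mm; values >= 0.
#' @param truncation_radius kernel half-width in standard deviations (>= 3).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm_mm = 3.0, truncation_radius = 4) {
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (length(fwhm_mm) != 3L || any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0))
    stop("`fwhm_mm` must be 1 or 3 non-negative finite numbers")
  if (!is.finite(truncation_radius) || truncation_radius < 3)
    stop("`truncation_radius` must be >= 3 sigmas")
  structure(list(fwhm_mm = fwhm_mm, truncation_radius = truncation_radius),
            class = "psf_model")
}

#' Delta (identity) PSF
#'
#' @return A `psf_model` whose blur is the identity.
#' @export
psf_delta <- function() psf_model(c(0, 0, 0))

is_delta_psf <- function(psf) all(psf$fwhm_mm == 0)

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> FWHM %s mm\n",
              paste(format(x$fwhm_mm), collapse = "x")))
  invisible(x)
}
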