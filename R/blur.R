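#' Convert Gaussian FWHM to standard deviation
#'
#' FWHM = 2 sqrt(2 ln 2) sigma for a Gaussian, so sigma = FWHM / 2.3548...
#'
#' @param fwhm_mm positive FWHM in mm.
#' @return sigma in mm.
#' @seealso [sigma_to_fwhm()]
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm <= 0))
    stop("`fwhm_mm` must be positive")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

#' Convert Gaussian standard deviation to FWHM
#'
#' @param sigma_mm positive sigma in mm.
#' @return FWHM in mm.
#' @export
sigma_to_fwhm <- function(sigma_mm) {
  if (any(!is.finite(sigma_mm)) || any(sigma_mm <= 0))
    stop("`sigma_mm` must be positive")
  sigma_mm * (2 * sqrt(2 * log(2)))
}

# Discrete 1D Gaussian taps at integer voxel offsets, normalized to sum 1.
# sigma_vox == 0 yields the identity kernel.
gaussian_taps <- function(sigma_vox, truncation_radius) {
  if (sigma_vox == 0) return(list(weights = 1, offsets = 0L))
  r <- max(1L, as.integer(ceiling(truncation_radius * sigma_vox)))
  offs <- seq.int(-r, r)
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  list(weights = w / sum(w), offsets = offs)
}

# Convolve one axis with arbitrary taps using edge replication: shifted
# copies with clamped indices, weighted and summed. Exactly preserves
# constant arrays because the taps sum to 1.
convolve_axis <- function(a, taps, axis) {
  if (length(taps$offsets) == 1L && taps$offsets[1] == 0L)
    return(a * taps$weights[1])
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (k in seq_along(taps$offsets)) {
    idx <- pmin(pmax(seq_len(n) + taps$offsets[k], 1L), n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + taps$weights[k] * shifted
  }
  out
}

# Separable blur of a raw 3D array given per-axis sigmas in voxels.
blur_array <- function(a, sigma_vox, truncation_radius = 4) {
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      taps <- gaussian_taps(sigma_vox[axis], truncation_radius)
      a <- convolve_axis(a, taps, axis)
    }
  }
  a
}

#' Gaussian blur of a volume by a PSF model
#'
#' Separable 3D Gaussian convolution. The FWHM is given in mm and converted
#' per axis to voxel units via the volume spacing, so anisotropic spacings
#' are handled correctly. Boundaries use edge replication, which maps a
#' constant image to itself exactly (the discrete kernel is normalized to
#' unit sum). A delta PSF (all-zero FWHM) returns the input unchanged.
#'
#' @param img a `volume_image`.
#' @param psf a `psf_model`.
#' @return A blurred `volume_image` on the same grid.
#' @export
gaussian_blur <- function(img, psf) {
  stopifnot(is_volume_image(img), inherits(psf, "psf_model"))
  if (is_delta_psf(psf)) return(img)
  sigma_vox <- ifelse(psf$fwhm_mm > 0,
                      psf$fwhm_mm / (2 * sqrt(2 * log(2))) / img$spacing,
                      0)
  with_values(img, blur_array(img$values, sigma_vox, psf$truncation_radius))
}
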