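# shared fixture builders; everything is generated in code at test time

# small two-region half-space atlas on an n^3 grid
half_space_atlas <- function(n = 8L) {
  lab <- array(0L, c(n, n, n))
  lab[1:(n %/% 2), , ] <- 1L
  lab[(n %/% 2 + 1):n, , ] <- 2L
  label_atlas(lab, c("left", "right"))
}

# random volume image
rand_volume <- function(n = 8L, lo = 0, hi = 1, spacing = c(1, 1, 1),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volume_image(array(runif(n^3, lo, hi), c(n, n, n)), spacing)
}

# random discretized level array with a random (or full) region mask
rand_level_region <- function(side, n_bins = 6L, p_in = 1,
                              min_vox = 8L) {
  repeat {
    mask <- array(runif(side^3) < p_in, c(side, side, side))
    if (sum(mask) >= min_vox) break
  }
  lev <- array(NA_integer_, c(side, side, side))
  lev[mask] <- sample.int(n_bins, sum(mask), replace = TRUE)
  lev
}

# standard noiseless piecewise-constant phantom pair used by several tests
noiseless_phantom <- function(seed = 42, fwhm = 3.0, shape = c(64, 64, 64)) {
  spec <- phantom_spec(shape = shape, spacing_mm = c(2, 2, 2),
                       noise_level = 0, psf = psf_model(fwhm), seed = seed)
  atlas <- make_atlas(spec)
  probmaps <- make_probability_maps(atlas)
  truth <- assign_activities(atlas, spec)
  blurred <- simulate_pet(truth, spec$psf, 0)
  list(spec = spec, atlas = atlas, probmaps = probmaps, truth = truth,
       blurred = blurred)
}

# the desk-scale training fixture shared by the learning-signal checks:
# 4 phantoms for training (40 slices after capping), 1 held out
gan_fixture <- function() {
  spec <- phantom_spec(noise_level = 0.05, seed = 7)
  ds <- make_dataset(5, spec, iy_config())
  list(train = ds[1:4], test = ds[5])
}
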