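#' Read a 3D volume from a NIfTI-1 file
#'
#' Spacing is taken from the header pixdim; the origin from the stored
#' transform's translation. Files that are not 3D are rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A `volume_image`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  if (length(dim(a)) != 3L)
    stop("expected a 3D volume, got ", length(dim(a)), "D in ", path)
  xf <- try(RNifti::xform(im), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  volume_image(a, spacing = RNifti::pixdim(im)[1:3], origin = origin)
}

#' Write a volume to NIfTI-1
#'
#' Values are stored as doubles so a write/read round-trip preserves them
#' within floating-point tolerance; spacing is written exactly.
#'
#' @param img a `volume_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot(is_volume_image(img))
  im <- RNifti::asNifti(img$values)
  RNifti::pixdim(im) <- img$spacing
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' Write / read a label atlas as NIfTI plus a sidecar name table
#'
#' The labels go to `<path>` and the region names to `<path>.labels.txt`
#' (one name per line, label order).
#'
#' @param atlas a `label_atlas`; `spacing` voxel spacing to record.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(atlas, "label_atlas"))
  im <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path, datatype = "int16")
  writeLines(atlas$region_names, paste0(path, ".labels.txt"))
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  if (length(dim(a)) != 3L) stop("expected a 3D label volume")
  nm_file <- paste0(path, ".labels.txt")
  nm <- if (file.exists(nm_file)) readLines(nm_file)
        else sprintf("region_%02d", seq_len(max(a)))
  label_atlas(array(as.integer(round(a)), dim(a)), nm)
}

#' Write / read probability maps as a 4D NIfTI (one volume per region)
#'
#' @param probmaps a `probability_maps` object.
#' @param path output NIfTI path; names go to `<path>.labels.txt`.
#' @param spacing voxel spacing to record.
#' @return `path`, invisibly.
#' @export
write_probmaps <- function(probmaps, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(probmaps, "probability_maps"))
  d <- dim(probmaps$maps[[1]])
  a <- array(0, c(d, length(probmaps$maps)))
  for (j in seq_along(probmaps$maps)) a[, , , j] <- probmaps$maps[[j]]
  im <- RNifti::asNifti(a)
  RNifti::pixdim(im) <- c(spacing, 1)
  RNifti::writeNifti(im, path, datatype = "double")
  writeLines(probmaps$region_names, paste0(path, ".labels.txt"))
  invisible(path)
}

#' @rdname write_probmaps
#' @export
read_probmaps <- function(path) {
  im <- RNifti::readNifti(path)
  a <- as.array(im)
  if (length(dim(a)) != 4L) stop("expected a 4D probability-map volume")
  nm_file <- paste0(path, ".labels.txt")
  nm <- if (file.exists(nm_file)) readLines(nm_file)
        else sprintf("region_%02d", seq_len(dim(a)[4]))
  probability_maps(lapply(seq_len(dim(a)[4]), function(j) a[, , , j]), nm)
}
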