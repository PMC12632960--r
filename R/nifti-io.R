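# NIfTI-1 import/export. Simulated artifacts live on an identity-affine grid;
# real inputs keep whatever geometry their header carries.

#' Write receptor templates as a 4D NIfTI image (one volume per target)
#' @param templates a `receptor_templates` object.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_templates_nifti <- function(templates, path) {
  arr <- array(templates$values, c(templates$dim, ncol(templates$values)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write enriched connectivity maps as a 4D NIfTI image
#' @param maps an `enriched_maps` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maps_nifti <- function(maps, path) {
  arr <- array(maps$values, c(maps$dim, ncol(maps$values)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write an atlas label image as NIfTI
#' @param atlas a `parcellation_atlas`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  RNifti::writeNifti(RNifti::asNifti(atlas$labels), path)
  invisible(path)
}

#' Write a BOLD run as a 4D NIfTI image (time last)
#' @param bold a `bold_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path) {
  arr <- array(t(bold$values), c(bold$dim, nrow(bold$values)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a 4D NIfTI BOLD image into a `bold_run`
#' @param path NIfTI path.
#' @param mask optional logical 3D array; defaults to all voxels.
#' @param repetition_time seconds (default 2).
#' @return a `bold_run`.
#' @export
read_bold_nifti <- function(path, mask = NULL, repetition_time = 2) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) abort("expected a 4D BOLD image")
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  vals <- t(matrix(img, prod(dm[1:3]), dm[4]))
  structure(list(values = vals, repetition_time = repetition_time,
                 mask = mask, dim = dm[1:3]),
            class = "bold_run")
}

#' Read a set of 3D NIfTI templates into a `receptor_templates`
#' @param paths named character vector of NIfTI paths (names = targets).
#' @param mask optional logical 3D array; defaults to all voxels.
#' @return a `receptor_templates` object.
#' @export
read_templates_nifti <- function(paths, mask = NULL) {
  if (is.null(names(paths))) names(paths) <- tools::file_path_sans_ext(basename(paths), compression = TRUE)
  imgs <- lapply(paths, RNifti::readNifti)
  dm <- dim(imgs[[1]])
  if (is.null(mask)) mask <- array(TRUE, dm)
  vals <- sapply(imgs, as.vector)
  structure(list(values = vals, target_names = names(paths), mask = mask, dim = dm),
            class = "receptor_templates")
}
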