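#' Read a 4D BOLD NIfTI file
#'
#' The spatial grid is taken from the image xform and the repetition time
#' from the header time step (`pixdim[4]`), overridable because headers are
#' frequently wrong in the wild. The affine maps 0-based voxel indices to mm.
#'
#' @param path path to a `.nii` / `.nii.gz` file containing a 4D image.
#' @param tr_seconds optional TR override in seconds; when `NULL` the header
#'   value is used (it must then be positive).
#' @return A [bold_volume].
#' @export
read_bold_nifti <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop(sprintf("expected a 4D image, got %dD: %s", length(dim(img)), path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- image_grid(dim(img)[1:3], affine = aff)
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_seconds) || tr_seconds <= 0)
      stop("header time step is not positive; pass tr_seconds explicitly")
  }
  bold_volume(array(as.numeric(img), dim = dim(img)), grid, tr_seconds)
}

# build an RNifti image carrying the grid affine (and TR for 4D data)
as_nifti_image <- function(values, grid, tr_seconds = 1) {
  pd <- c(-1, grid$voxel_size_mm, tr_seconds, 0, 0, 0)
  img <- RNifti::asNifti(values, reference = list(pixdim = pd))
  aff <- structure(grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  img
}

#' Write a statistic map (or any volume) as NIfTI-1
#'
#' Out-of-mask voxels are written as zero; in-mask values are stored at
#' double precision so a write/read roundtrip is lossless.
#'
#' @param map a [stat_map], or a [bold_volume] for 4D output.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_stat_nifti <- function(map, path) {
  if (inherits(map, "bold_volume")) {
    img <- as_nifti_image(map$values, map$grid, map$tr_seconds)
  } else if (inherits(map, "stat_map")) {
    img <- as_nifti_image(map$values, map$grid)
  } else stop("expected a stat_map or bold_volume")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 3D statistic map written by [write_stat_nifti()]
#'
#' @param path path to a 3D NIfTI file.
#' @param mask the [brain_mask] the map was defined on.
#' @param kind the map kind label (see [stat_map]).
#' @return A [stat_map].
#' @export
read_stat_nifti <- function(path, mask, kind) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D image: ", path)
  if (!identical(as.integer(dim(img)), mask$grid$dims))
    stop("image dimensions do not match mask grid")
  stat_map(array(as.numeric(img), dim = dim(img)), mask, kind)
}

#' Head-motion trace
#'
#' Six rigid-body realignment parameters per timepoint: translations along
#' x, y, z in mm and rotations about x, y, z in radians (the prevailing
#' rp-file convention; quality-control thresholds stated in degrees are
#' converted at comparison time).
#'
#' @param translations_mm n x 3 numeric matrix of translations (mm).
#' @param rotations_rad n x 3 numeric matrix of rotations (radians).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(translations_mm, rotations_rad) {
  translations_mm <- as.matrix(translations_mm)
  rotations_rad <- as.matrix(rotations_rad)
  stopifnot(ncol(translations_mm) == 3L, ncol(rotations_rad) == 3L,
            nrow(translations_mm) == nrow(rotations_rad))
  if (nrow(translations_mm) < 1L) stop("empty motion trace")
  if (!all(is.finite(translations_mm)) || !all(is.finite(rotations_rad)))
    stop("motion trace must be finite")
  structure(list(n_timepoints = nrow(translations_mm),
                 translations_mm = translations_mm,
                 rotations_rad = rotations_rad),
            class = "motion_trace")
}

#' Read a six-column realignment-parameter text file
#'
#' @param path whitespace-delimited text, six numeric columns per row:
#'   three translations in mm then three rotations in radians.
#' @param n_expected optional expected row count; a mismatch is an error.
#' @return A [motion_trace].
#' @export
read_motion_trace <- function(path, n_expected = NULL) {
  m <- tryCatch(as.matrix(utils::read.table(path, header = FALSE)),
                error = function(e) stop("cannot parse motion trace: ",
                                         conditionMessage(e)))
  if (!is.numeric(m)) stop("motion trace contains non-numeric cells")
  if (ncol(m) != 6L) stop("motion trace must have exactly 6 columns")
  dimnames(m) <- NULL
  if (!is.null(n_expected) && nrow(m) != n_expected)
    stop(sprintf("motion trace has %d rows, expected %d", nrow(m), n_expected))
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Write a motion trace in rp-file format
#' @param trace a [motion_trace].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_motion_trace <- function(trace, path) {
  m <- cbind(trace$translations_mm, trace$rotations_rad)
  utils::write.table(format(m, digits = 10, scientific = FALSE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
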