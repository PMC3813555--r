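# NIfTI and table I/O. Volumes travel as NIfTI-1 (the standard interchange
# format for MRI), tables as CSV, and structured reports as JSON.

#' Write a 3-D volume as NIfTI
#'
#' @param x numeric or logical 3-D array (logicals are written as 0/1).
#' @param path output path (`.nii`; uncompressed for byte-reproducible
#'   checksums).
#' @param spacing voxel spacing in mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, spacing = c(0.97, 0.97, 1)) {
  if (is.logical(x)) {
    x <- array(as.integer(x), dim(x))
  }
  img <- RNifti::asNifti(x, reference = NULL)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return numeric array with attribute `"spacing"`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attributes(out) <- list(dim = dim(out))
  attr(out, "spacing") <- RNifti::pixdim(img)
  out
}

#' Write a phantom to disk
#'
#' Emits one NIfTI per grid (echoes, ground-truth water/fat/fat-fraction,
#' labels), a JSON sidecar with the seeds and the per-region truth table,
#' and the truth table as CSV.
#'
#' @param phantom output of [make_phantom()] or its wrappers.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$truth$spacing
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  paths <- c(
    write_volume(phantom$echoes$in_phase, p("in_phase.nii"), sp),
    write_volume(phantom$echoes$opposed_phase, p("opposed_phase.nii"), sp),
    write_volume(phantom$truth$water, p("true_water.nii"), sp),
    write_volume(phantom$truth$fat, p("true_fat.nii"), sp),
    write_volume(ifelse(is.na(phantom$truth$ff), -1, phantom$truth$ff),
                 p("true_ff.nii"), sp),
    write_volume(phantom$truth$labels, p("labels.nii"), sp))
  sidecar <- list(spacing_mm = sp,
                  seeds = phantom$seeds,
                  regions = phantom$truth$region_table)
  jsonlite::write_json(sidecar, p("sidecar.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.csv(phantom$truth$region_table, p("truth.csv"),
                   row.names = FALSE)
  invisible(c(paths, p("sidecar.json"), p("truth.csv")))
}

#' Write a fat-fraction map (values + validity mask) as NIfTI
#' @param ff a `fat_fraction_map`.
#' @param path_ff,path_valid output paths.
#' @return the paths, invisibly.
#' @export
write_fat_fraction <- function(ff, path_ff, path_valid) {
  write_volume(ifelse(is.na(ff$ff), -1, ff$ff), path_ff, ff$spacing)
  write_volume(ff$valid, path_valid, ff$spacing)
  invisible(c(path_ff, path_valid))
}
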