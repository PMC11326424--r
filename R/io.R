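#' Write a perfusion series (and mask) as NIfTI with a JSON sidecar
#'
#' The 2D+time volume is stored as a 3D NIfTI image, the mask (if any) as a
#' separate integer NIfTI, and the metadata (pixel spacing, frame times,
#' heart center, series id) as a JSON sidecar.
#'
#' @param series a `perfusion_series`.
#' @param mask optional label mask.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; defaults to the series id.
#' @return Invisibly, the paths written.
#' @export
write_series_nifti <- function(series, mask = NULL, dir, prefix = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prefix)) prefix <- series$series_id
  paths <- c(series = file.path(dir, paste0(prefix, "_series.nii.gz")),
             sidecar = file.path(dir, paste0(prefix, ".json")))
  RNifti::writeNifti(series$intensities, paths["series"])
  meta <- list(series_id = series$series_id,
               pixel_spacing_mm = series$pixel_spacing_mm,
               frame_times_s = series$frame_times_s,
               heart_center = series$heart_center)
  if (!is.null(mask)) {
    mask <- validate_mask(mask, series)
    paths["mask"] <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
    RNifti::writeNifti(mask, paths["mask"])
  }
  jsonlite::write_json(meta, paths["sidecar"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a series written by [write_series_nifti()]
#'
#' @param dir directory containing the files.
#' @param prefix the file name prefix used at write time.
#' @return `list(series, mask)`; `mask` is `NULL` if absent.
#' @export
read_series_nifti <- function(dir, prefix) {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(dir, paste0(prefix, "_series.nii.gz")))
  arr <- array(as.numeric(img), dim = dim(img))
  series <- perfusion_series(arr,
                             pixel_spacing_mm = meta$pixel_spacing_mm,
                             frame_times_s = meta$frame_times_s,
                             heart_center = meta$heart_center,
                             series_id = meta$series_id)
  mask_path <- file.path(dir, paste0(prefix, "_mask.nii.gz"))
  mask <- NULL
  if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- validate_mask(matrix(as.integer(round(m)), dim(m)[1], dim(m)[2]),
                          series)
  }
  list(series = series, mask = mask)
}

#' Write a segmentation solution (mask, probabilities, U-map) to disk
#'
#' @param solution a `segmentation_solution`.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_solution <- function(solution, dir) {
  stopifnot(inherits(solution, "segmentation_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- solution$series_id
  paths <- c(mask = file.path(dir, paste0(prefix, "_pred.nii.gz")),
             umap = file.path(dir, paste0(prefix, "_umap.nii.gz")),
             log = file.path(dir, paste0(prefix, "_selection.csv")))
  RNifti::writeNifti(solution$mask, paths["mask"])
  RNifti::writeNifti(solution$umap, paths["umap"])
  utils::write.csv(solution$log, paths["log"], row.names = FALSE)
  invisible(paths)
}
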