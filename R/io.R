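#' Write a phantom label volume as NIfTI
#'
#' Labels are written as int16 with the voxel size in the header; the bregma
#' voxel and tissue-property table go to a JSON sidecar (`<path>.json`, with
#' the `.nii`/`.nii.gz` extension stripped).
#'
#' @param phantom A `voxel_phantom`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, path) {
  h_mm <- phantom$voxel_size_um / 1000
  arr <- phantom$labels
  attr(arr, "pixdim") <- c(h_mm, h_mm, h_mm)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(voxel_size_um = phantom$voxel_size_um,
         bregma_voxel = phantom$bregma_voxel,
         provenance = phantom$provenance,
         properties = phantom$properties),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_phantom_nifti()]
#'
#' @param path NIfTI path; the JSON sidecar must sit next to it.
#' @return A `voxel_phantom`.
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("sidecar JSON not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  labels <- array(as.integer(img), dim(img))
  ph <- structure(list(labels = labels,
                       voxel_size_um = meta$voxel_size_um,
                       bregma_voxel = as.integer(meta$bregma_voxel),
                       properties = as.data.frame(meta$properties),
                       spec = NULL,
                       provenance = meta$provenance %||% "read from NIfTI"),
                  class = "voxel_phantom")
  validate_tissue_table(ph$properties, check_ordering = FALSE)
  ph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write potential and field-magnitude volumes as NIfTI
#'
#' Writes `phi.nii.gz`, `magE.nii.gz` and `magJ.nii.gz` (float32, sharing
#' the phantom voxel size) into a directory.
#'
#' @param potential A `qs_potential`.
#' @param fields A `field_maps`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_field_maps_nifti <- function(potential, fields, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h_mm <- fields$voxel_size_um / 1000
  phi <- potential$phi
  phi[is.na(phi)] <- 0
  vols <- list(phi = phi, magE = fields$magE, magJ = fields$magJ)
  paths <- character(0)
  for (nm in names(vols)) {
    arr <- vols[[nm]]
    attr(arr, "pixdim") <- c(h_mm, h_mm, h_mm)
    img <- RNifti::asNifti(arr, datatype = "float")
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
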