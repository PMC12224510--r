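#' Write a displacement field to disk
#'
#' Stores the field as one uncompressed NIfTI volume per phase (the three
#' displacement components stacked on the 4th dimension), a mask volume, and
#' a JSON sidecar with the phase count, lattice shape and voxel spacing.
#' Values are stored at double precision so a write/read round trip is
#' bitwise lossless.
#'
#' @param field A [displacement_field()].
#' @param dir Output directory (created if needed).
#' @param id File-name stem for this subject.
#' @return Named list of written paths, invisibly.
#' @export
write_field <- function(field, dir, id = "field") {
  stopifnot(inherits(field, "displacement_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (p in seq_len(field$n_phases)) {
    vol <- field$u[, , , , p]
    dim(vol) <- c(field$shape, 3L)
    path <- file.path(dir, sprintf("%s_phase%02d.nii", id, p))
    RNifti::writeNifti(vol, path, datatype = "double")
    paths[[sprintf("phase%02d", p)]] <- path
  }
  mask_path <- file.path(dir, sprintf("%s_mask.nii", id))
  RNifti::writeNifti(array(as.integer(field$mask), field$shape), mask_path,
                     datatype = "uint8")
  meta <- list(id = id, shape = field$shape, n_phases = field$n_phases,
               voxel_spacing_mm = field$voxel_spacing_mm)
  meta_path <- file.path(dir, sprintf("%s_meta.json", id))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(mask = mask_path, meta = meta_path)))
}

#' Read a displacement field written by [write_field()]
#'
#' @param dir Directory containing the files.
#' @param id File-name stem used at write time.
#' @return A [displacement_field()].
#' @export
read_field <- function(dir, id = "field") {
  meta_path <- file.path(dir, sprintf("%s_meta.json", id))
  if (!file.exists(meta_path)) {
    stop("format error: missing sidecar ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n_phases <- as.integer(meta$n_phases)
  mask_path <- file.path(dir, sprintf("%s_mask.nii", id))
  if (!file.exists(mask_path)) stop("format error: missing mask ", mask_path)
  mask_arr <- as.array(RNifti::readNifti(mask_path))
  if (!identical(dim(mask_arr), shape)) {
    stop("format error: mask shape mismatch in ", mask_path)
  }
  u <- array(0, c(shape, 3L, n_phases))
  for (p in seq_len(n_phases)) {
    path <- file.path(dir, sprintf("%s_phase%02d.nii", id, p))
    if (!file.exists(path)) stop("format error: missing phase file ", path)
    vol <- as.array(RNifti::readNifti(path))
    if (!identical(dim(vol), c(shape, 3L))) {
      stop("format error: inconsistent shape in ", path)
    }
    u[, , , , p] <- vol
  }
  displacement_field(u, mask_arr > 0,
                     voxel_spacing_mm = as.numeric(meta$voxel_spacing_mm))
}

#' Write a cohort manifest CSV
#'
#' @param records Subject record tibble (from [simulate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
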