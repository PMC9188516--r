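#' Write a volume as NIfTI
#'
#' Thin wrapper over `RNifti::writeNifti` that stamps the voxel size.
#'
#' @param values 3D or 4D numeric array, or a [`voxel_map`][fit_map].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm (taken from a `voxel_map`
#'   automatically).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(values, path, voxel_size = c(1, 1, 1)) {
  if (inherits(values, "voxel_map")) {
    voxel_size <- values$voxel_size
    values <- values$values
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(values)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return A numeric array with attribute `voxel_size`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  arr
}

#' Write the simulated acquisition of one subject to disk
#'
#' Writes the four signal series as 4D NIfTI volumes, the gradient table
#' as FSL-dialect `bvals`/`bvecs` text files, the phantom labels and
#' ground-truth maps as NIfTI, and a JSON sidecar echoing the generation
#' parameters.
#'
#' @param signals Output of [simulate_subject_signals()].
#' @param phantom Output of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @param params Named list echoed to `params.json`.
#' @return The directory, invisibly.
#' @export
write_subject_dataset <- function(signals, phantom, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- phantom$voxel_size
  write_volume_nifti(signals$ir, file.path(dir, "ir.nii.gz"), vs)
  write_volume_nifti(signals$se, file.path(dir, "se.nii.gz"), vs)
  write_volume_nifti(signals$gre, file.path(dir, "gre.nii.gz"), vs)
  write_volume_nifti(signals$dwi, file.path(dir, "dwi.nii.gz"), vs)
  write_bvals_bvecs(signals$protocol, file.path(dir, "bvals"),
                    file.path(dir, "bvecs"))
  write_volume_nifti(phantom$labels + 0, file.path(dir, "labels.nii.gz"), vs)
  for (nm in c("t1", "t2", "t2s", "md", "fa", "m0", "p"))
    write_volume_nifti(phantom$maps[[nm]],
                       file.path(dir, paste0("truth_", nm, ".nii.gz")), vs)
  subj <- phantom$subject
  params <- c(list(subject_id = subj$subject_id, cohort = subj$cohort,
                   brain_temperature = subj$brain_temperature,
                   seed = subj$seed), params)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
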