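adc_unit_note <- "ADC in 1e-3 mm^2/s"

write_nifti_vol <- function(arr, spacing, path, descrip = NULL) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  if (!is.null(descrip)) img$descrip <- descrip
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write one phantom case as NIfTI files
#'
#' Creates `b0.nii.gz`, `b1000.nii.gz`, `adc.nii.gz` and `mask.nii.gz`
#' inside `dir`, with voxel spacing in the headers and the ADC unit
#' convention (10^-3 mm^2/s) noted in the ADC header description.
#'
#' @param case A `patient_case`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti_vol(case$b0, case$spacing, file.path(dir, "b0.nii.gz"))
  write_nifti_vol(case$b1000, case$spacing, file.path(dir, "b1000.nii.gz"))
  write_nifti_vol(case$adc, case$spacing, file.path(dir, "adc.nii.gz"),
                  descrip = adc_unit_note)
  write_nifti_vol(case$reference_mask$voxels, case$spacing,
                  file.path(dir, "mask.nii.gz"))
  invisible(dir)
}

#' Read a case from NIfTI files
#'
#' Validates that all sequences share one grid shape and spacing and that
#' the mask is strictly binary.
#'
#' @param dir Directory holding `b0.nii.gz`, `b1000.nii.gz`, `adc.nii.gz`,
#'   `mask.nii.gz` (as written by [write_case()]).
#' @param case_id Identifier for the loaded case.
#' @return A `patient_case` (age and invasion status are `NA` unless a
#'   cohort manifest supplies them).
#' @export
read_case <- function(dir, case_id = basename(dir)) {
  paths <- file.path(dir, c("b0.nii.gz", "b1000.nii.gz", "adc.nii.gz",
                            "mask.nii.gz"))
  names(paths) <- c("b0", "b1000", "adc", "mask")
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      abort(sprintf("Missing `%s` volume: %s not found.", nm, paths[[nm]]))
    }
  }
  vols <- lapply(paths, function(p) RNifti::readNifti(p))
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    abort("Sequences differ in grid shape across the case.")
  }
  sp <- lapply(vols, function(v) RNifti::pixdim(v))
  if (max(vapply(sp, function(s) max(abs(s - sp[[1]])), numeric(1))) > 1e-4) {
    abort("Sequences differ in voxel spacing across the case.")
  }
  mask <- array(as.numeric(vols$mask), dim(vols$mask))
  if (!is_binary_array(mask)) {
    abort("Mask volume is not binary: values outside {0, 1} found.")
  }
  structure(
    list(case_id = case_id,
         b0 = array(as.numeric(vols$b0), dim(vols$b0)),
         b1000 = array(as.numeric(vols$b1000), dim(vols$b1000)),
         adc = array(as.numeric(vols$adc), dim(vols$adc)),
         spacing = as.numeric(sp[[1]][1:3]),
         reference_mask = new_seg_mask(array(as.integer(mask), dim(mask)),
                                       as.numeric(sp[[1]][1:3])),
         age = NA_integer_, muscle_invasion = NA),
    class = "patient_case"
  )
}

#' Write a cohort to disk with a manifest
#'
#' @param cohort List of `patient_case` objects.
#' @param dir Output directory; one subdirectory per case.
#' @return Manifest tibble (case_id, path, age, muscle_invasion),
#'   also written to `manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(cohort, function(cs) {
    p <- file.path(dir, cs$case_id)
    write_case(cs, p)
    tibble::tibble(case_id = cs$case_id, path = p, age = cs$age,
                   muscle_invasion = cs$muscle_invasion)
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Write a tidy radiomics feature table as CSV
#'
#' Columns: `case_id`, `mask_source`, `family`, `feature`, `value`. Every
#' (case, mask source) pair must carry the complete 107-feature vector.
#'
#' @param features Tidy feature tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  man <- feature_manifest()
  chk <- features |>
    dplyr::count(.data$case_id, .data$mask_source)
  if (any(chk$n != nrow(man))) {
    bad <- chk[chk$n != nrow(man), ]
    abort(sprintf("Incomplete feature vector for %s (%d of %d features).",
                  paste0(bad$case_id[1], "/", bad$mask_source[1]),
                  bad$n[1], nrow(man)))
  }
  key <- paste(features$family, features$feature)
  if (!all(key %in% paste(man$family, man$feature))) {
    abort("Feature table contains names outside the manifest.")
  }
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Tidy feature tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    case_id = readr::col_character(),
    mask_source = readr::col_character(),
    family = readr::col_character(),
    feature = readr::col_character(),
    value = readr::col_double()
  ))
}
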