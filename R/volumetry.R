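# --- structure volumetry and ICV normalization -------------------------------

get_affine <- function(image) {
  if (inherits(image, "niftiImage")) return(structure(RNifti::xform(image),
                                                      class = "matrix"))
  aff <- attr(image, "affine")
  if (is.list(image) && !is.null(image$affine)) aff <- image$affine
  if (is.null(aff)) abort_fcd("image carries no affine (voxel -> mm) matrix",
                              "volumetry_error")
  aff
}

get_voxels <- function(image) {
  if (is.list(image) && !is.null(image$data)) return(image$data)
  as.array(image)
}

#' Volume of labeled voxels in a segmentation label map
#'
#' Counts the voxels whose label belongs to `target_labels` and multiplies
#' by the voxel volume, taken as the absolute determinant of the affine's
#' 3x3 linear part. Using the determinant (rather than header voxel
#' dimensions) keeps oblique or rotated acquisitions correct.
#'
#' @param image A NIfTI image read with [read_label_map()] (or any
#'   `RNifti::niftiImage`), an integer array with an `affine` attribute,
#'   or a `list(data = array, affine = 4x4 matrix)`.
#' @param target_labels Nonempty set of integer labels to count.
#' @return Volume in mm^3. Zero (with a warning) when no voxel matches.
#' @export
#' @examples
#' img <- list(data = array(c(rep(1L, 10), rep(0L, 17)), dim = c(3, 3, 3)),
#'             affine = diag(4))
#' mask_volume(img, 1) # 10 mm^3
mask_volume <- function(image, target_labels) {
  if (length(target_labels) == 0) abort_fcd("target_labels must be nonempty",
                                            "volumetry_error")
  aff <- get_affine(image)
  lin <- aff[1:3, 1:3]
  voxvol <- abs(det(lin))
  if (voxvol == 0) abort_fcd("affine is non-invertible (zero determinant)",
                             "volumetry_error")
  n <- sum(get_voxels(image) %in% target_labels)
  if (n == 0) warning("no voxels matched target labels; returning 0 mm^3")
  n * voxvol
}

#' Read a NIfTI segmentation label map
#'
#' Thin wrapper around `RNifti::readNifti()` for `.nii` / `.nii.gz` label
#' images consumed by [mask_volume()].
#'
#' @param path Path to the NIfTI file.
#' @return An `RNifti::niftiImage`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) abort_fcd(paste0("no such file: ", path), "io_error")
  RNifti::readNifti(path)
}

#' Head-size correction of a structure volume
#'
#' Normalizes a structure volume for intracranial volume (ICV):
#' `normalized = raw * mean_icv / icv`, where `mean_icv` is the cohort
#' mean ICV. A subject whose ICV equals the cohort mean is unchanged.
#'
#' @param raw Raw structure volume(s), mm^3, > 0.
#' @param icv Subject intracranial volume(s), mm^3, > 0.
#' @param mean_icv Cohort mean ICV, mm^3, > 0.
#' @return Normalized volume(s) in mm^3.
#' @export
#' @examples
#' normalize_volume(1000, 1.5e6, 1.4e6) # 933.33
normalize_volume <- function(raw, icv, mean_icv) {
  if (any(c(raw, icv, mean_icv) <= 0, na.rm = TRUE) ||
      anyNA(c(icv, mean_icv))) {
    abort_fcd("raw, icv and mean_icv must all be positive", "domain_error")
  }
  raw * mean_icv / icv
}

#' Base-10 log of a volume
#'
#' Applied to normalized lesion volumes to correct their right-skewed
#' (approximately log-normal) distribution before linear modeling.
#'
#' @param v Positive volume(s), mm^3.
#' @return `log10(v)`.
#' @export
log10_volume <- function(v) {
  if (any(v <= 0, na.rm = TRUE)) abort_fcd("volume must be > 0", "domain_error")
  log10(v)
}

#' Ipsilateral / contralateral thalamic volumes
#'
#' Maps left/right thalamic volumes to lesion-relative sides: for a
#' left-sided lesion the left thalamus is ipsilateral, and vice versa.
#'
#' @param left_mm3,right_mm3 Thalamic volumes, mm^3.
#' @param lesion_side `"left"` or `"right"` (vectorized).
#' @return Tibble with columns `ipsi_mm3`, `contra_mm3`.
#' @export
#' @examples
#' thalamus_sides(7000, 7500, "left")  # ipsi 7000, contra 7500
thalamus_sides <- function(left_mm3, right_mm3, lesion_side) {
  if (anyNA(lesion_side) || !all(lesion_side %in% c("left", "right"))) {
    abort_fcd("lesion side must be 'left' or 'right'; exclude patients with unknown side from thalamic analysis",
              "domain_error")
  }
  is_left <- lesion_side == "left"
  tibble::tibble(ipsi_mm3 = ifelse(is_left, left_mm3, right_mm3),
                 contra_mm3 = ifelse(is_left, right_mm3, left_mm3))
}

#' Cohort mean intracranial volume
#'
#' @param cohort A cohort data frame with `icv_mm3` (and
#'   `lesion_volume_mm3` when `scope = "measurable"`).
#' @param scope `"all"` (default; every patient with a processed MRI) or
#'   `"measurable"` (only patients with a delineable lesion volume).
#' @return Mean ICV in mm^3.
#' @export
cohort_mean_icv <- function(cohort, scope = c("all", "measurable")) {
  scope <- match.arg(scope)
  icv <- cohort$icv_mm3
  if (scope == "measurable") icv <- icv[!is.na(cohort$lesion_volume_mm3)]
  if (length(icv) == 0) abort_fcd("no patients in scope", "domain_error")
  mean(icv)
}

#' Add normalized and log-transformed volume columns to a cohort
#'
#' Computes `lesion_norm_mm3` (ICV-normalized lesion volume),
#' `lesion_log10`, and ipsilateral / contralateral normalized thalamic
#' volumes (`thal_ipsi_norm_mm3`, `thal_contra_norm_mm3`) where the
#' inputs are present. When `volumes_are = "normalized"` the stored
#' volumes are taken as already head-size-corrected and copied through.
#'
#' @param cohort A validated cohort tibble.
#' @param volumes_are `"raw"` or `"normalized"`.
#' @param mean_icv_scope Passed to [cohort_mean_icv()].
#' @return The cohort with the derived columns appended.
#' @export
add_volume_norms <- function(cohort, volumes_are = c("raw", "normalized"),
                             mean_icv_scope = c("all", "measurable")) {
  volumes_are <- match.arg(volumes_are)
  cohort <- validate_cohort(cohort)
  micv <- cohort_mean_icv(cohort, mean_icv_scope)
  norm1 <- function(raw) {
    if (volumes_are == "normalized") raw
    else ifelse(is.na(raw), NA_real_, raw * micv / cohort$icv_mm3)
  }
  cohort$lesion_norm_mm3 <- norm1(cohort$lesion_volume_mm3)
  cohort$lesion_log10 <- ifelse(is.na(cohort$lesion_norm_mm3), NA_real_,
                                log10(cohort$lesion_norm_mm3))
  th <- thalamus_sides(cohort$thal_left_mm3, cohort$thal_right_mm3,
                       cohort$side)
  cohort$thal_ipsi_norm_mm3 <- norm1(th$ipsi_mm3)
  cohort$thal_contra_norm_mm3 <- norm1(th$contra_mm3)
  attr(cohort, "mean_icv") <- micv
  cohort
}
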