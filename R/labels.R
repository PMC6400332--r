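#' SUV threshold rule
#'
#' Ground truth is generated by thresholding PET at a fixed fraction of the
#' per-dataset maximum standardized uptake value: `T = SUVmax * fraction`,
#' with the default fraction 0.2 (20%). The threshold is computed once per
#' dataset over the whole 3D PET volume, never per slice.
#'
#' @param fraction scalar in (0, 1); default 0.2.
#' @return A `suvseg_threshold_rule`.
#' @export
threshold_rule <- function(fraction = 0.2) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop_suvseg("threshold fraction must lie strictly between 0 and 1",
                class = "suvseg_config_error")
  }
  structure(list(fraction = fraction), class = "suvseg_threshold_rule")
}

#' Compute the per-dataset SUV threshold
#'
#' @param pet a PET [volume()] with a positive maximum.
#' @param rule a [threshold_rule()].
#' @return Scalar threshold `T = max(pet) * fraction`.
#' @export
compute_threshold <- function(pet, rule = threshold_rule()) {
  stopifnot(inherits(pet, "suvseg_volume"), inherits(rule, "suvseg_threshold_rule"))
  if (pet$modality != "PET") {
    stop_suvseg("compute_threshold expects a PET volume",
                class = "suvseg_config_error")
  }
  m <- max(pet$data)
  if (m <= 0) {
    stop_suvseg("PET volume has no uptake anywhere (max <= 0); ",
                "cannot derive a threshold", class = "suvseg_degenerate_error")
  }
  m * rule$fraction
}

#' Binarize a PET volume at a threshold
#'
#' Voxels strictly greater than the threshold become foreground (1); all
#' others, including voxels exactly equal to the threshold, become
#' background (0).
#'
#' @param pet_on_ct_grid a PET [volume()] (typically already resampled onto
#'   the CT grid).
#' @param threshold scalar > 0.
#' @return Binary integer array with the volume's dimensions.
#' @export
binarize <- function(pet_on_ct_grid, threshold) {
  stopifnot(inherits(pet_on_ct_grid, "suvseg_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_suvseg("threshold must be a positive scalar", class = "suvseg_config_error")
  }
  out <- array(0L, dim(pet_on_ct_grid$data))
  out[pet_on_ct_grid$data > threshold] <- 1L
  out
}

#' Construct a CT slice / mask pair
#'
#' The unit of training data: one 2D CT slice with an aligned binary label
#' mask and provenance describing how it was produced (source slice index,
#' applied rotation/scaling, noise).
#'
#' @param image 2D numeric matrix (CT intensities).
#' @param mask 2D binary matrix of identical dimensions.
#' @param patient_id identifier.
#' @param slice_index origin slice index in the source volume.
#' @param angle_deg,scale_x,scale_y,noise provenance of applied augmentation;
#'   an unaugmented slice carries (0, 1, 1, "none").
#' @return A `suvseg_slice_pair`.
#' @export
slice_pair <- function(image, mask, patient_id = "unknown", slice_index = 1L,
                       angle_deg = 0, scale_x = 1, scale_y = 1, noise = "none") {
  if (!is.matrix(image) || !is.matrix(mask) || !all(dim(image) == dim(mask))) {
    stop_suvseg("image and mask must be matrices of identical dimensions",
                class = "suvseg_format_error")
  }
  if (!is_binary(mask)) {
    stop_suvseg("mask values must be in {0, 1}", class = "suvseg_format_error")
  }
  structure(list(image = image, mask = matrix(as.integer(mask), nrow(mask)),
                 patient_id = patient_id, slice_index = as.integer(slice_index),
                 angle_deg = angle_deg, scale_x = scale_x, scale_y = scale_y,
                 noise = noise),
            class = "suvseg_slice_pair")
}

#' Extract bladder-bearing CT slices
#'
#' Returns every slice whose mask contains at least one foreground pixel,
#' optionally padded with `margin` empty-mask context slices on each side of
#' every foreground run, ordered by slice index.
#'
#' @param ct a CT [volume()].
#' @param mask3d binary array on the same grid.
#' @param margin non-negative integer count of context slices (default 0).
#' @return List of [slice_pair()]s (empty, with a warning, if the mask has
#'   no foreground anywhere).
#' @export
extract_bladder_slices <- function(ct, mask3d, margin = 0L) {
  stopifnot(inherits(ct, "suvseg_volume"))
  if (!all(dim(ct$data) == dim(mask3d))) {
    stop_suvseg("ct and mask3d must share one grid", class = "suvseg_format_error")
  }
  margin <- as.integer(margin)
  stopifnot(margin >= 0L)
  fg <- apply(mask3d, 1, sum) > 0
  if (!any(fg)) {
    warning("mask is empty everywhere; no slices extracted")
    return(list())
  }
  keep <- which(fg)
  if (margin > 0L) {
    keep <- unique(sort(unlist(lapply(which(fg), function(i) {
      seq(max(1L, i - margin), min(dim(mask3d)[1], i + margin))
    }))))
  }
  lapply(keep, function(i) {
    slice_pair(image = ct$data[i, , ], mask = mask3d[i, , ],
               patient_id = ct$patient_id, slice_index = i)
  })
}

#' Generate weak labels from a co-registered PET/CT pair
#'
#' The full automatic ground-truth pipeline: resample PET onto the CT grid
#' (trilinear), compute the per-dataset threshold `T = SUVmax * fraction` on
#' the resampled PET, binarize (strictly above `T` is foreground), and
#' extract bladder-bearing CT slices with aligned masks. Provenance of every
#' returned pair is marked unaugmented.
#'
#' The threshold is computed after resampling; trilinear interpolation never
#' exceeds the original maximum, so resampling cannot create foreground
#' above a threshold derived from the native PET grid.
#'
#' @param pet PET [volume()].
#' @param ct CT [volume()] co-registered with `pet`.
#' @param rule a [threshold_rule()].
#' @param margin passed to [extract_bladder_slices()].
#' @return List of [slice_pair()]s.
#' @export
make_labels <- function(pet, ct, rule = threshold_rule(), margin = 0L) {
  pet_r <- resample_to_reference(pet, ct, interpolation = "trilinear")
  T <- compute_threshold(pet_r, rule)
  mask3d <- binarize(pet_r, T)
  extract_bladder_slices(ct, mask3d, margin = margin)
}
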