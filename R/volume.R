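#' Construct a 3D scalar volume
#'
#' The canonical in-memory image container: a 3D array ordered
#' (slice, row, col) with voxel spacing and physical origin in millimetres
#' and a modality tag. All interpolation in the package uses the
#' pixel-centre convention: voxel `(i, j, k)` (1-based) sits at physical
#' position `origin + (i-1, j-1, k-1) * spacing` along (z, y, x).
#'
#' @param data 3D numeric array, dimensions (slices, rows, cols), all >= 1.
#' @param spacing numeric length-3, (dz, dy, dx) in mm, strictly positive.
#' @param origin numeric length-3, physical position (z, y, x) in mm of the
#'   centre of the first voxel. Default `c(0, 0, 0)`.
#' @param modality `"PET"` or `"CT"`. PET intensities must be non-negative
#'   (they are proportional to standardized uptake values); CT intensities
#'   are unrestricted.
#' @param patient_id opaque identifier string.
#' @return An object of class `suvseg_volume`.
#' @export
volume <- function(data, spacing, origin = c(0, 0, 0), modality = c("CT", "PET"),
                   patient_id = "unknown") {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_suvseg("`data` must be a 3D array (slices, rows, cols)",
                class = "suvseg_format_error")
  }
  if (any(dim(data) < 1L)) {
    stop_suvseg("all three volume dimensions must be >= 1",
                class = "suvseg_format_error")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_suvseg("`spacing` must be 3 strictly positive numbers (dz, dy, dx)",
                class = "suvseg_format_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop_suvseg("`origin` must be 3 finite numbers", class = "suvseg_format_error")
  }
  if (modality == "PET" && any(data < 0)) {
    stop_suvseg("PET intensities must be >= 0 (SUV-proportional)",
                class = "suvseg_format_error")
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 modality = modality, patient_id = patient_id),
            class = "suvseg_volume")
}

#' @export
print.suvseg_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<suvseg_volume> %s  %d x %d x %d (slice x row x col)\n",
              x$modality, d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz,dy,dx): %s mm   origin: %s mm\n",
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range: [%g, %g]   patient: %s\n",
              min(x$data), max(x$data), x$patient_id))
  invisible(x)
}

#' Read a volume from a NIfTI file
#'
#' NIfTI (`.nii` / `.nii.gz`) is the package's canonical volume interchange
#' format. Slice order follows the file's ascending patient axis; voxel
#' spacing and origin are recovered from the NIfTI geometry.
#'
#' @param path path to a NIfTI file.
#' @param modality `"PET"` or `"CT"`.
#' @param patient_id identifier attached to the returned volume.
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = c("CT", "PET"), patient_id = "unknown") {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    stop_suvseg("no such file: ", path, class = "suvseg_format_error")
  }
  if (dir.exists(path) || !grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    stop_suvseg("unreadable volume (expected a NIfTI .nii/.nii.gz file): ", path,
                class = "suvseg_format_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_suvseg("failed to read NIfTI file ",
                                                  path, ": ", conditionMessage(e),
                                                  class = "suvseg_format_error"))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) {
    stop_suvseg("NIfTI file is not a 3D volume: ", path,
                class = "suvseg_format_error")
  }
  pd <- RNifti::pixdim(img)[1:3]                  # (dx, dy, dz)
  aff <- RNifti::xform(img)
  orig_xyz <- aff[1:3, 4]
  # internal order is (slice, row, col) = (z, y, x)
  data <- aperm(arr, c(3, 2, 1))
  volume(data, spacing = rev(abs(pd)),
         origin = c(orig_xyz[3], orig_xyz[2], orig_xyz[1]),
         modality = modality, patient_id = patient_id)
}

#' Write a volume to a NIfTI file
#'
#' @param v a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "suvseg_volume"))
  arr <- aperm(v$data, c(3, 2, 1))               # to (x, y, z)
  img <- RNifti::asNifti(arr)
  sp <- rev(v$spacing)                           # (dx, dy, dz)
  aff <- diag(c(sp, 1))
  aff[1:3, 4] <- c(v$origin[3], v$origin[2], v$origin[1])
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

# physical coordinates (z, y, x) of every voxel centre of a volume's grid,
# returned as three vectors in array (column-major) order
grid_coords <- function(v) {
  d <- dim(v$data)
  iz <- rep.int(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep.int(rep(seq_len(d[2]), each = d[1]), times = d[3])
  ix <- rep(seq_len(d[3]), each = d[1] * d[2])
  list(z = v$origin[1] + (iz - 1) * v$spacing[1],
       y = v$origin[2] + (iy - 1) * v$spacing[2],
       x = v$origin[3] + (ix - 1) * v$spacing[3])
}

#' Resample a volume onto the grid of a reference volume
#'
#' Maps the reference grid's voxel centres into the moving volume's physical
#' space and interpolates there; positions outside the moving volume's field
#' of view are set to 0. PET is always resampled onto the CT grid (never CT
#' onto PET) before thresholding so that masks align pixel-for-pixel with the
#' CT training slices.
#'
#' @param moving the [volume()] supplying intensities.
#' @param reference the [volume()] supplying the target grid.
#' @param interpolation `"trilinear"` (intensities) or `"nearest"` (labels;
#'   keeps binary volumes binary).
#' @return A [volume()] on the reference grid carrying the moving volume's
#'   modality and patient id.
#' @export
resample_to_reference <- function(moving, reference,
                                  interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(moving, "suvseg_volume"), inherits(reference, "suvseg_volume"))
  dm <- dim(moving$data)
  co <- grid_coords(reference)
  # continuous 1-based voxel indices in the moving volume
  iz <- (co$z - moving$origin[1]) / moving$spacing[1] + 1
  iy <- (co$y - moving$origin[2]) / moving$spacing[2] + 1
  ix <- (co$x - moving$origin[3]) / moving$spacing[3] + 1

  out <- numeric(length(iz))
  if (interpolation == "nearest") {
    rz <- round(iz); ry <- round(iy); rx <- round(ix)
    ok <- rz >= 1 & rz <= dm[1] & ry >= 1 & ry <= dm[2] & rx >= 1 & rx <= dm[3]
    if (any(ok)) {
      lin <- rz[ok] + dm[1] * (ry[ok] - 1) + dm[1] * dm[2] * (rx[ok] - 1)
      out[ok] <- moving$data[lin]
    }
  } else {
    ok <- iz >= 1 & iz <= dm[1] & iy >= 1 & iy <= dm[2] & ix >= 1 & ix <= dm[3]
    if (any(ok)) {
      z0 <- pmin(pmax(floor(iz[ok]), 1), max(dm[1] - 1, 1))
      y0 <- pmin(pmax(floor(iy[ok]), 1), max(dm[2] - 1, 1))
      x0 <- pmin(pmax(floor(ix[ok]), 1), max(dm[3] - 1, 1))
      fz <- iz[ok] - z0; fy <- iy[ok] - y0; fx <- ix[ok] - x0
      z1 <- pmin(z0 + 1, dm[1]); y1 <- pmin(y0 + 1, dm[2]); x1 <- pmin(x0 + 1, dm[3])
      lin <- function(a, b, cc) a + dm[1] * (b - 1) + dm[1] * dm[2] * (cc - 1)
      d <- moving$data
      out[ok] <-
        d[lin(z0, y0, x0)] * (1 - fz) * (1 - fy) * (1 - fx) +
        d[lin(z1, y0, x0)] * fz       * (1 - fy) * (1 - fx) +
        d[lin(z0, y1, x0)] * (1 - fz) * fy       * (1 - fx) +
        d[lin(z1, y1, x0)] * fz       * fy       * (1 - fx) +
        d[lin(z0, y0, x1)] * (1 - fz) * (1 - fy) * fx +
        d[lin(z1, y0, x1)] * fz       * (1 - fy) * fx +
        d[lin(z0, y1, x1)] * (1 - fz) * fy       * fx +
        d[lin(z1, y1, x1)] * fz       * fy       * fx
    }
  }
  if (!any(ok)) {
    warning("moving and reference volumes do not overlap; output is all zero")
  }
  volume(array(out, dim(reference$data)), spacing = reference$spacing,
         origin = reference$origin, modality = moving$modality,
         patient_id = moving$patient_id)
}
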