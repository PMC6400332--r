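#' Export a slice dataset to disk
#'
#' Writes one 16-bit TIFF per CT slice image and one 8-bit PNG ({0, 255})
#' per mask, plus a tab-separated manifest with columns
#' `image, label, patient_id, source_slice, angle_deg, scale_x, scale_y,
#' noise`. Images are stored as unsigned 16-bit integers with a fixed
#' intercept of 1024 (`stored = round(x) + 1024`, clamped to
#' \[0, 65535\]), so reading back reproduces integer-valued images in
#' \[-1024, 64511\] bit-exactly.
#'
#' @param pairs list of [slice_pair()]s.
#' @param out_dir output directory; must be empty or absent unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into an existing nonempty directory.
#' @return Invisibly, the manifest as a data.frame (also written to
#'   `manifest.tsv` when `pairs` is nonempty).
#' @export
export_slice_dataset <- function(pairs, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !overwrite) {
    stop_suvseg("output directory exists and is not empty: ", out_dir,
                class = "suvseg_io_error")
  }
  man <- data.frame(image = character(), label = character(),
                    patient_id = character(), source_slice = integer(),
                    angle_deg = numeric(), scale_x = numeric(),
                    scale_y = numeric(), noise = character(),
                    stringsAsFactors = FALSE)
  if (length(pairs) == 0L) return(invisible(man))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    stopifnot(inherits(p, "suvseg_slice_pair"))
    img_name <- sprintf("slice_%06d.tif", i)
    lab_name <- sprintf("slice_%06d_mask.png", i)
    stored <- pmin(pmax(round(p$image) + 1024, 0), 65535)
    tiff::writeTIFF(stored / 65535, file.path(out_dir, img_name),
                    bits.per.sample = 16L)
    png::writePNG(p$mask * 1.0, file.path(out_dir, lab_name))
    rows[[i]] <- data.frame(image = img_name, label = lab_name,
                            patient_id = p$patient_id,
                            source_slice = p$slice_index,
                            angle_deg = p$angle_deg, scale_x = p$scale_x,
                            scale_y = p$scale_y, noise = p$noise,
                            stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man)
}

#' Read a slice dataset written by [export_slice_dataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @return List of [slice_pair()]s in manifest order.
#' @export
read_slice_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) {
    stop_suvseg("no manifest.tsv in ", dir, class = "suvseg_io_error")
  }
  man <- utils::read.table(mf, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    img <- round(tiff::readTIFF(file.path(dir, man$image[i])) * 65535) - 1024
    msk <- round(png::readPNG(file.path(dir, man$label[i])))
    if (!all(dim(img) == dim(msk))) {
      stop_suvseg("image/label dimension mismatch at manifest row ", i,
                  class = "suvseg_format_error")
    }
    slice_pair(img, msk, patient_id = man$patient_id[i],
               slice_index = man$source_slice[i],
               angle_deg = man$angle_deg[i], scale_x = man$scale_x[i],
               scale_y = man$scale_y[i], noise = man$noise[i])
  })
}
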