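## On-disk image convention: one grayscale TIFF per channel per field,
## named {well}_{field}_{channel}.tif, 16-bit unsigned, stored value =
## round(intensity) (so intensities up to 65535 round-trip to within
## 0.5 units).

#' Write a field's channels as per-channel grayscale TIFFs
#'
#' @param field a [field_image()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_field_tiff <- function(field, dir) {
  stopifnot(inherits(field, "field_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(field$channels)) {
    f <- file.path(dir, sprintf("%s_%d_%s.tif", field$well_id,
                                field$field_id, ch))
    v <- pmin(pmax(round(field$channels[[ch]]$pixels), 0), 65535)
    tiff::writeTIFF(v / 65535, f, bits.per.sample = 16L)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Read a field back from per-channel TIFFs
#'
#' @param dir directory holding `{well}_{field}_{channel}.tif` files.
#' @param well_id,field_id field identity to read.
#' @param pixel_size um/pixel to stamp on the channels.
#' @param treatment treatment metadata for the field.
#' @return a [field_image()]; the `nfat` channel is attached only if its
#'   file exists.
#' @export
read_field_tiff <- function(dir, well_id, field_id, pixel_size = 1,
                            treatment = list(rankl = NA_real_,
                                             mcsf = NA_real_,
                                             time_h = NA_real_)) {
  channels <- list()
  for (ch in CHANNELS) {
    f <- file.path(dir, sprintf("%s_%d_%s.tif", well_id, field_id, ch))
    if (!file.exists(f)) {
      if (ch == "nfat") next
      stop("missing channel file: ", f)
    }
    px <- tiff::readTIFF(f) * 65535
    channels[[ch]] <- channel_image(px, ch, pixel_size)
  }
  field_image(well_id, field_id, channels, treatment)
}

#' Write a field's ground truth (CSV + JSON sidecar)
#'
#' One row per nucleus in `<prefix>_truth.csv`; generator parameters in
#' `<prefix>_params.json`.
#'
#' @param truth the `truth` component of [simulate_field()].
#' @param dir output directory.
#' @param prefix file-name prefix, e.g. `"A01_1"`.
#' @return invisibly, the CSV path.
#' @export
write_ground_truth <- function(truth, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, paste0(prefix, "_truth.csv"))
  write.csv(truth$nuclei, f, row.names = FALSE)
  write.csv(truth$osteoclasts,
            file.path(dir, paste0(prefix, "_osteoclasts.csv")),
            row.names = FALSE)
  p <- truth$params
  p$intensity_model$foreground <- as.list(p$intensity_model$foreground)
  p$intensity_model$nfat_nucleus_sd <- as.list(p$intensity_model$nfat_nucleus_sd)
  jsonlite::write_json(unclass(p),
                       file.path(dir, paste0(prefix, "_params.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(f)
}

#' Write / read a long-format cytokine panel CSV
#'
#' Columns: condition_id, rankl, mcsf, cytokine, timepoint_h, value,
#' below_detection.
#'
#' @param panel panel data frame (see [simulate_cytokine_panel()]).
#' @param path CSV path.
#' @return `write_panel_csv`: invisibly, `path`; `read_panel_csv`: the
#'   panel data frame.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "cytokine", "timepoint_h", "value")
  if (!all(need %in% names(p)))
    stop("not a panel CSV (missing columns): ", path)
  p
}
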