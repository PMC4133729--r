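CHANNELS <- c("nuclei", "wholecell", "avb3", "nfat")

#' Single-channel fluorescence image
#'
#' Wraps one grayscale intensity grid with its stain identity and pixel
#' size. The four channels of an osteoclastogenesis field are `nuclei`
#' (Hoechst), `wholecell` (whole-cell cytoplasmic stain), `avb3`
#' (alpha-v-beta-3 integrin / CD51-CD61 osteoclast marker) and `nfat`
#' (NFATc1 immunofluorescence).
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (arbitrary units), row-major with pixel `[1, 1]` at the image origin.
#' @param channel one of `"nuclei"`, `"wholecell"`, `"avb3"`, `"nfat"`.
#' @param pixel_size physical pixel edge length in micrometres (> 0).
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, pixel_size = 1) {
  channel <- match.arg(channel, CHANNELS)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("channel_image: pixels must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("channel_image: pixel_size must be a single positive number")
  structure(list(pixels = pixels, channel = channel,
                 pixel_size = pixel_size),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d px  (%.3g um/px)  range [%.3g, %.3g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Multi-channel imaged field
#'
#' One imaged field of one well: a set of registered [channel_image()]s
#' sharing shape and pixel size, plus the treatment applied to the well.
#' The `nfat` channel is optional; `nuclei`, `wholecell` and `avb3` are
#' required.
#'
#' @param well_id plate coordinate, e.g. `"B07"`.
#' @param field_id integer field index within the well.
#' @param channels named list of [channel_image()]s.
#' @param treatment named list or vector with elements `rankl` and `mcsf`
#'   (ng/ml) and `time_h` (hours).
#' @return an object of class `field_image`.
#' @export
field_image <- function(well_id, field_id, channels,
                        treatment = list(rankl = NA_real_, mcsf = NA_real_,
                                         time_h = NA_real_)) {
  stopifnot(is.list(channels))
  need <- setdiff(c("nuclei", "wholecell", "avb3"), names(channels))
  if (length(need))
    stop("field_image: missing required channel(s): ",
         paste(need, collapse = ", "))
  dims <- lapply(channels, function(ch) dim(ch$pixels))
  px <- vapply(channels, function(ch) ch$pixel_size, numeric(1))
  if (length(unique(dims)) != 1L || length(unique(px)) != 1L)
    stop("field_image: all channels must share shape and pixel_size")
  structure(list(well_id = well_id, field_id = as.integer(field_id),
                 channels = channels, treatment = as.list(treatment)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]]$pixels)
  cat(sprintf("<field_image> well %s field %d  %d x %d px  channels: %s\n",
              x$well_id, x$field_id, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  tr <- x$treatment
  cat(sprintf("  treatment: RANKL %s ng/ml, MCSF %s ng/ml, t = %s h\n",
              tr$rankl, tr$mcsf, tr$time_h))
  invisible(x)
}
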