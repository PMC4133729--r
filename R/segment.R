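#' Segment nuclei from the Hoechst channel
#'
#' Nuclei are the 8-connected components of the nuclei channel above an
#' intensity threshold, with components below a minimum physical area
#' removed. Touching nuclei are deliberately not split (no watershed) so
#' that the merged-nuclei error mode of threshold-based counting is
#' reproduced; an optional distance-transform watershed splitter is
#' available via `split_touching = TRUE`. Components touching the field
#' border are kept and flagged.
#'
#' @param img a [channel_image()] with `channel == "nuclei"`.
#' @param threshold `"otsu"` (default; per-field Otsu threshold) or a
#'   fixed intensity value.
#' @param min_area minimum component area in um^2.
#' @param split_touching if `TRUE`, apply a distance-transform watershed
#'   to split touching nuclei.
#' @return an object of class `oc_segmentation`: list with `labels`
#'   (integer label matrix), `table` (data frame: id, area_px, area_um2,
#'   centroid_r, centroid_c (0-based), border), `threshold` (value
#'   used), `channel`, `pixel_size`.
#' @export
segment_nuclei <- function(img, threshold = "otsu", min_area = 10,
                           split_touching = FALSE) {
  .segment_channel(img, "nuclei", threshold, min_area, split_touching)
}

#' Segment candidate osteoclast cytoplasm from the marker channel
#'
#' Candidate osteoclast cytoplasm regions are the 8-connected components
#' of the alpha-v-beta-3 (CD51/CD61) channel above an intensity
#' threshold, filtered by a minimum physical area.
#'
#' @inheritParams segment_nuclei
#' @param img a [channel_image()] with `channel == "avb3"`.
#' @param min_area minimum region area in um^2 (default 100).
#' @return an `oc_segmentation` object (see [segment_nuclei()]).
#' @export
segment_avb3_regions <- function(img, threshold = "otsu", min_area = 100) {
  .segment_channel(img, "avb3", threshold, min_area, FALSE)
}

.segment_channel <- function(img, expect, threshold, min_area,
                             split_touching) {
  if (!inherits(img, "channel_image"))
    stop("expected a channel_image")
  if (img$channel != expect)
    stop(sprintf("channel mismatch: expected '%s' channel, got '%s'",
                 expect, img$channel))
  th <- if (identical(threshold, "otsu")) otsu_threshold(img$pixels)
        else as.numeric(threshold)
  mask <- img$pixels > th
  labels <- label_components(mask)
  if (split_touching && max(labels) > 0L) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    labels <- matrix(as.integer(EBImage::imageData(ws)), nrow = nrow(mask))
  }
  min_area_px <- min_area / img$pixel_size^2
  fc <- filter_components(labels, min_area_px)
  tab <- fc$table
  tab$area_um2 <- tab$area_px * img$pixel_size^2
  tab <- tab[, c("id", "area_px", "area_um2", "centroid_r", "centroid_c",
                 "border")]
  structure(list(labels = fc$labels, table = tab, threshold = th,
                 channel = img$channel, pixel_size = img$pixel_size),
            class = "oc_segmentation")
}

#' @export
print.oc_segmentation <- function(x, ...) {
  cat(sprintf("<oc_segmentation> %s: %d components (threshold %.4g)\n",
              x$channel, nrow(x$table), x$threshold))
  invisible(x)
}

#' Classify nuclei as osteoclastic or monocytic
#'
#' A nucleus is osteoclastic if and only if its centroid lies inside an
#' alpha-v-beta-3-positive region that contains at least two nucleus
#' centroids; every such region becomes an osteoclast record. All other
#' nuclei -- including the single occupant of a marker-positive region
#' with only one nucleus, and nuclei outside any region -- are
#' monocytic. Marker regions containing no nucleus are discarded.
#'
#' @param nuc_seg nuclei segmentation from [segment_nuclei()].
#' @param oc_seg marker-region segmentation from
#'   [segment_avb3_regions()].
#' @return list with `nuclei` (data frame: id, centroid_r, centroid_c,
#'   area_px, area_um2, class (`"osteoclastic"`/`"monocytic"`),
#'   parent_osteoclast_id, border, mean_nfat (NA), nfat_call
#'   (`"ungated"`)), `osteoclasts` (data frame: id, region_id, area_um2,
#'   n_nuclei), and the two input label matrices.
#' @export
classify_nuclei <- function(nuc_seg, oc_seg) {
  stopifnot(inherits(nuc_seg, "oc_segmentation"),
            inherits(oc_seg, "oc_segmentation"))
  if (!identical(dim(nuc_seg$labels), dim(oc_seg$labels)) ||
      nuc_seg$pixel_size != oc_seg$pixel_size)
    stop("segmentations do not share geometry")
  nt <- nuc_seg$table
  region <- label_at(oc_seg$labels, nt$centroid_r, nt$centroid_c)
  occupancy <- tabulate(region[region > 0L], nbins = max(oc_seg$labels, 0L))
  oc_regions <- which(occupancy >= 2L)
  is_oc <- region %in% oc_regions
  oc_ids <- match(region, oc_regions)       # NA for monocytic
  nuclei <- data.frame(
    id = nt$id, centroid_r = nt$centroid_r, centroid_c = nt$centroid_c,
    area_px = nt$area_px, area_um2 = nt$area_um2,
    class = ifelse(is_oc, "osteoclastic", "monocytic"),
    parent_osteoclast_id = ifelse(is_oc, oc_ids, NA_integer_),
    border = nt$border, mean_nfat = NA_real_, nfat_call = "ungated",
    stringsAsFactors = FALSE)
  osteoclasts <- data.frame(
    id = seq_along(oc_regions), region_id = oc_regions,
    area_um2 = oc_seg$table$area_um2[match(oc_regions, oc_seg$table$id)],
    n_nuclei = occupancy[oc_regions])
  list(nuclei = nuclei, osteoclasts = osteoclasts,
       nucleus_labels = nuc_seg$labels, region_labels = oc_seg$labels)
}

#' Attach precursor cytoplasm to monocytic nuclei
#'
#' Each monocytic nucleus receives the thresholded whole-cell component
#' surrounding its centroid; when several monocytic nuclei share one
#' component its pixels are partitioned by nearest-nucleus (Euclidean
#' centroid distance) assignment, so the per-nucleus cytoplasm masks are
#' disjoint and their union is the shared component. A nucleus whose
#' centroid has no supra-threshold whole-cell pixel falls back to its
#' own nucleus mask and is flagged.
#'
#' @param classified result of [classify_nuclei()].
#' @param img a [channel_image()] with `channel == "wholecell"`.
#' @param threshold `"otsu"` or a fixed intensity.
#' @return list with `cytoplasm_labels` (integer matrix; value = nucleus
#'   id owning the pixel, 0 elsewhere) and `table` (data frame: id,
#'   area_um2, fallback).
#' @export
attach_monocyte_cytoplasm <- function(classified, img, threshold = "otsu") {
  if (!inherits(img, "channel_image") || img$channel != "wholecell")
    stop("channel mismatch: expected 'wholecell' channel")
  nuc <- classified$nuclei
  mono <- nuc[nuc$class == "monocytic", , drop = FALSE]
  out <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  tab <- data.frame(id = mono$id, area_um2 = NA_real_, fallback = FALSE)
  if (!nrow(mono)) return(list(cytoplasm_labels = out, table = tab))
  th <- if (identical(threshold, "otsu")) otsu_threshold(img$pixels)
        else as.numeric(threshold)
  wc <- label_components(img$pixels > th)
  comp <- label_at(wc, mono$centroid_r, mono$centroid_c)
  for (cmp in unique(comp[comp > 0L])) {
    members <- which(comp == cmp)
    idx <- which(wc == cmp)
    rr <- (idx - 1L) %% nrow(wc); cc <- (idx - 1L) %/% nrow(wc)
    d2 <- vapply(members, function(m)
      (rr - mono$centroid_r[m])^2 + (cc - mono$centroid_c[m])^2,
      numeric(length(idx)))
    owner <- mono$id[members[max.col(-matrix(d2, ncol = length(members)),
                                    ties.method = "first")]]
    out[idx] <- owner
  }
  ## fallback: nucleus mask for nuclei outside any supra-threshold blob
  orphans <- mono$id[comp == 0L]
  if (length(orphans)) {
    nl <- classified$nucleus_labels
    for (id in orphans) out[nl == id] <- id
    tab$fallback[tab$id %in% orphans] <- TRUE
  }
  area <- tabulate(out[out > 0L], nbins = max(nuc$id))
  tab$area_um2 <- area[tab$id] * img$pixel_size^2
  list(cytoplasm_labels = out, table = tab)
}

#' Measure mean nuclear NFATc1 intensity
#'
#' Sets `mean_nfat` on every nucleus record to the arithmetic mean of
#' the NFAT-channel pixels under the nucleus mask.
#'
#' @param classified result of [classify_nuclei()].
#' @param img a [channel_image()] with `channel == "nfat"`.
#' @return `classified` with `nuclei$mean_nfat` filled in.
#' @export
measure_nuclear_nfat <- function(classified, img) {
  if (!inherits(img, "channel_image") || img$channel != "nfat")
    stop("channel mismatch: expected 'nfat' channel")
  nl <- classified$nucleus_labels
  if (!identical(dim(nl), dim(img$pixels)))
    stop("nfat channel does not share geometry with the segmentation")
  n <- max(nl)
  if (n > 0L) {
    idx <- which(nl > 0L)
    sums <- rowsum(img$pixels[idx], nl[idx])
    cnt <- tabulate(nl[idx], nbins = n)
    if (any(cnt[classified$nuclei$id] == 0L))
      stop("empty nucleus mask encountered")
    means <- as.numeric(sums[, 1]) / cnt[as.integer(rownames(sums))]
    classified$nuclei$mean_nfat <-
      means[match(classified$nuclei$id, as.integer(rownames(sums)))]
  }
  classified
}

#' Quantify one field end to end
#'
#' Convenience wrapper: segments nuclei and marker regions, classifies
#' nuclei, and (when the field carries an `nfat` channel) measures mean
#' nuclear NFATc1.
#'
#' @param field a [field_image()].
#' @param nuclei_threshold,avb3_threshold `"otsu"` or fixed intensities.
#' @param min_nucleus_area,min_region_area area floors in um^2.
#' @param split_touching see [segment_nuclei()].
#' @return the [classify_nuclei()] result, augmented with `well_id`,
#'   `field_id`, `treatment` and the thresholds used.
#' @export
quantify_field <- function(field, nuclei_threshold = "otsu",
                           avb3_threshold = "otsu",
                           min_nucleus_area = 10, min_region_area = 100,
                           split_touching = FALSE) {
  stopifnot(inherits(field, "field_image"))
  ns <- segment_nuclei(field$channels$nuclei, nuclei_threshold,
                       min_nucleus_area, split_touching)
  os <- segment_avb3_regions(field$channels$avb3, avb3_threshold,
                             min_region_area)
  cl <- classify_nuclei(ns, os)
  if (!is.null(field$channels$nfat))
    cl <- measure_nuclear_nfat(cl, field$channels$nfat)
  cl$well_id <- field$well_id
  cl$field_id <- field$field_id
  cl$treatment <- field$treatment
  cl$thresholds <- c(nuclei = ns$threshold, avb3 = os$threshold)
  cl$pixel_size <- field$channels$nuclei$pixel_size
  cl
}

#' Aggregate quantified fields of one well
#'
#' Sums nucleus and osteoclast counts over all quantified fields of a
#' well and derives the per-well readouts: total / monocyte / osteoclast
#' nuclei, osteoclast count, and cytoplasm area per nucleus (total
#' osteoclast cytoplasm area divided by total osteoclast nuclei; the
#' per-cell mean of area/nuclei is available via
#' `area_per_nucleus = "per_cell_mean"`). NFAT positivity columns are
#' `NA` until [classify_nfat()] has been applied.
#'
#' @param fields list of [quantify_field()] results from one well.
#' @param area_per_nucleus `"pooled"` (default) or `"per_cell_mean"`.
#' @return one-row data frame (a well summary): well_id, rankl, mcsf,
#'   time_h, total_nuclei, monocyte_nuclei, osteoclast_nuclei,
#'   n_osteoclasts, cytoplasm_area_per_nucleus, nfat_pos_monocytes,
#'   nfat_pos_fraction.
#' @export
summarize_well <- function(fields, area_per_nucleus = c("pooled",
                                                        "per_cell_mean")) {
  area_per_nucleus <- match.arg(area_per_nucleus)
  stopifnot(length(fields) >= 1L)
  wells <- unique(vapply(fields, `[[`, character(1), "well_id"))
  if (length(wells) != 1L)
    stop("summarize_well: fields from more than one well: ",
         paste(wells, collapse = ", "))
  tr <- unique(t(vapply(fields, function(f)
    unlist(f$treatment[c("rankl", "mcsf", "time_h")]), numeric(3))))
  if (nrow(tr) != 1L)
    stop("summarize_well: mixed treatments within well ", wells)
  nuclei <- do.call(rbind, lapply(fields, `[[`, "nuclei"))
  ocs <- do.call(rbind, lapply(fields, `[[`, "osteoclasts"))
  n_mono <- sum(nuclei$class == "monocytic")
  n_oc_nuc <- sum(nuclei$class == "osteoclastic")
  capn <- if (is.null(ocs) || !nrow(ocs)) NA_real_
  else if (area_per_nucleus == "pooled") sum(ocs$area_um2) / sum(ocs$n_nuclei)
  else mean(ocs$area_um2 / ocs$n_nuclei)
  gated <- nuclei$class == "monocytic" & nuclei$nfat_call != "ungated"
  npos <- if (any(gated)) sum(nuclei$nfat_call[gated] == "pos") else NA_integer_
  data.frame(well_id = wells, rankl = unname(tr[1, 1]),
             mcsf = unname(tr[1, 2]), time_h = unname(tr[1, 3]),
             row.names = NULL,
             total_nuclei = nrow(nuclei),
             monocyte_nuclei = n_mono,
             osteoclast_nuclei = n_oc_nuc,
             n_osteoclasts = if (is.null(ocs)) 0L else nrow(ocs),
             cytoplasm_area_per_nucleus = capn,
             nfat_pos_monocytes = npos,
             nfat_pos_fraction = if (is.na(npos) || n_mono == 0) NA_real_
                                 else npos / n_mono,
             stringsAsFactors = FALSE)
}
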