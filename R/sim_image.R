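#' Parameters for the synthetic culture-field generator
#'
#' Describes one simulated imaging field of a differentiating osteoclast
#' culture: small mononuclear precursors ("monocytes") plus large
#' multinucleated, marker-positive osteoclasts. Osteoclast morphology
#' defaults follow the reported heterogeneity of cultured human
#' osteoclasts: 3--20 nuclei per cell and 20--500 um cell diameter (the
#' diameter range is truncated so a cell fits in the field, and inflated
#' to the minimum packing diameter its sampled nuclei count requires).
#'
#' @param field_shape integer 2-vector, image size in pixels (rows, cols).
#' @param pixel_size physical pixel size, um/pixel.
#' @param n_monocytes number of mononuclear (monocytic) nuclei.
#' @param n_osteoclasts number of multinucleated osteoclasts.
#' @param oc_nuclei_range integer interval, nuclei per osteoclast
#'   (minimum >= 2).
#' @param oc_diameter_range osteoclast diameter interval in um.
#' @param nucleus_radius nucleus radius in um.
#' @param nfat_positive_fraction fraction of monocytic nuclei carrying the
#'   nuclear-NFATc1-positive label (exactly `round(f * n_monocytes)` nuclei
#'   are labelled positive).
#' @param intensity_model list with elements `background` (all channels),
#'   `foreground` (named: nuclei, wholecell, avb3), `nfat_level_neg`,
#'   `nfat_level_pos` (per-nucleus mean NFAT levels), `nfat_nucleus_sd`
#'   (named: neg, pos; between-nucleus sd of those levels), `noise_sd`
#'   (additive Gaussian pixel noise) and `shot_noise` (logical; Poisson
#'   resampling of each pixel).
#' @param overlap_fraction target fraction of monocytic nuclei placed as
#'   touching pairs (centroid distance < 2 x radius), the generator's
#'   analogue of the merged-nuclei error mode of automated counting.
#'   `round(overlap_fraction * n_monocytes / 2)` pairs are planted.
#' @param seed integer RNG seed; identical parameters give bit-identical
#'   output.
#' @return an object of class `sim_image_params`.
#' @seealso [simulate_field()]
#' @export
sim_image_params <- function(field_shape = c(512L, 512L),
                             pixel_size = 1,
                             n_monocytes = 120,
                             n_osteoclasts = 3,
                             oc_nuclei_range = c(3L, 20L),
                             oc_diameter_range = c(20, 500),
                             nucleus_radius = 4,
                             nfat_positive_fraction = 0.35,
                             intensity_model = list(),
                             overlap_fraction = 0,
                             seed = 1L) {
  im <- modifyList(list(
    background = 100,
    foreground = c(nuclei = 600, wholecell = 300, avb3 = 450),
    nfat_level_neg = 160, nfat_level_pos = 500,
    nfat_nucleus_sd = c(neg = 20, pos = 45),
    noise_sd = 20, shot_noise = FALSE), intensity_model)
  p <- list(field_shape = as.integer(field_shape), pixel_size = pixel_size,
            n_monocytes = as.integer(n_monocytes),
            n_osteoclasts = as.integer(n_osteoclasts),
            oc_nuclei_range = as.integer(oc_nuclei_range),
            oc_diameter_range = oc_diameter_range,
            nucleus_radius = nucleus_radius,
            nfat_positive_fraction = nfat_positive_fraction,
            intensity_model = im,
            overlap_fraction = overlap_fraction,
            seed = as.integer(seed))
  stopifnot(length(p$field_shape) == 2L, all(p$field_shape >= 32L),
            p$pixel_size > 0,
            p$n_monocytes >= 0L, p$n_osteoclasts >= 0L,
            length(p$oc_nuclei_range) == 2L,
            p$oc_nuclei_range[1] >= 2L,
            p$oc_nuclei_range[2] >= p$oc_nuclei_range[1],
            length(p$oc_diameter_range) == 2L,
            p$oc_diameter_range[2] >= p$oc_diameter_range[1],
            p$oc_diameter_range[1] > 0,
            p$nucleus_radius > 0,
            p$nfat_positive_fraction >= 0, p$nfat_positive_fraction <= 1,
            p$overlap_fraction >= 0, p$overlap_fraction <= 1,
            im$noise_sd >= 0)
  class(p) <- "sim_image_params"
  p
}

## -- placement ---------------------------------------------------------

## Sequential placement of points with a minimum pairwise distance, an
## optional per-point rectangular margin and arbitrary extra predicate.
.place_points <- function(n, nr, nc, margin, min_dist, existing,
                          accept = NULL, what = "nuclei",
                          max_tries = 400L) {
  pts <- existing
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- runif(1, 1 + margin, nr - margin)
      c <- runif(1, 1 + margin, nc - margin)
      if (nrow(pts)) {
        d2 <- (pts[, 1] - r)^2 + (pts[, 2] - c)^2
        if (min(d2) < min_dist^2) next
      }
      if (!is.null(accept) && !accept(r, c)) next
      pts <- rbind(pts, c(r, c)); out <- rbind(out, c(r, c))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("placement error: could not place %s %d of %d in a ",
                          "%d x %d field (min distance %.1f px, margin %.1f px); ",
                          "reduce counts or enlarge the field"),
                   what, i, n, nr, nc, min_dist, margin))
  }
  out
}

## Soft-edged disc written into `img` (pmax composition). 1-based centre.
.render_disc <- function(img, r0, c0, radius, value, edge = 0.7) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- ceiling(radius + 4 * edge)
  rs <- max(1, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  d <- sqrt(outer((rs - r0)^2, (cs - c0)^2, `+`))
  img[rs, cs] <- pmax(img[rs, cs], value / (1 + exp((d - radius) / edge)))
  img
}

## Irregular smooth blob mask (cosine-perturbed disc). Returns a logical
## matrix of the full field.
.blob_mask <- function(nr, nc, r0, c0, radius, amp, phase) {
  ext <- ceiling(radius * (1 + sum(amp)) + 2)
  rs <- max(1, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  dr <- rs - r0; dc <- cs - c0
  d <- sqrt(outer(dr^2, dc^2, `+`))
  th <- atan2(matrix(rep(dc, each = length(dr)), length(dr)),
              matrix(rep(dr, times = length(dc)), length(dr)))
  rb <- radius * (1 + Reduce(`+`, lapply(seq_along(amp), function(h)
    amp[h] * cos((h + 1) * th + phase[h]))))
  mask <- matrix(FALSE, nr, nc)
  mask[rs, cs] <- d <= rb
  mask
}

## -- generator ---------------------------------------------------------

#' Generate one ground-truthed synthetic culture field
#'
#' Renders the four registered fluorescence channels of a simulated
#' osteoclast culture field (nuclei, whole-cell, alpha-v-beta-3 marker,
#' NFATc1) together with the exact ground truth of every nucleus and
#' osteoclast. Osteoclasts are irregular marker-positive blobs enclosing
#' their own nuclei; monocytic nuclei lie outside all marker-positive
#' regions and carry a whole-cell halo; the NFAT channel is elevated only
#' over nuclei labelled NFAT-positive, with a bimodal between-nucleus
#' level distribution. Identical parameters (including seed) give
#' bit-identical output.
#'
#' @param params a [sim_image_params()] object.
#' @param well_id,field_id identifiers stored on the returned field.
#' @param treatment treatment metadata stored on the returned field.
#' @return a list with components `field` (a [field_image()]) and `truth`
#'   (list: `nuclei` data frame -- id, centroid_r, centroid_c (0-based
#'   pixels), radius_um, class, nfat_label, parent_osteoclast_id,
#'   pair_id; `osteoclasts` data frame -- id, n_nuclei, area_um2;
#'   `params`).
#' @export
simulate_field <- function(params, well_id = "A01", field_id = 1L,
                           treatment = list(rankl = 33, mcsf = 33,
                                            time_h = 168)) {
  stopifnot(inherits(params, "sim_image_params"))
  with_seed(params$seed, .simulate_field_impl(params, well_id, field_id,
                                              treatment))
}

.simulate_field_impl <- function(p, well_id, field_id, treatment) {
  nr <- p$field_shape[1]; nc <- p$field_shape[2]
  px <- p$pixel_size
  r_nuc <- p$nucleus_radius / px              # px
  sep <- 2.9 * r_nuc                          # non-touching centre distance
  im <- p$intensity_model

  ## --- osteoclast geometry ---
  oc <- list()
  oc_centres <- matrix(numeric(0), ncol = 2)
  if (p$n_osteoclasts > 0L) {
    for (i in seq_len(p$n_osteoclasts)) {
      ks <- seq(p$oc_nuclei_range[1], p$oc_nuclei_range[2])
      k <- ks[sample.int(length(ks), 1L)]
      d_um <- runif(1, p$oc_diameter_range[1], p$oc_diameter_range[2])
      ## minimum diameter so k separated nuclei fit inside 0.62 R
      ## (0.35 packing fraction leaves room for sequential placement)
      d_min <- sep * sqrt(k / 0.35) * px / 0.7
      d_um <- max(d_um, d_min)
      ## per-cell cap: fit the field and keep the total osteoclast
      ## footprint below ~30% of the field area
      d_cap <- min(0.45 * min(nr, nc),
                   2 * sqrt(0.25 * nr * nc / (p$n_osteoclasts * pi)) / 1.25) * px
      if (d_min > d_cap)
        stop(sprintf(paste0("placement error: osteoclast with %d nuclei needs ",
                            "diameter %.0f um but the field only admits %.0f um; ",
                            "enlarge field_shape or reduce oc_nuclei_range"),
                     k, d_min, d_cap))
      d_um <- min(d_um, d_cap)
      R <- d_um / 2 / px                       # px
      margin <- R * 1.25 + 2
      ok <- FALSE
      for (try in 1:800) {
        r0 <- runif(1, 1 + margin, nr - margin)
        c0 <- runif(1, 1 + margin, nc - margin)
        if (nrow(oc_centres)) {
          dmin <- sqrt(min((oc_centres[, 1] - r0)^2 + (oc_centres[, 2] - c0)^2))
          prevR <- vapply(oc, function(o) o$R, numeric(1))
          if (dmin < 1.28 * (R + max(prevR)) + sep) next
        }
        ok <- TRUE; break
      }
      if (!ok)
        stop(sprintf(paste0("placement error: could not place osteoclast %d ",
                            "(radius %.0f px) in a %d x %d field"),
                     i, R, nr, nc))
      oc_centres <- rbind(oc_centres, c(r0, c0))
      ## sample nucleus positions directly inside the cell body
      nuc <- matrix(numeric(0), ncol = 2)
      for (j in seq_len(k)) {
        placed <- FALSE
        for (try in 1:400) {
          d <- 0.7 * R * sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
          cand <- c(r0 + d * cos(ang), c0 + d * sin(ang))
          if (nrow(nuc) &&
              min((nuc[, 1] - cand[1])^2 + (nuc[, 2] - cand[2])^2) < sep^2)
            next
          nuc <- rbind(nuc, cand); placed <- TRUE; break
        }
        if (!placed)
          stop(sprintf(paste0("placement error: could not place nucleus %d of %d ",
                              "inside osteoclast %d (radius %.0f px, min distance ",
                              "%.1f px); reduce oc_nuclei_range or enlarge ",
                              "oc_diameter_range"), j, k, i, R, sep))
      }
      oc[[i]] <- list(id = i, r0 = r0, c0 = c0, R = R, k = k,
                      amp = runif(3, 0.02, 0.06),
                      phase = runif(3, 0, 2 * pi), nuclei = nuc)
    }
  }

  ## --- monocytic nuclei ---
  oc_excl <- function(r, c) {
    if (!nrow(oc_centres)) return(TRUE)
    Rb <- vapply(oc, function(o) o$R * 1.25, numeric(1))
    all((oc_centres[, 1] - r)^2 + (oc_centres[, 2] - c)^2 >
          (Rb + 2.2 * r_nuc)^2)
  }
  all_nuc <- do.call(rbind, c(list(matrix(numeric(0), ncol = 2)),
                              lapply(oc, `[[`, "nuclei")))
  n_pairs <- round(p$overlap_fraction * p$n_monocytes / 2)
  n_single <- p$n_monocytes - 2L * n_pairs
  mono <- matrix(numeric(0), ncol = 2)
  pair_id <- integer(0)
  if (n_single > 0L) {
    pts <- .place_points(n_single, nr, nc, margin = r_nuc + 2,
                         min_dist = sep, existing = all_nuc,
                         accept = oc_excl, what = "monocyte nucleus")
    mono <- rbind(mono, pts); pair_id <- c(pair_id, rep(NA_integer_, n_single))
    all_nuc <- rbind(all_nuc, pts)
  }
  if (n_pairs > 0L) {
    for (j in seq_len(n_pairs)) {
      placed <- FALSE
      for (try in 1:400) {
        r1 <- runif(1, 1 + r_nuc + 2, nr - r_nuc - 2)
        c1 <- runif(1, 1 + r_nuc + 2, nc - r_nuc - 2)
        ang <- runif(1, 0, 2 * pi)
        dd <- 1.4 * r_nuc                     # touching: < 2 x radius
        r2 <- r1 + dd * cos(ang); c2 <- c1 + dd * sin(ang)
        if (r2 < 1 + r_nuc + 2 || r2 > nr - r_nuc - 2 ||
            c2 < 1 + r_nuc + 2 || c2 > nc - r_nuc - 2) next
        if (nrow(all_nuc)) {
          d2a <- min((all_nuc[, 1] - r1)^2 + (all_nuc[, 2] - c1)^2)
          d2b <- min((all_nuc[, 1] - r2)^2 + (all_nuc[, 2] - c2)^2)
          if (min(d2a, d2b) < sep^2) next
        }
        if (!oc_excl(r1, c1) || !oc_excl(r2, c2)) next
        mono <- rbind(mono, c(r1, c1), c(r2, c2))
        pair_id <- c(pair_id, j, j)
        all_nuc <- rbind(all_nuc, c(r1, c1), c(r2, c2))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("placement error: could not place touching nucleus pair %d of %d",
                     j, n_pairs))
    }
  }

  ## --- ground truth tables ---
  oc_nuc_n <- if (length(oc)) sum(vapply(oc, `[[`, numeric(1), "k")) else 0L
  n_total <- nrow(mono) + oc_nuc_n
  nuclei <- data.frame(id = seq_len(n_total),
                       centroid_r = numeric(n_total),
                       centroid_c = numeric(n_total),
                       radius_um = rep(p$nucleus_radius, n_total),
                       class = character(n_total),
                       nfat_label = character(n_total),
                       parent_osteoclast_id = rep(NA_integer_, n_total),
                       pair_id = rep(NA_integer_, n_total),
                       stringsAsFactors = FALSE)
  idx <- 0L
  for (o in oc) {
    rows <- idx + seq_len(o$k)
    nuclei$centroid_r[rows] <- o$nuclei[, 1] - 1
    nuclei$centroid_c[rows] <- o$nuclei[, 2] - 1
    nuclei$class[rows] <- "osteoclast"
    nuclei$nfat_label[rows] <- "pos"
    nuclei$parent_osteoclast_id[rows] <- o$id
    idx <- idx + o$k
  }
  if (nrow(mono)) {
    rows <- idx + seq_len(nrow(mono))
    nuclei$centroid_r[rows] <- mono[, 1] - 1
    nuclei$centroid_c[rows] <- mono[, 2] - 1
    nuclei$class[rows] <- "monocyte"
    n_pos <- round(p$nfat_positive_fraction * nrow(mono))
    lab <- rep("neg", nrow(mono))
    if (n_pos > 0) lab[sample(nrow(mono), n_pos)] <- "pos"
    nuclei$nfat_label[rows] <- lab
    nuclei$pair_id[rows] <- pair_id
  }

  ## --- rendering ---
  fg_nuclei <- matrix(0, nr, nc)
  fg_whole  <- matrix(0, nr, nc)
  fg_avb3   <- matrix(0, nr, nc)
  fg_nfat   <- matrix(0, nr, nc)
  oc_truth <- data.frame(id = integer(), n_nuclei = integer(),
                         area_um2 = numeric())
  for (o in oc) {
    mask <- .blob_mask(nr, nc, o$r0, o$c0, o$R, o$amp, o$phase)
    fg_avb3[mask] <- im$foreground[["avb3"]]
    fg_whole[mask] <- pmax(fg_whole[mask], im$foreground[["wholecell"]])
    oc_truth <- rbind(oc_truth,
                      data.frame(id = o$id, n_nuclei = o$k,
                                 area_um2 = sum(mask) * px^2))
  }
  for (i in seq_len(n_total)) {
    r0 <- nuclei$centroid_r[i] + 1; c0 <- nuclei$centroid_c[i] + 1
    fg_nuclei <- .render_disc(fg_nuclei, r0, c0, r_nuc,
                              im$foreground[["nuclei"]])
    lvl_sd <- im$nfat_nucleus_sd[[nuclei$nfat_label[i]]]
    lvl_mu <- if (nuclei$nfat_label[i] == "pos") im$nfat_level_pos
              else im$nfat_level_neg
    lvl <- max(0, rnorm(1, lvl_mu, lvl_sd))
    fg_nfat <- .render_disc(fg_nfat, r0, c0, r_nuc, lvl)
    if (nuclei$class[i] == "monocyte")
      fg_whole <- .render_disc(fg_whole, r0, c0, 2.3 * r_nuc,
                               im$foreground[["wholecell"]], edge = 1.2)
  }

  finish <- function(fg) {
    x <- im$background + as.numeric(EBImage::imageData(
      EBImage::gblur(EBImage::Image(fg), sigma = 0.7)))
    x <- matrix(x, nr, nc)
    if (im$shot_noise) x <- matrix(rpois(length(x), pmax(x, 0)), nr, nc)
    if (im$noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, im$noise_sd),
                                         nr, nc)
    pmax(x, 0)
  }
  channels <- list(
    nuclei    = channel_image(finish(fg_nuclei), "nuclei", px),
    wholecell = channel_image(finish(fg_whole), "wholecell", px),
    avb3      = channel_image(finish(fg_avb3), "avb3", px),
    nfat      = channel_image(finish(fg_nfat), "nfat", px))

  list(field = field_image(well_id, field_id, channels, treatment),
       truth = list(nuclei = nuclei, osteoclasts = oc_truth, params = p))
}
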