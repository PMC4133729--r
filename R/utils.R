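`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Otsu threshold for an arbitrary-scale intensity matrix
#'
#' Rescales the image to `[0, 1]`, applies Otsu's between-class-variance
#' criterion on a 256-level histogram (via \pkg{EBImage}), and maps the
#' threshold back to the original intensity scale. Used as the default
#' "auto" threshold for every channel.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @return a single threshold on the intensity scale of `pixels`.
#' @export
otsu_threshold <- function(pixels) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  lo <- min(pixels); hi <- max(pixels)
  if (hi <= lo) return(hi)  # constant image: nothing above threshold
  x <- (pixels - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  lo + th * (hi - lo)
}

## 8-connected component labelling. EBImage::bwlabel is 8-connected on this
## platform; we assert that once at load time would be brittle, so we instead
## keep labelling behind this wrapper.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
}

## Per-component features of a label matrix: pixel area, centroid (0-based,
## row/col), border contact. Returns a data.frame ordered by label id.
component_features <- function(labels) {
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(id = integer(), area_px = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      border = logical()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels)        # 0-based row
  cc <- (idx - 1L) %/% nrow(labels)       # 0-based col
  area <- tabulate(lab, nbins = n)
  sum_r <- rowsum(as.numeric(rr), lab)[, 1]
  sum_c <- rowsum(as.numeric(cc), lab)[, 1]
  on_border <- rr == 0L | rr == nrow(labels) - 1L |
    cc == 0L | cc == ncol(labels) - 1L
  border <- as.logical(rowsum(as.numeric(on_border), lab)[, 1] > 0)
  data.frame(id = seq_len(n), area_px = area,
             centroid_r = sum_r / area, centroid_c = sum_c / area,
             border = border)
}

## Drop components below a pixel-area floor and relabel 1..k (stable order).
filter_components <- function(labels, min_area_px) {
  feats <- component_features(labels)
  keep <- feats$id[feats$area_px >= min_area_px]
  remap <- integer(max(labels, 1L))
  remap[keep] <- seq_along(keep)
  out <- labels
  out[out > 0L] <- remap[out[out > 0L]]
  list(labels = out, table = {
    t <- feats[feats$id %in% keep, , drop = FALSE]
    t$id <- seq_along(keep)
    rownames(t) <- NULL
    t
  })
}

## Label id at a (0-based) centroid, 0 if background / outside.
label_at <- function(labels, r, c) {
  i <- round(r) + 1L; j <- round(c) + 1L
  ok <- i >= 1L & i <= nrow(labels) & j >= 1L & j <= ncol(labels)
  out <- integer(length(r))
  out[ok] <- labels[cbind(i[ok], j[ok])]
  out
}
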