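## Shared fixture builders. Everything is generated in code; no files.

## Clean (noise-free, non-overlapping) field parameters: the regime in
## which segmentation must recover the ground truth exactly.
clean_params <- function(n_monocytes = 25, n_osteoclasts = 1, seed = 1,
                         ...) {
  sim_image_params(field_shape = c(256L, 256L),
                   n_monocytes = n_monocytes,
                   n_osteoclasts = n_osteoclasts,
                   oc_nuclei_range = c(3L, 5L),
                   intensity_model = list(noise_sd = 0),
                   overlap_fraction = 0, seed = seed, ...)
}

## Hand-built classified object: a label matrix with two 3x3 square
## "nuclei" plus an uniform field geometry, for direct method tests.
toy_classified <- function(nr = 24, nc = 24) {
  labels <- matrix(0L, nr, nc)
  labels[3:5, 3:5] <- 1L
  labels[10:12, 15:17] <- 2L
  nuclei <- data.frame(
    id = 1:2,
    centroid_r = c(3, 10), centroid_c = c(3, 15),
    area_px = c(9L, 9L), area_um2 = c(9, 9),
    class = c("monocytic", "monocytic"),
    parent_osteoclast_id = NA_integer_, border = FALSE,
    mean_nfat = NA_real_, nfat_call = "ungated",
    stringsAsFactors = FALSE)
  list(nuclei = nuclei,
       osteoclasts = data.frame(id = integer(), region_id = integer(),
                                area_um2 = numeric(), n_nuclei = integer()),
       nucleus_labels = labels,
       region_labels = matrix(0L, nr, nc))
}

## Random PLSR problem on the scale the panel stage uses.
random_pls_problem <- function(n, p, m = 2, seed = 1) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n, p)),
       Y = matrix(rnorm(n * m), n, m))
}
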