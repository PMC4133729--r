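test_that("noise-free fields are segmented exactly (generator oracle)", {
  s <- simulate_field(clean_params(n_monocytes = 20, n_osteoclasts = 0,
                                   seed = 21))
  seg <- segment_nuclei(s$field$channels$nuclei)
  expect_equal(nrow(seg$table), 20L)
  ## each truth centroid falls in exactly one distinct mask
  lab <- osteoquant:::label_at(seg$labels, s$truth$nuclei$centroid_r,
                               s$truth$nuclei$centroid_c)
  expect_true(all(lab > 0))
  expect_equal(length(unique(lab)), 20L)
})

test_that("a blank image yields no masks, not an error", {
  img <- channel_image(matrix(100, 64, 64), "nuclei")
  seg <- segment_nuclei(img)
  expect_equal(nrow(seg$table), 0L)
})

test_that("touching nuclei merge into one mask (documented error mode)", {
  p <- sim_image_params(field_shape = c(128L, 128L), n_monocytes = 2,
                        n_osteoclasts = 0, overlap_fraction = 1,
                        intensity_model = list(noise_sd = 0), seed = 2)
  s <- simulate_field(p)
  expect_equal(sum(!is.na(s$truth$nuclei$pair_id)), 2L)
  seg <- segment_nuclei(s$field$channels$nuclei)
  expect_equal(nrow(seg$table), 1L)
})

test_that("the optional watershed splitter separates moderately touching nuclei", {
  ## two discs of radius 4 px with centres 7 px apart: one component by
  ## plain labelling (centroid distance < 2 r), two after the splitter
  px <- matrix(0, 64, 64)
  for (ct in list(c(30, 30), c(30, 37)))
    for (i in 1:64) for (j in 1:64)
      if ((i - ct[1])^2 + (j - ct[2])^2 <= 16) px[i, j] <- 500
  img <- channel_image(px, "nuclei")
  expect_equal(nrow(segment_nuclei(img, threshold = 250)$table), 1L)
  expect_equal(nrow(segment_nuclei(img, threshold = 250,
                                   split_touching = TRUE)$table), 2L)
})

test_that("channel mismatch is rejected for both segmenters", {
  img <- channel_image(matrix(1, 8, 8), "wholecell")
  expect_error(segment_nuclei(img), "channel mismatch")
  expect_error(segment_avb3_regions(img), "channel mismatch")
})

test_that("raising threshold or min_area never increases counts", {
  s <- simulate_field(sim_image_params(field_shape = c(256L, 256L),
                                       n_monocytes = 40, n_osteoclasts = 1,
                                       oc_nuclei_range = c(3L, 4L),
                                       seed = 31))
  img <- s$field$channels$nuclei
  base_th <- otsu_threshold(img$pixels)
  counts_th <- vapply(base_th * c(0.8, 1, 1.3, 1.8, 2.4), function(th)
    nrow(segment_nuclei(img, threshold = th)$table), numeric(1))
  expect_true(all(diff(counts_th) <= 0))
  counts_area <- vapply(c(1, 10, 30, 60), function(a)
    nrow(segment_nuclei(img, min_area = a)$table), numeric(1))
  expect_true(all(diff(counts_area) <= 0))
})

test_that("border-touching components are kept and flagged", {
  px <- matrix(0, 64, 64)
  px[1:5, 30:34] <- 500          # touches row 1
  px[30:34, 30:34] <- 500        # interior
  seg <- segment_nuclei(channel_image(px, "nuclei"), threshold = 250,
                        min_area = 1)
  expect_equal(nrow(seg$table), 2L)
  expect_equal(sort(seg$table$border), c(FALSE, TRUE))
})

test_that("marker regions contain their nuclei and respect min_area", {
  s <- simulate_field(clean_params(n_monocytes = 5, n_osteoclasts = 1,
                                   seed = 41))
  seg <- segment_avb3_regions(s$field$channels$avb3)
  expect_equal(nrow(seg$table), 1L)
  oc_nuc <- s$truth$nuclei[s$truth$nuclei$class == "osteoclast", ]
  lab <- osteoquant:::label_at(seg$labels, oc_nuc$centroid_r,
                               oc_nuc$centroid_c)
  expect_true(all(lab == 1L))
  ## a min_area above the region size excludes it
  big <- seg$table$area_um2[1] * 2
  expect_equal(nrow(segment_avb3_regions(s$field$channels$avb3,
                                         min_area = big)$table), 0L)
})
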