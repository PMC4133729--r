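## Build a small geometric scene by hand: one marker region holding two
## nuclei, plus isolated nuclei outside it.
scene <- function() {
  nuc <- matrix(0, 64, 64)
  av <- matrix(0, 64, 64)
  centres <- list(c(20, 20), c(20, 30), c(45, 10), c(45, 30), c(45, 50))
  for (ct in centres)
    nuc[ct[1] + (-2:2), ct[2] + (-2:2)] <- 500
  av[12:28, 12:38] <- 400                       # encloses the first two
  list(nuc = segment_nuclei(channel_image(nuc, "nuclei"), 250, min_area = 1),
       av = segment_avb3_regions(channel_image(av, "avb3"), 200,
                                 min_area = 1))
}

test_that("nuclei in a two-nucleus marker region are osteoclastic, others monocytic", {
  sc <- scene()
  cl <- classify_nuclei(sc$nuc, sc$av)
  expect_equal(sum(cl$nuclei$class == "osteoclastic"), 2L)
  expect_equal(sum(cl$nuclei$class == "monocytic"), 3L)
  expect_equal(nrow(cl$osteoclasts), 1L)
  expect_equal(cl$osteoclasts$n_nuclei, 2L)
  ## every nucleus classified exactly once; parent set iff osteoclastic
  expect_equal(nrow(cl$nuclei), 5L)
  expect_identical(!is.na(cl$nuclei$parent_osteoclast_id),
                   cl$nuclei$class == "osteoclastic")
})

test_that("a single-nucleus marker region yields a monocyte and no osteoclast", {
  nuc <- matrix(0, 64, 64); nuc[20 + (-2:2), 20 + (-2:2)] <- 500
  av <- matrix(0, 64, 64); av[12:28, 12:28] <- 400
  cl <- classify_nuclei(
    segment_nuclei(channel_image(nuc, "nuclei"), 250, min_area = 1),
    segment_avb3_regions(channel_image(av, "avb3"), 200, min_area = 1))
  expect_equal(cl$nuclei$class, "monocytic")
  expect_equal(nrow(cl$osteoclasts), 0L)
})

test_that("no marker regions means every nucleus is monocytic", {
  sc <- scene()
  empty <- segment_avb3_regions(channel_image(matrix(0, 64, 64), "avb3"),
                                200, min_area = 1)
  cl <- classify_nuclei(sc$nuc, empty)
  expect_true(all(cl$nuclei$class == "monocytic"))
})

test_that("monocyte cytoplasm is the nearest-nucleus partition of its blob", {
  ## two nuclei sharing one whole-cell blob
  nuc <- matrix(0, 48, 48)
  nuc[20 + (-2:2), 14 + (-2:2)] <- 500
  nuc[20 + (-2:2), 30 + (-2:2)] <- 500
  wc <- matrix(0, 48, 48); wc[10:30, 6:40] <- 300
  nseg <- segment_nuclei(channel_image(nuc, "nuclei"), 250, min_area = 1)
  cl <- classify_nuclei(nseg, segment_avb3_regions(
    channel_image(matrix(0, 48, 48), "avb3"), 200, min_area = 1))
  res <- attach_monocyte_cytoplasm(cl, channel_image(wc, "wholecell"),
                                   threshold = 150)
  cy <- res$cytoplasm_labels
  ## masks are disjoint by construction and union equals the blob
  expect_equal(sum(cy > 0), sum(wc > 150))
  ## pixel-wise nearest-nucleus oracle
  idx <- which(wc > 150)
  rr <- (idx - 1) %% 48; cc <- (idx - 1) %/% 48
  cents <- cl$nuclei[, c("centroid_r", "centroid_c")]
  d1 <- (rr - cents[1, 1])^2 + (cc - cents[1, 2])^2
  d2 <- (rr - cents[2, 1])^2 + (cc - cents[2, 2])^2
  oracle <- ifelse(d1 <= d2, cl$nuclei$id[1], cl$nuclei$id[2])
  ## ties may go either way between equidistant pixels; compare off-tie
  off_tie <- d1 != d2
  expect_equal(cy[idx][off_tie], oracle[off_tie])
  ## each cytoplasm mask contains its own nucleus mask
  for (id in cl$nuclei$id)
    expect_true(all(cy[cl$nucleus_labels == id] == id))
})

test_that("a blank whole-cell channel falls back to nucleus masks, flagged", {
  cl <- toy_classified()
  res <- attach_monocyte_cytoplasm(cl, channel_image(matrix(0, 24, 24),
                                                     "wholecell"),
                                   threshold = 100)
  expect_true(all(res$table$fallback))
  expect_identical(res$cytoplasm_labels, cl$nucleus_labels)
})

test_that("mean nuclear NFAT equals the brute-force mask mean", {
  cl <- toy_classified()
  flat <- channel_image(matrix(100, 24, 24), "nfat")
  out <- measure_nuclear_nfat(cl, flat)
  expect_equal(out$nuclei$mean_nfat, c(100, 100))
  ## hand-computable asymmetric case: nucleus 1's nine pixels hold
  ## 0, 100, ..., 800, whose mean is 400
  known <- matrix(0, 24, 24)
  known[3:5, 3:5] <- seq(0, 800, by = 100)
  out_k <- measure_nuclear_nfat(cl, channel_image(known, "nfat"))
  expect_equal(out_k$nuclei$mean_nfat[1], 400)
  set.seed(1)
  rnd <- channel_image(matrix(runif(24 * 24, 0, 500), 24, 24), "nfat")
  out2 <- measure_nuclear_nfat(cl, rnd)
  for (id in 1:2)
    expect_equal(out2$nuclei$mean_nfat[id],
                 mean(rnd$pixels[cl$nucleus_labels == id]))
})

test_that("well summaries add up and reject mixed treatments", {
  s <- simulate_field(clean_params(n_monocytes = 12, n_osteoclasts = 1,
                                   seed = 8), well_id = "A01")
  q <- quantify_field(s$field)
  ws <- summarize_well(list(q))
  expect_equal(ws$total_nuclei, ws$monocyte_nuclei + ws$osteoclast_nuclei)
  expect_equal(ws$monocyte_nuclei, 12)
  ## additivity: two identical fields double every count
  ws2 <- summarize_well(list(q, q))
  expect_equal(ws2$total_nuclei, 2 * ws$total_nuclei)
  expect_equal(ws2$n_osteoclasts, 2 * ws$n_osteoclasts)
  ## pooled area per nucleus is invariant under duplication
  expect_equal(ws2$cytoplasm_area_per_nucleus,
               ws$cytoplasm_area_per_nucleus)
  ## mixed treatments are an error
  q2 <- q; q2$treatment$rankl <- 66
  expect_error(summarize_well(list(q, q2)), "mixed treatments")
})

test_that("quantification is idempotent and conserves nuclei", {
  for (seed in c(2, 5)) {
    s <- simulate_field(sim_image_params(field_shape = c(256L, 256L),
                                         n_monocytes = 30,
                                         n_osteoclasts = 1,
                                         oc_nuclei_range = c(3L, 4L),
                                         seed = seed))
    a <- quantify_field(s$field); b <- quantify_field(s$field)
    expect_identical(a$nuclei, b$nuclei)
    expect_identical(a$osteoclasts, b$osteoclasts)
    expect_equal(nrow(a$nuclei),
                 sum(a$nuclei$class == "monocytic") +
                   sum(a$nuclei$class == "osteoclastic"))
    expect_true(all(a$osteoclasts$n_nuclei >= 2))
    ## parent bookkeeping: per-parent nucleus counts match the records
    par <- a$nuclei$parent_osteoclast_id[!is.na(a$nuclei$parent_osteoclast_id)]
    expect_equal(as.integer(table(par)[as.character(a$osteoclasts$id)]),
                 a$osteoclasts$n_nuclei)
  }
})
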