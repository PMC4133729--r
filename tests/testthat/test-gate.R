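## Analytic oracle: grid-search minimum of the true mixture density
## between the two true modes.
true_gate <- function(w1, m1, s1, m2, s2) {
  dens <- function(t) w1 * dnorm(t, m1, s1) + (1 - w1) * dnorm(t, m2, s2)
  optimize(dens, c(m1, m2))$minimum
}

test_that("the fitted gate lands near the analytic inter-mode minimum", {
  set.seed(11)
  x <- c(rnorm(2500, 100, 10), rnorm(2500, 300, 20))
  g <- fit_nfat_gate(x)
  expect_equal(g$fallback_used, "none")
  expect_true(g$converged)
  expect_lt(abs(g$gate - true_gate(0.5, 100, 10, 300, 20)), 5)
  ## component order is canonical and parameters are close to truth
  expect_lt(g$means[1], g$means[2])
  expect_equal(g$means, c(100, 300), tolerance = 0.05)
  expect_equal(g$sds, c(10, 20), tolerance = 0.15)
})

test_that("a symmetric mixture is gated at its midpoint", {
  set.seed(3)
  x <- c(rnorm(3000, -50, 8), rnorm(3000, 50, 8))
  g <- fit_nfat_gate(x)
  expect_lt(abs(g$gate), 2)
})

test_that("effectively unimodal data trips the flagged fallback", {
  set.seed(5)
  x <- rnorm(500, 200, 15)
  g <- fit_nfat_gate(x)
  expect_true(g$fallback_used != "none")
  g2 <- fit_nfat_gate(x, fallback = "otsu")
  expect_true(g2$fallback_used %in% c("none", "otsu"))
})

test_that("insufficient or degenerate data raise informative errors", {
  expect_error(fit_nfat_gate(rnorm(10)), "insufficient data")
  expect_error(fit_nfat_gate(rep(5, 100)), "degenerate")
  expect_error(fit_nfat_gate(c(rnorm(100), NA)), "non-finite")
})

test_that("the gate is location-equivariant", {
  set.seed(7)
  x <- c(rnorm(1500, 100, 10), rnorm(1500, 260, 18))
  g0 <- fit_nfat_gate(x)
  g1 <- fit_nfat_gate(x + 500)
  expect_equal(g1$means, g0$means + 500, tolerance = 1e-6)
  expect_equal(g1$gate, g0$gate + 500, tolerance = 1e-4)
})

test_that("gate parameters agree with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  set.seed(13)
  x <- c(rnorm(2000, 120, 12), rnorm(1000, 320, 25))
  g <- fit_nfat_gate(x)
  m <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(g$means), sort(as.numeric(m$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(g$weights), sort(as.numeric(m$parameters$pro)),
               tolerance = 0.05)
})

test_that("positivity calls use a strict gate with ties negative", {
  set.seed(9)
  x <- c(rnorm(500, 100, 10), rnorm(500, 300, 20))
  g <- fit_nfat_gate(x)
  cl <- toy_classified()
  cl$nuclei$mean_nfat <- c(g$gate, g$gate + 1)   # tie and just-above
  out <- classify_nfat(cl, g)
  expect_equal(out$nuclei$nfat_call, c("neg", "pos"))
  expect_equal(out$nfat_pos_monocytes, 1L)
  expect_equal(out$nfat_pos_fraction, 0.5)
  ## all-below gives zero positives; counts always partition
  cl$nuclei$mean_nfat <- c(g$gate - 50, g$gate - 20)
  out0 <- classify_nfat(cl, g)
  expect_equal(out0$nfat_pos_fraction, 0)
  ## missing intensities are an error naming ids
  cl$nuclei$mean_nfat[2] <- NA
  expect_error(classify_nfat(cl, g), "missing mean_nfat.*2")
})

test_that("planted NFAT-positive fractions are recovered through the gate", {
  qs <- list(); trs <- list()
  for (i in 1:2) {
    s <- simulate_field(sim_image_params(field_shape = c(400L, 400L),
                                         n_monocytes = 120L,
                                         n_osteoclasts = 1L,
                                         oc_nuclei_range = c(3L, 4L),
                                         nfat_positive_fraction = 0.35,
                                         seed = 60L + i),
                        well_id = "W01", field_id = i)
    qs[[i]] <- quantify_field(s$field)
    trs[[i]] <- s$truth
  }
  vals <- unlist(lapply(qs, function(q)
    q$nuclei$mean_nfat[q$nuclei$class == "monocytic"]))
  g <- fit_nfat_gate(vals)
  qs <- lapply(qs, classify_nfat, model = g)
  rep <- validate_against_truth(qs, trs)
  expect_lt(abs(rep$nfat_fraction_error), 0.05)
})
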