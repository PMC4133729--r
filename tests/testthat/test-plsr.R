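test_that("the default panel assembles to the 6 x 188 design", {
  pp <- sim_panel_params(seed = 1)
  sim <- simulate_cytokine_panel(pp)
  X <- assemble_predictor_matrix(sim$panel, pp$detection_limit)
  expect_equal(dim(X), c(6L, 188L))
  expect_false(attr(X, "zscored"))
})

test_that("column order is cytokine-major with documented labels", {
  pan <- expand.grid(condition_id = 1:2, cytokine = c("A", "B", "C"),
                     timepoint_h = c(24, 48), stringsAsFactors = FALSE)
  pan$value <- seq_len(nrow(pan))
  X <- assemble_predictor_matrix(pan)
  expect_equal(dim(X), c(2L, 6L))
  expect_equal(colnames(X),
               c("A@t024h", "A@t048h", "B@t024h", "B@t048h",
                 "C@t024h", "C@t048h"))
  ## values land in the right cells
  expect_equal(X["1", "B@t048h"],
               pan$value[pan$condition_id == 1 & pan$cytokine == "B" &
                           pan$timepoint_h == 48])
  ## a single pair still works; duplicates are rejected
  one <- data.frame(condition_id = 1:2, cytokine = "A", timepoint_h = 24,
                    value = c(1, 2))
  expect_equal(dim(assemble_predictor_matrix(one)), c(2L, 1L))
  expect_error(assemble_predictor_matrix(rbind(pan, pan[1, ])),
               "duplicate")
})

test_that("z-scoring centres and scales every live column", {
  X <- assemble_predictor_matrix(local({
    set.seed(2)
    pan <- expand.grid(condition_id = 1:6, cytokine = sprintf("c%02d", 1:20),
                       timepoint_h = c(24, 48), stringsAsFactors = FALSE)
    pan$value <- rnorm(nrow(pan), 100, 20)
    pan$value[pan$cytokine == "c07"] <- 5   # constant column pair
    pan
  }))
  Z <- zscore_columns(X)
  dead <- attr(Z, "zeroed_columns")
  expect_equal(sort(colnames(Z)[dead]), c("c07@t024h", "c07@t048h"))
  live <- setdiff(seq_len(ncol(Z)), dead)
  expect_lt(max(abs(colMeans(Z[, live]))), 1e-10)
  expect_lt(max(abs(apply(Z[, live], 2, var) - 1)), 1e-10)
  expect_true(all(Z[, dead] == 0))
  expect_equal(zscore_columns(matrix(c(1, 2, 3), ncol = 1))[, 1],
               c(-1, 0, 1))
  expect_error(zscore_columns(Z), "already")
})

test_that("a response equal to one predictor is explained by one component", {
  ## with orthogonal predictors the first weight vector selects exactly
  ## that column, so one component explains the response completely
  set.seed(3)
  ## centred orthonormal columns (the span of centred columns excludes
  ## the intercept direction, so the Q columns are centred too)
  X <- qr.Q(qr(scale(matrix(rnorm(64), 8, 8), scale = FALSE)))[, 1:5]
  Y <- X[, 2, drop = FALSE]
  f <- plsr_fit(X, Y, A = 1)
  expect_gt(sum(f$r2y), 1 - 1e-8)
})

test_that("full-component PLSR reproduces least squares (both algorithms)", {
  for (seed in 1:3) {
    pr <- random_pls_problem(12, 6, m = 2, seed = seed)
    Xc <- scale(pr$X, scale = FALSE); Yc <- scale(pr$Y, scale = FALSE)
    B_ls <- qr.solve(Xc, Yc)
    for (alg in c("nipals", "simpls")) {
      f <- plsr_fit(pr$X, pr$Y, A = 6, algorithm = alg, scale_y = FALSE)
      expect_lt(norm(f$coefficients - B_ls, "F") / norm(B_ls, "F"), 1e-6)
      ## predictions match the least-squares fitted values
      fitted_ls <- sweep(Xc %*% B_ls, 2, colMeans(pr$Y), `+`)
      expect_equal(predict(f, pr$X), fitted_ls, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("NIPALS and SIMPLS coincide where equality is exact", {
  ## one component, and the full-rank fit, are algebraically identical
  for (seed in 1:5) {
    n <- sample(4:10, 1); p <- sample(5:60, 1)
    pr <- random_pls_problem(n, p, m = 2, seed = 100 + seed)
    for (A in unique(c(1L, min(n - 1L, p)))) {
      B1 <- plsr_fit(pr$X, pr$Y, A = A, algorithm = "nipals")$B
      B2 <- plsr_fit(pr$X, pr$Y, A = A, algorithm = "simpls")$B
      expect_lt(norm(B1 - B2, "F") / norm(B1, "F"), 1e-6)
    }
  }
})

test_that("at intermediate ranks the two deflations stay close but not equal", {
  pr <- random_pls_problem(8, 40, m = 2, seed = 42)
  B1 <- plsr_fit(pr$X, pr$Y, A = 3, algorithm = "nipals")$B
  B2 <- plsr_fit(pr$X, pr$Y, A = 3, algorithm = "simpls")$B
  expect_lt(norm(B1 - B2, "F") / norm(B1, "F"), 0.1)
})

test_that("component counts are validated and rank deficiency reduces A", {
  pr <- random_pls_problem(6, 10, seed = 5)
  expect_error(plsr_fit(pr$X, pr$Y, A = 0), "A must be")
  expect_error(plsr_fit(pr$X, pr$Y, A = 6), "A must be")
  ## duplicate rows reduce the usable rank below the requested A
  X <- pr$X[c(1, 1, 2, 2, 3, 3), ]; Y <- pr$Y[c(1, 1, 2, 2, 3, 3), ]
  expect_warning(f <- plsr_fit(X, Y, A = 5), "rank-deficient")
  expect_lt(f$A, 5)
})

test_that("VIP satisfies its normalisation and degeneracies", {
  pr <- random_pls_problem(6, 1, m = 1, seed = 6)
  f1 <- plsr_fit(pr$X, pr$Y, A = 1)
  expect_equal(unname(vip(f1)), 1, tolerance = 1e-10)
  for (seed in 1:4) {
    pr <- random_pls_problem(6, 30, seed = 10 + seed)
    f <- plsr_fit(pr$X, pr$Y, A = 3)
    v <- vip(f)
    expect_equal(sum(v^2), 30, tolerance = 1e-8)
  }
  ## an all-zero predictor column carries zero weight hence zero VIP
  X <- cbind(random_pls_problem(6, 5, seed = 20)$X, 0)
  f <- plsr_fit(X, random_pls_problem(6, 5, seed = 20)$Y, A = 2)
  expect_equal(unname(vip(f)[6]), 0)
})

test_that("fitted values match an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  pr <- random_pls_problem(10, 15, m = 2, seed = 30)
  colnames(pr$X) <- paste0("x", seq_len(ncol(pr$X)))
  f <- plsr_fit(pr$X, pr$Y, A = 2, algorithm = "nipals", scale_y = FALSE)
  ref <- mixOmics::pls(pr$X, pr$Y, ncomp = 2, mode = "regression",
                       scale = FALSE)
  pred <- predict(ref, pr$X)$predict[, , 2]
  expect_equal(unname(predict(f, pr$X)), unname(pred), tolerance = 1e-6)
})

test_that("cumulative rankings sum timepoint scores with stable tie-breaks", {
  ## panel with known per-predictor scores via a fitted model
  pp <- sim_panel_params(seed = 8)
  sim <- simulate_cytokine_panel(pp)
  X <- zscore_columns(assemble_predictor_matrix(sim$panel,
                                                pp$detection_limit))
  Y <- as.matrix(sim$responses[, c("monocyte_nuclei_d7",
                                   "osteoclast_nuclei_d7")])
  f <- plsr_fit(X, Y, A = 3)
  tab <- rank_regulators(f, "vip")
  v <- vip(f)
  for (i in sample(nrow(tab), 5)) {
    k <- tab$cytokine[i]
    expect_equal(tab$cumulative[i],
                 sum(v[attr(X, "cytokine") == k]), tolerance = 1e-12)
  }
  expect_equal(tab$rank, seq_len(nrow(tab)))
  ## all-zero scores rank in label order (deterministic tie-break)
  ctab <- rank_regulators(f, "coefficient", response = 1)
  expect_true(all(c("direction", "cumulative") %in% names(ctab)))
  und <- ctab$cytokine[ctab$cumulative == 0]
  lab_order <- unique(attr(X, "cytokine"))
  expect_equal(und, lab_order[lab_order %in% und])
})

test_that("scores and loadings expose the projection for plotting", {
  pp <- sim_panel_params(seed = 9)
  sim <- simulate_cytokine_panel(pp)
  X <- zscore_columns(assemble_predictor_matrix(sim$panel,
                                                pp$detection_limit))
  Y <- as.matrix(sim$responses[, c("monocyte_nuclei_d7",
                                   "osteoclast_nuclei_d7")])
  f1 <- plsr_fit(X, Y, A = 1)
  expect_error(scores_and_loadings(f1), "at least 2")
  f <- plsr_fit(X, Y, A = 3)
  sl <- scores_and_loadings(f)
  expect_equal(nrow(sl$scores), 6)
  expect_equal(names(sl$scores), c("condition", "t1", "t2", "t3"))
  expect_equal(nrow(sl$loadings), 188)
  expect_lte(sum(sl$explained_y), 1 + 1e-8)
  expect_lte(sum(sl$explained_x), 1 + 1e-8)
  ## replicated conditions receive identical score coordinates
  Xr <- rbind(X[1:3, ], X[1:3, ]); Yr <- rbind(Y[1:3, ], Y[1:3, ])
  fr <- plsr_fit(Xr, Yr, A = 2)
  expect_equal(fr$T[1:3, ], fr$T[4:6, ], tolerance = 1e-8)
  ## a dominant dose effect orders conditions along component 1
  expect_true(all(abs(cor(sl$scores$t1, Y)) > 0.7) ||
                all(abs(cor(sl$scores$t1, sim$responses$rankl)) > 0.7))
})
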