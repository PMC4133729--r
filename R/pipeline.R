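#' Default pipeline configuration
#'
#' Returns the fully-resolved default [run_pipeline()] configuration;
#' supplied values override defaults element-wise.
#'
#' @param ... named overrides, nested lists merged element-wise (e.g.
#'   `quantify = list(min_nucleus_area = 20)`).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "osteoquant-run",
    simulate = list(
      images = TRUE, panel = TRUE, n_fields = 1L,
      image_params = list(field_shape = c(320L, 320L), n_monocytes = 60L,
                          n_osteoclasts = 2L, oc_nuclei_range = c(3L, 5L)),
      panel_params = list()),
    images = list(dir = NULL, pixel_size = 1, plate_map = NULL),
    quantify = list(nuclei_threshold = "otsu", avb3_threshold = "otsu",
                    min_nucleus_area = 10, min_region_area = 100,
                    split_touching = FALSE,
                    area_per_nucleus = "pooled"),
    gate = list(enabled = TRUE, min_n = 50, fallback = "midpoint",
                log_transform = FALSE, per = "well"),
    plsr = list(n_components = 3L, algorithm = "nipals", scale_y = TRUE,
                response_source = "panel"))
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  cfg
}

## No wall-clock in the log: a re-run of the same configuration must
## produce byte-identical outputs (the manifest hashes the log too).
.log_line <- function(con, level, msg) {
  writeLines(sprintf("[%s] %s", level, msg), con)
}

#' Run the osteoclastogenesis pipeline end to end
#'
#' Executes (optionally) image and panel simulation, then
#' quantification, NFATc1 gating, PLSR and regulator ranking, writing
#' every stage's outputs under `config$out_dir` together with a frozen
#' copy of the resolved configuration, a log of defaulted parameters
#' and fallback events, and a manifest listing each output file with
#' its MD5 content hash. A stage failure aborts the run with the
#' failing stage named and leaves a `MANIFEST.partial` marker.
#'
#' Outputs: `nuclei.csv` (one nucleus record per row), `osteoclasts.csv`,
#' `well_summary.csv`, `gates.csv`, `panel.csv`, `responses.csv`,
#' `predictor_matrix.csv`, `plsr_fit.json`, `vip.csv`,
#' `coefficients.csv`, `ranking_positive_<response>.csv`,
#' `ranking_negative_<response>.csv`, `ranking_vip.csv`,
#' `scores_loadings.csv`, `config.yaml`, `run.log`, `manifest.json`.
#'
#' @param config configuration list (see [default_config()]) or path to
#'   a YAML file of overrides.
#' @return invisibly, the manifest list (`seed`, `files` with MD5
#'   hashes, `log`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- do.call(default_config,
                                              yaml::read_yaml(config))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  .log_line(con, "INFO", sprintf("seed = %d", config$seed))
  partial <- file.path(out, "MANIFEST.partial")
  file.create(partial)
  stage <- "init"
  res <- tryCatch({
    ## ---- simulate ----
    fields <- NULL; truths <- NULL
    panel_sim <- NULL
    conditions <- expand.grid(rankl = c(0, 15, 33), mcsf = c(15, 33))
    if (isTRUE(config$simulate$panel)) {
      stage <- "simulate-panel"
      pp <- do.call(sim_panel_params,
                    modifyList(list(seed = config$seed),
                               config$simulate$panel_params))
      panel_sim <- simulate_cytokine_panel(pp)
      conditions <- pp$conditions
      write_panel_csv(panel_sim$panel, file.path(out, "panel.csv"))
      write.csv(panel_sim$responses, file.path(out, "responses.csv"),
                row.names = FALSE)
      .log_line(con, "INFO", sprintf("simulated panel: %d cytokines x %d timepoints x %d conditions",
                                     pp$n_cytokines, length(pp$timepoints),
                                     nrow(pp$conditions)))
    }
    if (isTRUE(config$simulate$images)) {
      stage <- "simulate-images"
      fields <- list(); truths <- list()
      nf <- config$simulate$n_fields
      for (w in seq_len(nrow(conditions))) {
        for (f in seq_len(nf)) {
          sp <- do.call(sim_image_params,
                        modifyList(list(seed = config$seed + 97L * w + f),
                                   config$simulate$image_params))
          well <- sprintf("C%02d", w)
          sim <- simulate_field(sp, well_id = well, field_id = f,
                                treatment = list(
                                  rankl = conditions$rankl[w],
                                  mcsf = conditions$mcsf[w], time_h = 168))
          fields <- c(fields, list(sim$field))
          truths <- c(truths, list(sim$truth))
          write_field_tiff(sim$field, file.path(out, "images"))
          write_ground_truth(sim$truth, file.path(out, "truth"),
                             sprintf("%s_%d", well, f))
        }
      }
      .log_line(con, "INFO", sprintf("simulated %d fields", length(fields)))
    } else if (!is.null(config$images$dir)) {
      stage <- "load-images"
      pm <- config$images$plate_map
      if (is.character(pm)) pm <- yaml::read_yaml(pm)
      if (is.null(pm)) stop("images$plate_map required when loading images")
      fields <- list()
      for (w in names(pm)) {
        for (f in seq_len(pm[[w]]$n_fields %||% 1L)) {
          fields <- c(fields, list(read_field_tiff(
            config$images$dir, w, f,
            pixel_size = config$images$pixel_size,
            treatment = pm[[w]][c("rankl", "mcsf", "time_h")])))
        }
      }
    }

    ## ---- quantify ----
    quantified <- NULL
    if (!is.null(fields)) {
      stage <- "quantify"
      q <- config$quantify
      quantified <- lapply(fields, function(f) {
        r <- quantify_field(f, q$nuclei_threshold, q$avb3_threshold,
                            q$min_nucleus_area, q$min_region_area,
                            q$split_touching)
        .log_line(con, "DEBUG",
                  sprintf("well %s field %d: thresholds nuclei=%.4g avb3=%.4g, %d nuclei",
                          r$well_id, r$field_id, r$thresholds["nuclei"],
                          r$thresholds["avb3"], nrow(r$nuclei)))
        r
      })

      ## ---- gate ----
      has_nfat <- all(vapply(quantified, function(r)
        !all(is.na(r$nuclei$mean_nfat)), logical(1)))
      gates <- NULL
      if (isTRUE(config$gate$enabled) && has_nfat) {
        stage <- "gate"
        g <- config$gate
        wells <- unique(vapply(quantified, `[[`, character(1), "well_id"))
        pool <- identical(g$per, "plate")
        gates <- list()
        fit_one <- function(vals, label) {
          m <- fit_nfat_gate(vals, min_n = g$min_n, fallback = g$fallback,
                             log_transform = g$log_transform)
          if (m$fallback_used != "none")
            .log_line(con, "INFO", sprintf("gate %s: fallback %s used",
                                           label, m$fallback_used))
          m
        }
        if (pool) {
          vals <- unlist(lapply(quantified, function(r)
            r$nuclei$mean_nfat[r$nuclei$class == "monocytic"]))
          model <- fit_one(vals, "plate")
        }
        for (w in wells) {
          iw <- which(vapply(quantified, `[[`, character(1),
                             "well_id") == w)
          if (!pool) {
            vals <- unlist(lapply(quantified[iw], function(r)
              r$nuclei$mean_nfat[r$nuclei$class == "monocytic"]))
            model <- fit_one(vals, w)
          }
          for (i in iw) quantified[[i]] <- classify_nfat(quantified[[i]],
                                                         model)
          gates[[w]] <- data.frame(
            well_id = w, pi1 = model$weights[1], pi2 = model$weights[2],
            mu1 = model$means[1], mu2 = model$means[2],
            sigma1 = model$sds[1], sigma2 = model$sds[2],
            gate = model$gate, converged = model$converged,
            fallback = model$fallback_used)
        }
        write.csv(do.call(rbind, gates), file.path(out, "gates.csv"),
                  row.names = FALSE)
      } else if (isTRUE(config$gate$enabled)) {
        .log_line(con, "INFO",
                  "gating skipped: no NFAT channel in the input fields")
      }

      stage <- "summarize"
      nuc_all <- do.call(rbind, lapply(quantified, function(r)
        cbind(well_id = r$well_id, field_id = r$field_id, r$nuclei)))
      oc_all <- do.call(rbind, lapply(quantified, function(r)
        if (nrow(r$osteoclasts))
          cbind(well_id = r$well_id, field_id = r$field_id, r$osteoclasts)))
      write.csv(nuc_all, file.path(out, "nuclei.csv"), row.names = FALSE)
      write.csv(oc_all %||% data.frame(), file.path(out, "osteoclasts.csv"),
                row.names = FALSE)
      wells <- unique(vapply(quantified, `[[`, character(1), "well_id"))
      ws <- do.call(rbind, lapply(wells, function(w) {
        summarize_well(quantified[vapply(quantified, `[[`, character(1),
                                         "well_id") == w],
                       config$quantify$area_per_nucleus)
      }))
      write.csv(ws, file.path(out, "well_summary.csv"), row.names = FALSE)
    }

    ## ---- plsr + ranking ----
    if (!is.null(panel_sim) || file.exists(file.path(out, "panel.csv"))) {
      stage <- "plsr"
      panel <- panel_sim$panel %||% read_panel_csv(file.path(out, "panel.csv"))
      pc <- config$plsr
      X <- assemble_predictor_matrix(panel)
      Xz <- zscore_columns(X)
      if (length(attr(Xz, "zeroed_columns")))
        .log_line(con, "INFO", sprintf("%d zero-variance predictor columns zeroed",
                                       length(attr(Xz, "zeroed_columns"))))
      Y <- if (identical(pc$response_source, "wells") && !is.null(fields)) {
        key <- paste(ws$rankl, ws$mcsf)
        ckey <- paste(conditions$rankl, conditions$mcsf)
        t(vapply(ckey, function(k) c(
          monocyte_nuclei_d7 = mean(ws$monocyte_nuclei[key == k]),
          osteoclast_nuclei_d7 = mean(ws$osteoclast_nuclei[key == k])),
          numeric(2)))
      } else {
        as.matrix(panel_sim$responses[, c("monocyte_nuclei_d7",
                                          "osteoclast_nuclei_d7")])
      }
      fit <- plsr_fit(Xz, Y, A = pc$n_components,
                      algorithm = pc$algorithm, scale_y = pc$scale_y)
      write.csv(data.frame(condition = rownames(Xz) %||% seq_len(nrow(Xz)),
                           Xz, check.names = FALSE),
                file.path(out, "predictor_matrix.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(algorithm = fit$algorithm, A = fit$A, W = fit$W, P = fit$P,
             Q = fit$Q, B = fit$B, ssx = fit$ssx, ssy = fit$ssy,
             r2x = fit$r2x, r2y = fit$r2y),
        file.path(out, "plsr_fit.json"), digits = NA)
      v <- vip(fit)
      write.csv(data.frame(predictor = names(v), vip = v, row.names = NULL),
                file.path(out, "vip.csv"), row.names = FALSE)
      write.csv(data.frame(predictor = fit$x_labels, coef(fit),
                           check.names = FALSE),
                file.path(out, "coefficients.csv"), row.names = FALSE)

      stage <- "rank"
      tabs <- regulator_tables(fit)
      for (r in names(tabs$positive)) {
        write.csv(tabs$positive[[r]],
                  file.path(out, sprintf("ranking_positive_%s.csv", r)),
                  row.names = FALSE)
        write.csv(tabs$negative[[r]],
                  file.path(out, sprintf("ranking_negative_%s.csv", r)),
                  row.names = FALSE)
      }
      write.csv(tabs$vip, file.path(out, "ranking_vip.csv"),
                row.names = FALSE)
      sl <- scores_and_loadings(fit)
      write.csv(merge(sl$scores,
                      data.frame(condition = seq_len(nrow(conditions)),
                                 conditions), by = "condition"),
                file.path(out, "scores_loadings.csv"), row.names = FALSE)
    }

    ## ---- manifest ----
    stage <- "manifest"
    flush(con)
    files <- setdiff(list.files(out, recursive = TRUE),
                     c("manifest.json", "MANIFEST.partial"))
    hashes <- tools::md5sum(file.path(out, files))
    manifest <- list(seed = config$seed,
                     files = as.list(setNames(unname(hashes), files)))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
    unlink(partial)
    invisible(manifest)
  }, error = function(e) {
    .log_line(con, "ERROR", sprintf("stage '%s' failed: %s", stage,
                                    conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), out), call. = FALSE)
  })
  res
}

#' Compare quantification output against synthetic ground truth
#'
#' Matches every ground-truth nucleus centroid against the detected
#' nucleus masks of the same field. A nucleus is *counted* if its
#' centroid falls inside a detected mask and *missed* otherwise
#' (`counted% + missed% = 100`); a counted nucleus is additionally
#' *merged* if it shares its mask with at least one other ground-truth
#' nucleus -- the merged-nuclei error mode of threshold-based counting.
#' Also reports the monocyte/osteoclast confusion over counted,
#' unmerged nuclei and, when gating was applied, the NFAT
#' positive-fraction error against the planted fraction.
#'
#' @param quantified list of [quantify_field()] results (optionally
#'   gated via [classify_nfat()]).
#' @param truths list of matching `truth` components from
#'   [simulate_field()], same order and length.
#' @return object of class `validation_report`: list with `n_truth`,
#'   `counted`, `missed`, `merged`, `counted_pct`, `missed_pct`,
#'   `merged_pct`, `accuracy_pct` (uniquely recovered: counted and not
#'   merged), `confusion` (truth class x detected class),
#'   `class_accuracy`, `nfat_fraction_detected`, `nfat_fraction_planted`,
#'   `nfat_fraction_error` (NA when not gated).
#' @export
validate_against_truth <- function(quantified, truths) {
  if (length(quantified) != length(truths))
    stop("quantified and truths must have the same length")
  counted <- missed <- merged <- 0L
  conf <- matrix(0L, 2, 2, dimnames = list(
    truth = c("monocyte", "osteoclast"),
    detected = c("monocytic", "osteoclastic")))
  npos <- nmono <- 0L
  planted <- numeric(0)
  for (i in seq_along(quantified)) {
    q <- quantified[[i]]; tr <- truths[[i]]
    if (nrow(tr$nuclei) == 0L) next
    lab <- label_at(q$nucleus_labels, tr$nuclei$centroid_r,
                    tr$nuclei$centroid_c)
    hit <- lab > 0L
    counted <- counted + sum(hit)
    missed <- missed + sum(!hit)
    occ <- table(lab[hit])
    shared <- as.integer(names(occ)[occ >= 2L])
    merged <- merged + sum(lab %in% shared)
    solo <- hit & !(lab %in% shared)
    if (any(solo)) {
      det_class <- q$nuclei$class[match(lab[solo], q$nuclei$id)]
      tt <- table(factor(tr$nuclei$class[solo],
                         c("monocyte", "osteoclast")),
                  factor(det_class, c("monocytic", "osteoclastic")))
      conf <- conf + as.matrix(tt)
    }
    if (!is.null(q$nfat_pos_monocytes)) {
      mono <- q$nuclei$class == "monocytic"
      npos <- npos + q$nfat_pos_monocytes
      nmono <- nmono + sum(mono)
      planted <- c(planted, tr$params$nfat_positive_fraction)
    }
  }
  n <- counted + missed
  det_frac <- if (nmono > 0) npos / nmono else NA_real_
  plant_frac <- if (length(planted)) mean(planted) else NA_real_
  structure(list(
    n_truth = n, counted = counted, missed = missed, merged = merged,
    counted_pct = 100 * counted / n, missed_pct = 100 * missed / n,
    merged_pct = 100 * merged / n,
    ## uniquely recovered: neither missed nor sharing a mask
    accuracy_pct = 100 * (counted - merged) / n,
    confusion = conf,
    class_accuracy = if (sum(conf) > 0) sum(diag(conf)) / sum(conf)
                     else NA_real_,
    nfat_fraction_detected = det_frac,
    nfat_fraction_planted = plant_frac,
    nfat_fraction_error = det_frac - plant_frac),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Quantification validation against ground truth\n")
  cat(sprintf("  nuclei: %d truth, %.1f%% counted, %.1f%% missed, %.1f%% merged\n",
              x$n_truth, x$counted_pct, x$missed_pct, x$merged_pct))
  cat(sprintf("  uniquely recovered (counted and unmerged): %.1f%%\n",
              x$accuracy_pct))
  if (is.finite(x$class_accuracy))
    cat(sprintf("  class accuracy (counted, unmerged): %.1f%%\n",
                100 * x$class_accuracy))
  if (is.finite(x$nfat_fraction_error %||% NA))
    cat(sprintf("  NFAT+ fraction: detected %.3f vs planted %.3f (error %+.3f)\n",
                x$nfat_fraction_detected, x$nfat_fraction_planted,
                x$nfat_fraction_error))
  invisible(x)
}
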