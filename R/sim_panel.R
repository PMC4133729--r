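#' Analyte names of the 48-plex cytokine immunoassay panel
#'
#' The bead-based multiplex panel used for conditioned-medium profiling
#' of differentiating osteoclast cultures. The generator takes the first
#' `n_cytokines` of these names (default 47).
#'
#' @format character vector of 48 analyte names.
#' @export
cytokine_panel_names <- c(
  "IL-1b", "IL-1ra", "IL-2", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8",
  "IL-9", "IL-10", "IL-12p70", "IL-13", "IL-15", "IL-17", "Eotaxin",
  "FGF-basic", "G-CSF", "GM-CSF", "IFN-g", "IP-10", "MCP-1", "MIP-1a",
  "MIP-1b", "PDGF-BB", "RANTES", "TNF-a", "VEGF", "IL-1a", "IL-2Ra",
  "IL-3", "IL-12p40", "IL-16", "IL-18", "CTACK", "GRO-a", "HGF",
  "IFN-a2", "LIF", "MCP-3", "M-CSF", "MIF", "MIG", "b-NGF", "SCF",
  "SCGF-b", "SDF-1a", "TNF-b", "TRAIL")

#' Parameters for the synthetic cytokine-panel generator
#'
#' Describes a conditions x cytokines x timepoints secreted-cytokine
#' panel with planted temporal/dose structure and two osteoclastogenesis
#' outcome responses (monocyte and osteoclast nuclei at day 7) that are a
#' stated linear function of RANKL/MCSF dose and planted cytokine
#' effects. Defaults emulate the design of the profiling experiment: 47
#' analytes, timepoints 24/48/72/144 h, six conditions (RANKL 0, 15 or
#' 33 ng/ml crossed with MCSF 15 or 33 ng/ml), and roughly half of the
#' analytes below the detection limit.
#'
#' @param n_cytokines number of analytes (named from
#'   [cytokine_panel_names]).
#' @param timepoints sampling times in hours.
#' @param conditions data frame with columns `rankl` and `mcsf` (ng/ml),
#'   one row per condition (>= 2 rows required downstream).
#' @param trend_classes character vector (length `n_cytokines`) over
#'   `{"time_up", "time_down", "rankl_dependent", "flat",
#'   "undetectable"}`. `NULL` picks a default assignment: planted-effect
#'   cytokines are `rankl_dependent`; the remainder are split between the
#'   classes with about 21 of 47 undetectable.
#' @param effect_weights `n_cytokines x 2` matrix of signed contributions
#'   of each cytokine to the (monocyte, osteoclast) responses. `NULL`
#'   plants the default regulators: IL-8, MCP-1 and VEGF at +1 for both
#'   responses, IL-4 and IL-10 at -1.5 (so each program carries a
#'   comparable aggregate influence).
#' @param effect_scale response units contributed per standardised unit
#'   of cytokine signal at weight 1.
#' @param dose_response list with numeric 3-vectors `monocyte` and
#'   `osteoclast`: (intercept, RANKL coefficient, MCSF coefficient) of
#'   the linear dose part of each response; dose coefficients apply to
#'   dose/33 ng/ml.
#' @param condition_sd relative sd of the per-(cytokine, condition)
#'   level modifier for cytokines with no planted effect -- the weak
#'   condition-to-condition coherence of biologically inert analytes.
#' @param effect_signal_sd relative sd of the same modifier for
#'   planted-effect cytokines: the condition-level secretion
#'   variability through which a planted regulator actually drives the
#'   outcome (it must exceed `condition_sd` for planted effects to be
#'   statistically identifiable from six conditions).
#' @param noise_sd additive Gaussian measurement noise on panel values
#'   (assay units).
#' @param response_noise_sd additive Gaussian noise on the two responses
#'   (nuclei counts).
#' @param detection_limit assay floor; values below it are floored and
#'   flagged.
#' @param seed integer RNG seed.
#' @return an object of class `sim_panel_params`.
#' @export
sim_panel_params <- function(n_cytokines = 47L,
                             timepoints = c(24, 48, 72, 144),
                             conditions = expand.grid(rankl = c(0, 15, 33),
                                                      mcsf = c(15, 33)),
                             trend_classes = NULL,
                             effect_weights = NULL,
                             effect_scale = 600,
                             dose_response = list(
                               monocyte = c(6000, 600, 300),
                               osteoclast = c(1500, 800, 0)),
                             condition_sd = 0.04,
                             effect_signal_sd = 0.8,
                             noise_sd = 5,
                             response_noise_sd = 50,
                             detection_limit = 2,
                             seed = 1L) {
  n_cytokines <- as.integer(n_cytokines)
  stopifnot(n_cytokines >= 1L, length(timepoints) >= 1L,
            noise_sd >= 0, response_noise_sd >= 0, detection_limit > 0,
            condition_sd >= 0, effect_scale >= 0)
  nms <- if (n_cytokines <= length(cytokine_panel_names))
    cytokine_panel_names[seq_len(n_cytokines)]
  else sprintf("CYT-%02d", seq_len(n_cytokines))
  if (is.null(effect_weights)) {
    effect_weights <- matrix(0, n_cytokines, 2,
                             dimnames = list(nms, c("monocyte", "osteoclast")))
    planted_pos <- intersect(c("IL-8", "MCP-1", "VEGF"), nms)
    planted_neg <- intersect(c("IL-4", "IL-10"), nms)
    ## the two suppressive cytokines get a larger weight so each planted
    ## program carries a comparable aggregate outcome influence
    effect_weights[planted_pos, ] <- 1
    effect_weights[planted_neg, ] <- -1.5
  }
  effect_weights <- as.matrix(effect_weights)
  if (nrow(effect_weights) != n_cytokines || ncol(effect_weights) != 2L)
    stop("effect_weights must be an n_cytokines x 2 matrix")
  if (is.null(trend_classes)) {
    trend_classes <- rep("flat", n_cytokines)
    n_undet <- round(n_cytokines * 21 / 47)
    ## planted cytokines must vary with condition to act on the responses
    planted <- rowSums(abs(effect_weights)) > 0
    free <- which(!planted)
    und <- free[seq_len(min(n_undet, length(free)))]
    trend_classes[und] <- "undetectable"
    rest <- setdiff(free, und)
    ## only a couple of inert analytes are RANKL-induced; most detectable
    ## non-regulator cytokines drift with time or stay flat
    cls <- rep(c("time_up", "time_down", "flat"), length.out = length(rest))
    cls[seq_len(min(2L, length(cls)))] <- "rankl_dependent"
    trend_classes[rest] <- cls
    ## positive regulators are RANKL-induced; negative regulators follow a
    ## RANKL-independent declining profile so their association with the
    ## outcome is carried by their own condition-level variation
    trend_classes[rowSums(effect_weights) > 0] <- "rankl_dependent"
    trend_classes[planted & rowSums(effect_weights) <= 0] <- "time_down"
  }
  trend_classes <- match.arg(trend_classes,
                             c("time_up", "time_down", "rankl_dependent",
                               "flat", "undetectable"), several.ok = TRUE)
  if (length(trend_classes) != n_cytokines)
    stop("trend_classes must have one entry per cytokine")
  conditions <- as.data.frame(conditions)
  stopifnot(all(c("rankl", "mcsf") %in% names(conditions)))
  structure(list(n_cytokines = n_cytokines, cytokines = nms,
                 timepoints = timepoints, conditions = conditions,
                 trend_classes = trend_classes,
                 effect_weights = effect_weights,
                 effect_scale = effect_scale, dose_response = dose_response,
                 condition_sd = condition_sd,
                 effect_signal_sd = effect_signal_sd,
                 noise_sd = noise_sd, response_noise_sd = response_noise_sd,
                 detection_limit = detection_limit,
                 seed = as.integer(seed)),
            class = "sim_panel_params")
}

#' Generate a ground-truthed synthetic cytokine panel
#'
#' Draws a conditions x cytokines x timepoints panel following each
#' cytokine's trend class plus measurement noise, and two outcome
#' responses (monocyte and osteoclast nuclei at day 7, on the 10^3--10^4
#' nuclei-per-condition scale) built as a linear function of RANKL/MCSF
#' dose plus the planted cytokine effects. Values below the detection
#' limit are floored at it and flagged. Trend models (relative to a
#' per-cytokine log-normal baseline level `b`):
#' `time_up` \eqn{b(0.4 + 1.2 t/t_max)}; `time_down`
#' \eqn{b(1 - 0.6 t/t_max)}; `rankl_dependent`
#' \eqn{b(0.4 + 1.5 (t/t_max)(RANKL/33))}; `flat` \eqn{b}; each scaled by
#' a per-(cytokine, condition) log-normal modifier of sd `condition_sd`.
#'
#' @param params a [sim_panel_params()] object.
#' @return list with components `panel` (long data frame: condition_id,
#'   rankl, mcsf, cytokine, timepoint_h, value, below_detection),
#'   `responses` (data frame: condition_id, rankl, mcsf,
#'   monocyte_nuclei_d7, osteoclast_nuclei_d7) and `truth` (list:
#'   trend_classes, effect_weights, signal -- the standardised noiseless
#'   condition-level signal actually used to build the responses).
#' @export
simulate_cytokine_panel <- function(params) {
  stopifnot(inherits(params, "sim_panel_params"))
  if (nrow(params$conditions) < 2L)
    stop("at least 2 conditions are required (regression undefined otherwise)")
  with_seed(params$seed, .simulate_panel_impl(params))
}

.simulate_panel_impl <- function(p) {
  nC <- nrow(p$conditions); nK <- p$n_cytokines; nT <- length(p$timepoints)
  tmax <- max(p$timepoints)
  base <- exp(rnorm(nK, log(100), 0.5))
  planted <- rowSums(abs(p$effect_weights)) > 0
  sign_k <- sign(rowSums(p$effect_weights))
  ## planted regulators of the same sign follow a shared condition-level
  ## secretion program (co-regulated autocrine factors) plus a small
  ## individual wobble; inert cytokines have only weak coherence
  ## the programs are drawn orthogonal to the dose contrasts and to each
  ## other, so planted positive and negative effects are identifiable in
  ## the small (six-condition) design rather than only in expectation
  f_pos <- rnorm(nC); f_neg <- rnorm(nC)
  if (nC >= 5) {
    base_dirs <- cbind(1, p$conditions$rankl, p$conditions$mcsf)
    proj_out <- function(v, M) {
      for (j in seq_len(ncol(M))) {
        m <- M[, j]
        if (sum(m^2) > 0) v <- v - m * sum(v * m) / sum(m^2)
      }
      v
    }
    f_pos <- proj_out(f_pos, base_dirs)
    f_neg <- proj_out(f_neg, cbind(base_dirs, f_pos))
    f_pos <- f_pos / max(sd(f_pos), 1e-12)
    f_neg <- f_neg / max(sd(f_neg), 1e-12)
  }
  u <- matrix(rnorm(nC * nK), nC, nK) %*%
    diag(ifelse(planted, p$effect_signal_sd / 8, p$condition_sd), nK)
  for (k in which(planted))
    u[, k] <- u[, k] + p$effect_signal_sd *
      (if (sign_k[k] >= 0) f_pos else f_neg)
  mu <- array(0, dim = c(nC, nK, nT))                     # noiseless mean
  for (k in seq_len(nK)) {
    cls <- p$trend_classes[k]
    for (ti in seq_len(nT)) {
      t <- p$timepoints[ti] / tmax
      f <- switch(cls,
                  time_up = 0.4 + 1.2 * t,
                  time_down = 1 - 0.6 * t,
                  rankl_dependent = 0.4 + 1.5 * t * (p$conditions$rankl / 33),
                  flat = 1,
                  undetectable = 0)
      mu[, k, ti] <- base[k] * f * exp(u[, k])
    }
  }
  value <- mu + array(rnorm(length(mu), 0, p$noise_sd), dim = dim(mu))
  for (k in which(p$trend_classes == "undetectable"))
    value[, k, ] <- runif(nC * nT, 0, 0.9 * p$detection_limit)
  below <- value < p$detection_limit
  value[below] <- p$detection_limit

  ## standardised noiseless condition-level signal driving the responses
  sig <- apply(mu, c(1, 2), mean)
  sig <- apply(sig, 2, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  colnames(sig) <- p$cytokines
  eff <- sig %*% p$effect_weights * p$effect_scale
  dr <- p$dose_response
  dose_part <- function(cf) cf[1] + cf[2] * p$conditions$rankl / 33 +
    cf[3] * p$conditions$mcsf / 33
  responses <- data.frame(
    condition_id = seq_len(nC),
    rankl = p$conditions$rankl, mcsf = p$conditions$mcsf,
    monocyte_nuclei_d7 = pmax(0, dose_part(dr$monocyte) + eff[, 1] +
      rnorm(nC, 0, p$response_noise_sd)),
    osteoclast_nuclei_d7 = pmax(0, dose_part(dr$osteoclast) + eff[, 2] +
      rnorm(nC, 0, p$response_noise_sd)))

  panel <- expand.grid(timepoint_h = p$timepoints,
                       cytokine = p$cytokines,
                       condition_id = seq_len(nC),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- cbind(panel$condition_id,
               match(panel$cytokine, p$cytokines),
               match(panel$timepoint_h, p$timepoints))
  panel$value <- value[ord]
  panel$below_detection <- below[ord]
  panel$rankl <- p$conditions$rankl[panel$condition_id]
  panel$mcsf <- p$conditions$mcsf[panel$condition_id]
  panel <- panel[, c("condition_id", "rankl", "mcsf", "cytokine",
                     "timepoint_h", "value", "below_detection")]
  list(panel = panel, responses = responses,
       truth = list(trend_classes = setNames(p$trend_classes, p$cytokines),
                    effect_weights = p$effect_weights, signal = sig))
}
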