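#' Fit the bimodal NFATc1 positivity gate
#'
#' Fits a two-component Gaussian mixture to per-nucleus mean nuclear
#' NFATc1 intensities by expectation--maximisation and places the gate
#' at the minimum of the fitted mixture density between the two modes
#' (numerical grid search on `(mu1, mu2)` followed by local refinement).
#' The fit is deterministic: components are initialised by a 2-means
#' split of the data (centres at the 25th and 75th percentiles), EM runs
#' to a log-likelihood tolerance of `1e-8` with a 500-iteration cap, and
#' components are canonically ordered `mu1 < mu2`.
#'
#' When the fitted mixture is effectively unimodal -- mode separation
#' `|mu2 - mu1| < max(sigma1, sigma2)` or a mixing fraction below 0.02
#' -- the inter-mode minimum is unstable and a fallback gate is used and
#' flagged: the component-mean midpoint (default) or an Otsu threshold
#' on the intensity histogram.
#'
#' @param intensities numeric vector of per-nucleus mean NFAT
#'   intensities (raw by default; set `log_transform = TRUE` to gate on
#'   the log scale and back-transform the gate).
#' @param min_n minimum number of observations (default 50).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param fallback `"midpoint"` or `"otsu"`.
#' @param log_transform gate on `log(intensities)`.
#' @return an object of class `nfat_gate`: list with `weights`, `means`,
#'   `sds` (each length 2, component 1 the dimmer mode), `gate`,
#'   `converged`, `fallback_used` (`"none"`, `"midpoint"` or `"otsu"`),
#'   `loglik`, `n`, `iterations`, `log_transform`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 100, 10), rnorm(300, 300, 20))
#' g <- fit_nfat_gate(x)
#' g$gate
#' @export
fit_nfat_gate <- function(intensities, min_n = 50, max_iter = 500,
                          tol = 1e-8, fallback = c("midpoint", "otsu"),
                          log_transform = FALSE) {
  fallback <- match.arg(fallback)
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("fit_nfat_gate: non-finite intensities")
  if (length(x) < min_n)
    stop(sprintf("fit_nfat_gate: insufficient data (n = %d < min_n = %d)",
                 length(x), min_n))
  if (sd(x) == 0)
    stop("fit_nfat_gate: degenerate data (zero variance)")
  raw <- x
  if (log_transform) {
    if (any(x <= 0)) stop("fit_nfat_gate: log transform needs positive values")
    x <- log(x)
  }

  ## deterministic 2-means init (Lloyd iterations from fixed quantiles)
  ctr <- quantile(x, c(0.25, 0.75), names = FALSE)
  if (ctr[1] == ctr[2]) ctr <- range(x)
  for (it in 1:50) {
    assign1 <- abs(x - ctr[1]) <= abs(x - ctr[2])
    new <- c(mean(x[assign1]), mean(x[!assign1]))
    if (any(!is.finite(new))) break
    if (max(abs(new - ctr)) < 1e-12) { ctr <- new; break }
    ctr <- new
  }
  grp <- abs(x - ctr[1]) <= abs(x - ctr[2])
  pi1 <- mean(grp)
  mu <- c(mean(x[grp]), mean(x[!grp]))
  sg <- pmax(c(sd(x[grp]), sd(x[!grp])), 1e-6 * sd(x))
  sg[!is.finite(sg)] <- sd(x)
  w <- c(pi1, 1 - pi1)

  ## EM
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    w <- c(n1, n2) / length(x)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                 sum((1 - g1) * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-6 * sd(x))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ## canonical ordering
  if (mu[1] > mu[2]) { mu <- rev(mu); sg <- rev(sg); w <- rev(w) }

  unimodal <- abs(mu[2] - mu[1]) < max(sg) || min(w) < 0.02
  fb <- "none"
  if (unimodal) {
    fb <- fallback
    gate <- if (fallback == "midpoint") mean(mu)
            else otsu_threshold(matrix(x, ncol = 1))  # histogram-based
  } else {
    dens <- function(t) w[1] * dnorm(t, mu[1], sg[1]) +
      w[2] * dnorm(t, mu[2], sg[2])
    grid <- seq(mu[1], mu[2], length.out = 512)
    i <- which.min(dens(grid))
    lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
    gate <- if (lo < hi) optimize(dens, c(lo, hi))$minimum else grid[i]
  }
  if (log_transform) { gate <- exp(gate); mu_r <- exp(mu) } else mu_r <- mu

  structure(list(weights = w, means = mu, sds = sg, gate = gate,
                 means_intensity = mu_r,
                 converged = converged, fallback_used = fb,
                 loglik = ll, n = length(raw), iterations = iter,
                 log_transform = log_transform, data = raw),
            class = "nfat_gate")
}

#' @export
print.nfat_gate <- function(x, digits = 4, ...) {
  cat("Bimodal Gaussian NFATc1 gate\n")
  cat(sprintf("  components: pi = (%.3f, %.3f), mu = (%s, %s), sigma = (%s, %s)%s\n",
              x$weights[1], x$weights[2],
              signif(x$means[1], digits), signif(x$means[2], digits),
              signif(x$sds[1], digits), signif(x$sds[2], digits),
              if (x$log_transform) "  [log scale]" else ""))
  cat(sprintf("  gate = %s  (n = %d, %s%s)\n", signif(x$gate, digits), x$n,
              if (x$converged) "EM converged" else "EM not converged",
              if (x$fallback_used != "none")
                paste0(", fallback: ", x$fallback_used) else ""))
  invisible(x)
}

#' @export
coef.nfat_gate <- function(object, ...) {
  c(pi1 = object$weights[1], pi2 = object$weights[2],
    mu1 = object$means[1], mu2 = object$means[2],
    sigma1 = object$sds[1], sigma2 = object$sds[2],
    gate = object$gate)
}

#' @export
summary.nfat_gate <- function(object, ...) {
  print(object)
  frac <- mean(object$data > object$gate)
  cat(sprintf("  %.1f%% of the fitted intensities fall above the gate\n",
              100 * frac))
  invisible(object)
}

#' Predict NFAT positivity calls from a fitted gate
#'
#' @param object an [fit_nfat_gate()] model.
#' @param newdata numeric intensities; defaults to the training data.
#' @param ... unused.
#' @return character vector of `"pos"` / `"neg"` calls; values strictly
#'   above the gate are positive (ties are negative).
#' @export
predict.nfat_gate <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else as.numeric(newdata)
  ifelse(x > object$gate, "pos", "neg")
}

#' @export
plot.nfat_gate <- function(x, breaks = 40, main = "NFATc1 gate", ...) {
  hist(x$data, breaks = breaks, freq = FALSE, main = main,
       xlab = "mean nuclear NFATc1 intensity", border = gray(0.4), ...)
  xx <- seq(min(x$data), max(x$data), length.out = 400)
  sc <- if (x$log_transform) function(t) log(t) else identity
  dd <- x$weights[1] * dnorm(sc(xx), x$means[1], x$sds[1]) +
    x$weights[2] * dnorm(sc(xx), x$means[2], x$sds[2])
  if (x$log_transform) dd <- dd / xx
  lines(xx, dd, lwd = 2)
  abline(v = x$gate, lty = 2, lwd = 2)
  invisible(x)
}

#' Gate nucleus records into NFATc1-negative and -positive populations
#'
#' Applies a fitted gate to every nucleus record: `nfat_call = "pos"`
#' iff `mean_nfat > gate` (strictly; ties are negative). The returned
#' positive count and fraction are computed over monocytic records only,
#' matching the monocyte-centred NFATc1 readout.
#'
#' @param classified result of [quantify_field()] / [classify_nuclei()]
#'   with `mean_nfat` measured, or a data frame of nucleus records.
#' @param model an [fit_nfat_gate()] object.
#' @return for a classified list: the list with `nuclei$nfat_call`
#'   filled and elements `nfat_pos_monocytes` / `nfat_pos_fraction`
#'   added; for a data frame: the same information as a list
#'   (`records`, `count_pos`, `fraction_pos`).
#' @export
classify_nfat <- function(classified, model) {
  stopifnot(inherits(model, "nfat_gate"))
  records <- if (is.data.frame(classified)) classified else classified$nuclei
  if (any(is.na(records$mean_nfat)))
    stop("classify_nfat: missing mean_nfat for nucleus id(s): ",
         paste(head(records$id[is.na(records$mean_nfat)], 10), collapse = ", "))
  records$nfat_call <- predict(model, records$mean_nfat)
  mono <- records$class == "monocytic"
  count_pos <- sum(records$nfat_call[mono] == "pos")
  fraction_pos <- if (any(mono)) count_pos / sum(mono) else NA_real_
  if (is.data.frame(classified))
    return(list(records = records, count_pos = count_pos,
                fraction_pos = fraction_pos))
  classified$nuclei <- records
  classified$nfat_pos_monocytes <- count_pos
  classified$nfat_pos_fraction <- fraction_pos
  classified
}
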