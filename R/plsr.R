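#' Assemble the conditions x (cytokine, timepoint) predictor matrix
#'
#' Flattens a long-format cytokine panel into the PLSR predictor matrix:
#' one row per condition, one column per (cytokine, timepoint) pair,
#' columns ordered cytokine-major (all timepoints of the first cytokine,
#' then the second, ...), labelled `"<cytokine>@t<hours>h"`. With the
#' default panel design (47 cytokines, 4 timepoints, 6 conditions) the
#' result is the 6 x 188 matrix of the study design. Values flagged
#' below detection are imputed at `detection_limit / 2` when a detection
#' limit is given (otherwise kept at their floored value).
#'
#' @param panel long data frame with columns `condition_id`, `cytokine`,
#'   `timepoint_h`, `value` and optionally `below_detection` (see
#'   [simulate_cytokine_panel()]).
#' @param detection_limit assay floor used for below-detection
#'   imputation, or `NULL`.
#' @return numeric matrix of class `predictor_matrix` with attributes
#'   `cytokine` and `timepoint_h` (per column), `conditions` (row ids)
#'   and `zscored = FALSE`.
#' @export
assemble_predictor_matrix <- function(panel, detection_limit = NULL) {
  need <- c("condition_id", "cytokine", "timepoint_h", "value")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  cyt <- unique(panel$cytokine)
  tps <- sort(unique(panel$timepoint_h))
  cond <- sort(unique(panel$condition_id))
  if (anyDuplicated(panel[, c("condition_id", "cytokine", "timepoint_h")]))
    stop("duplicate (condition, cytokine, timepoint) entries in panel")
  val <- panel$value
  if (!is.null(detection_limit) && "below_detection" %in% names(panel))
    val[panel$below_detection] <- detection_limit / 2
  X <- matrix(NA_real_, length(cond), length(cyt) * length(tps))
  ci <- match(panel$condition_id, cond)
  ki <- match(panel$cytokine, cyt)
  ti <- match(panel$timepoint_h, tps)
  X[cbind(ci, (ki - 1L) * length(tps) + ti)] <- val
  if (anyNA(X)) stop("panel is incomplete: missing (condition, cytokine, timepoint) cells")
  col_cyt <- rep(cyt, each = length(tps))
  col_tp <- rep(tps, times = length(cyt))
  colnames(X) <- sprintf("%s@t%03dh", col_cyt, as.integer(col_tp))
  rownames(X) <- as.character(cond)
  structure(X, class = c("predictor_matrix", "matrix"),
            cytokine = col_cyt, timepoint_h = col_tp,
            conditions = cond, zscored = FALSE, zeroed_columns = integer(0))
}

#' Column-wise z-scoring of a predictor matrix
#'
#' Centres every column and scales it by its sample standard deviation
#' (denominator n - 1). Zero-variance columns (e.g. cytokines never
#' detected) are set to all-zeros, kept in place to preserve the matrix
#' geometry, and recorded in the `zeroed_columns` attribute.
#'
#' @param X a [assemble_predictor_matrix()] result (or plain matrix).
#' @return the z-scored matrix with `zscored = TRUE`.
#' @export
zscore_columns <- function(X) {
  if (isTRUE(attr(X, "zscored"))) stop("matrix is already z-scored")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  dead <- which(!is.finite(s) | s == 0)
  s[dead] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, s, `/`)
  Z[, dead] <- 0
  attributes(Z) <- attributes(X)
  attr(Z, "zscored") <- TRUE
  attr(Z, "zeroed_columns") <- unname(dead)
  Z
}

## -- PLSR core ---------------------------------------------------------

.pls_nipals <- function(X, Y, A) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  E <- X; F <- Y
  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, m, A)
  TT <- matrix(0, n, A); U <- matrix(0, n, A)
  ssy <- ssx <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    u <- F[, which.max(colSums(F^2))]
    if (sum(u^2) < 1e-12 * max(1, sum(Y^2))) break
    w <- numeric(p)
    for (it in 1:1000) {
      wn <- drop(crossprod(E, u))
      nw <- sqrt(sum(wn^2))
      if (nw < 1e-14) break
      wn <- wn / nw
      t <- drop(E %*% wn)
      cc <- drop(crossprod(F, t)) / sum(t^2)
      u <- drop(F %*% cc) / sum(cc^2)
      if (sum((wn - w)^2) < 1e-24) { w <- wn; break }
      w <- wn
    }
    if (sqrt(sum(w^2)) < 0.5) break        # no usable direction left
    t <- drop(E %*% w)
    st <- sum(t^2)
    if (st < 1e-12 * max(1, sum(X^2))) break
    pp <- drop(crossprod(E, t)) / st
    cc <- drop(crossprod(F, t)) / st
    E <- E - tcrossprod(t, pp)
    F <- F - tcrossprod(t, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; TT[, a] <- t
    U[, a] <- u
    ssx[a] <- st * sum(pp^2)
    ssy[a] <- st * sum(cc^2)
    a_used <- a
  }
  if (a_used == 0L) stop("plsr_fit: X carries no usable variance")
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  C <- C[, keep, drop = FALSE]; TT <- TT[, keep, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(C))
  list(A = a_used, W = W, T = TT, P = P, Q = C, B = B,
       ssx = ssx[keep], ssy = ssy[keep])
}

.pls_simpls <- function(X, Y, A) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  S <- crossprod(X, Y)
  R <- matrix(0, p, A); V <- matrix(0, p, A); Q <- matrix(0, m, A)
  TT <- matrix(0, n, A); P <- matrix(0, p, A)
  ssy <- ssx <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    sv <- svd(S, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12 * max(1, sqrt(sum(crossprod(X, Y)^2)))) break
    q <- sv$v[, 1]
    r <- drop(S %*% q)
    t <- drop(X %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt; r <- r / nt
    pp <- drop(crossprod(X, t))
    qq <- drop(crossprod(Y, t))
    v <- pp
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pp)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v; Q[, a] <- qq; TT[, a] <- t; P[, a] <- pp
    ssx[a] <- sum(pp^2)                    # t is unit-norm
    ssy[a] <- sum(qq^2)
    a_used <- a
  }
  if (a_used == 0L) stop("plsr_fit: X'Y carries no usable covariance")
  keep <- seq_len(a_used)
  R <- R[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  TT <- TT[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  B <- tcrossprod(R, Q)
  list(A = a_used, W = R, T = TT, P = P, Q = Q, B = B,
       ssx = ssx[keep], ssy = ssy[keep])
}

#' Partial least squares regression (NIPALS or SIMPLS)
#'
#' Fits a PLSR model of the responses on the predictors with `A` latent
#' components, by either the NIPALS algorithm (sequential deflation of
#' predictor and response residuals) or the SIMPLS algorithm (deflation
#' of the cross-product matrix). Both centre `X` and `Y` internally;
#' `Y` columns are additionally scaled to unit variance by default
#' because the two osteoclastogenesis responses live on different count
#' scales (`scale_y = FALSE` fits raw centred responses). The fit is
#' fully deterministic.
#'
#' For a one-column response, or with as many components as the
#' centred-predictor rank, the two algorithms coincide; at intermediate
#' component counts with multiple responses their deflation schemes
#' differ and coefficients agree only approximately.
#'
#' @param X predictor matrix (n conditions x p predictors), typically
#'   z-scored via [zscore_columns()].
#' @param Y response matrix (n x m), e.g. monocyte and osteoclast
#'   nuclei at day 7.
#' @param A number of latent components, `1 <= A <= min(n - 1, p)`.
#'   Components whose scores carry no variance are dropped with a
#'   warning.
#' @param algorithm `"nipals"` or `"simpls"`.
#' @param scale_y scale response columns to unit variance before
#'   fitting.
#' @return an object of class `oc_plsr`: list with `A`, `W` (X-weights,
#'   p x A), `T` (X-scores, n x A), `P` (X-loadings), `Q` (Y-loadings,
#'   m x A), `B` (regression coefficients on the centred/scaled inner
#'   scale, p x m), `coefficients` (B back-scaled to original Y units),
#'   `intercept`, `ssx`, `ssy` (per-component explained sums of
#'   squares), `r2x`, `r2y` (fractions of total X / Y variance),
#'   `algorithm`, centring/scaling constants and labels.
#' @export
plsr_fit <- function(X, Y, A = 3, algorithm = c("nipals", "simpls"),
                     scale_y = TRUE) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 2L) stop("at least 2 observations are required")
  if (A < 1L || A > min(n - 1L, p))
    stop(sprintf("A must be in [1, min(n - 1, p)] = [1, %d]", min(n - 1L, p)))
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  y_scale <- if (scale_y) apply(Y, 2, sd) else rep(1, m)
  y_scale[!is.finite(y_scale) | y_scale == 0] <- 1
  Xc <- sweep(X, 2, x_center)
  Yc <- sweep(sweep(Y, 2, y_center), 2, y_scale, `/`)
  core <- if (algorithm == "nipals") .pls_nipals(Xc, Yc, A)
          else .pls_simpls(Xc, Yc, A)
  if (core$A < A)
    warning(sprintf("rank-deficient fit: using %d of %d requested components",
                    core$A, A))
  ssx_tot <- sum(Xc^2); ssy_tot <- sum(Yc^2)
  coefficients <- sweep(core$B, 2, y_scale, `*`)
  intercept <- y_center - drop(crossprod(coefficients, x_center))
  fit <- c(core,
           list(coefficients = coefficients, intercept = intercept,
                r2x = core$ssx / ssx_tot, r2y = core$ssy / ssy_tot,
                algorithm = algorithm,
                x_center = x_center, y_center = y_center,
                y_scale = y_scale, scale_y = scale_y,
                x_labels = colnames(X), y_labels = colnames(Y),
                cytokine = attr(X, "cytokine"),
                timepoint_h = attr(X, "timepoint_h")))
  class(fit) <- "oc_plsr"
  fit
}

#' @export
print.oc_plsr <- function(x, digits = 3, ...) {
  cat(sprintf("Partial least squares regression (%s), %d component%s\n",
              toupper(x$algorithm), x$A, if (x$A > 1) "s" else ""))
  cat(sprintf("  %d predictors, %d response%s (%s)\n", nrow(x$B),
              ncol(x$B), if (ncol(x$B) > 1) "s" else "",
              paste(x$y_labels, collapse = ", ")))
  cat("  explained variance per component:\n")
  tab <- rbind(X = signif(x$r2x, digits), Y = signif(x$r2y, digits))
  colnames(tab) <- paste0("comp", seq_len(x$A))
  print(tab)
  invisible(x)
}

#' @export
summary.oc_plsr <- function(object, ...) {
  print(object)
  cat(sprintf("  cumulative: X %.1f%%, Y %.1f%%\n",
              100 * sum(object$r2x), 100 * sum(object$r2y)))
  v <- vip(object)
  top <- head(order(v, decreasing = TRUE), 5)
  cat("  top VIP predictors:\n")
  for (i in top)
    cat(sprintf("    %-24s %.3f\n", object$x_labels[i] %||% i, v[i]))
  invisible(object)
}

#' @export
coef.oc_plsr <- function(object, scale = c("original", "inner"), ...) {
  scale <- match.arg(scale)
  B <- if (scale == "original") object$coefficients else object$B
  rownames(B) <- object$x_labels
  colnames(B) <- object$y_labels
  B
}

#' Predict responses from a fitted PLSR model
#'
#' @param object an [plsr_fit()] model.
#' @param newdata predictor matrix on the same scale as the training
#'   `X`; defaults to fitted values being unavailable, so `newdata` is
#'   required.
#' @param ... unused.
#' @return matrix of predicted responses in original `Y` units.
#' @export
predict.oc_plsr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata %*% object$coefficients, 2, object$intercept, `+`)
}

#' @export
residuals.oc_plsr <- function(object, X, Y, ...) {
  as.matrix(Y) - predict(object, X)
}

#' @export
plot.oc_plsr <- function(x, comps = c(1, 2), ...) {
  if (x$A < 2) stop("plot.oc_plsr needs at least 2 components")
  T <- x$T[, comps, drop = FALSE]
  plot(T[, 1], T[, 2],
       xlab = sprintf("component %d scores (X var %.0f%%)", comps[1],
                      100 * x$r2x[comps[1]]),
       ylab = sprintf("component %d scores (X var %.0f%%)", comps[2],
                      100 * x$r2x[comps[2]]),
       main = "PLSR condition scores", pch = 19, ...)
  text(T[, 1], T[, 2], labels = seq_len(nrow(T)), pos = 3)
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja} / \|w_a\|)^2 / \sum_a SS_a}}
#' where \eqn{SS_a} is the response sum of squares explained by
#' component \eqn{a}, so importance is accumulated over all responses.
#' By construction the mean squared VIP over predictors equals 1
#' (\eqn{\sum_j VIP_j^2 = p}).
#'
#' @param fit an [plsr_fit()] model.
#' @return named numeric vector, one VIP per predictor.
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "oc_plsr"))
  if (all(fit$ssy <= 0)) stop("vip: no explained response variance")
  Wn <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), `/`)
  v <- sqrt(nrow(fit$W) * drop(Wn^2 %*% fit$ssy) / sum(fit$ssy))
  names(v) <- fit$x_labels
  v
}

#' Cumulative regulator ranking over timepoints
#'
#' Collapses per-(cytokine, timepoint) predictor scores into one
#' cumulative score per cytokine by summing the raw scores over the
#' timepoints, and ranks cytokines on it. For signed scores (regression
#' coefficients) the sign of the cumulative score labels the cytokine a
#' positive or negative regulator of the chosen response; for VIP
#' scores the ranking is by (unsigned) cumulative importance. Ties are
#' broken deterministically by first appearance in the predictor
#' labels.
#'
#' @param fit an [plsr_fit()] model fitted on an
#'   [assemble_predictor_matrix()] matrix (so per-column cytokine and
#'   timepoint labels are available).
#' @param type `"vip"` or `"coefficient"`.
#' @param response for `type = "coefficient"`, response name or index.
#' @return data frame of class `ranking_table`, one row per cytokine,
#'   ordered by decreasing cumulative score: `cytokine`, one
#'   `t<hours>h` column per timepoint, `cumulative`, `direction`
#'   (`"positive"`/`"negative"`, coefficient rankings only) and `rank`.
#' @export
rank_regulators <- function(fit, type = c("vip", "coefficient"),
                            response = 1L) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "oc_plsr"))
  cyt <- fit$cytokine; tp <- fit$timepoint_h
  if (is.null(cyt) || is.null(tp))
    stop("fit was not made from an assembled predictor matrix ",
         "(cytokine/timepoint labels missing)")
  score <- switch(type,
                  vip = vip(fit),
                  coefficient = {
                    if (is.character(response))
                      response <- match(response, fit$y_labels)
                    coef(fit, scale = "inner")[, response]
                  })
  tps <- sort(unique(tp))
  cyts <- unique(cyt)
  if (!setequal(unique(tp), tps) || anyNA(score))
    stop("rank_regulators: missing timepoint scores")
  wide <- matrix(NA_real_, length(cyts), length(tps),
                 dimnames = list(cyts, sprintf("t%03dh", as.integer(tps))))
  wide[cbind(match(cyt, cyts), match(tp, tps))] <- score
  if (anyNA(wide)) {
    miss <- which(is.na(wide), arr.ind = TRUE)
    stop("rank_regulators: missing score for ", cyts[miss[1, 1]], " at ",
         colnames(wide)[miss[1, 2]])
  }
  cumulative <- rowSums(wide)
  ord <- order(-cumulative, match(cyts, cyts))   # label-order tie-break
  out <- data.frame(cytokine = cyts, wide, cumulative = cumulative,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (type == "coefficient")
    out$direction <- ifelse(cumulative >= 0, "positive", "negative")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Positive/negative/VIP regulator tables
#'
#' Convenience wrapper producing the three cumulative ranking tables:
#' positive regulators (largest cumulative summed coefficients first)
#' and negative regulators (most negative first) for each response, and
#' the cumulative-VIP table across both responses.
#'
#' @param fit an [plsr_fit()] model (see [rank_regulators()]).
#' @return list with elements `positive` and `negative` (each a list,
#'   one ranking table per response) and `vip`.
#' @export
regulator_tables <- function(fit) {
  resp <- fit$y_labels
  pos <- neg <- setNames(vector("list", length(resp)), resp)
  for (r in seq_along(resp)) {
    tab <- rank_regulators(fit, "coefficient", r)
    pos[[r]] <- tab
    ntab <- tab[order(tab$cumulative, match(tab$cytokine, tab$cytokine)), ]
    ntab$rank <- seq_len(nrow(ntab))
    rownames(ntab) <- NULL
    neg[[r]] <- ntab
  }
  list(positive = pos, negative = neg,
       vip = rank_regulators(fit, "vip"))
}

#' Condition scores and predictor loadings for plotting
#'
#' Emits the latent-component condition scores (components 1--3) and
#' predictor loadings (components 1--2) with per-component explained
#' variance fractions -- the projection underlying the
#' treatment-clustering and cytokine-weight biplots. Explained-variance
#' fractions are not necessarily monotone over components for PLSR.
#'
#' @param fit an [plsr_fit()] model with at least 2 components.
#' @return list with `scores` (data frame: condition, t1, t2 and t3
#'   when available), `loadings` (data frame: predictor, loading1,
#'   loading2), `explained_x`, `explained_y`.
#' @export
scores_and_loadings <- function(fit) {
  stopifnot(inherits(fit, "oc_plsr"))
  if (fit$A < 2) stop("scores_and_loadings requires at least 2 components")
  k <- min(3L, fit$A)
  scores <- data.frame(condition = seq_len(nrow(fit$T)),
                       fit$T[, seq_len(k), drop = FALSE])
  names(scores)[-1] <- paste0("t", seq_len(k))
  loadings <- data.frame(predictor = fit$x_labels %||%
                           as.character(seq_len(nrow(fit$P))),
                         loading1 = fit$P[, 1], loading2 = fit$P[, 2],
                         stringsAsFactors = FALSE)
  list(scores = scores, loadings = loadings,
       explained_x = fit$r2x, explained_y = fit$r2y)
}
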