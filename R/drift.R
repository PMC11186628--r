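#' Fit the retention-time drift by weighted spline regression
#'
#' Estimates the systematic map f from study-1 RT to study-2 RT using the
#' soft matches in the coupling: every support pair (i, j) with positive
#' weight contributes the point (RTx[i], RTy[j]) weighted by its coupling
#' entry, and a degree-`order` B-spline is fitted under the weighted
#' absolute (L1) loss `sum_ij pi[i,j] |f(RTx[i]) - RTy[j]|`. The L1 loss is
#' minimized by iteratively reweighted least squares (3 reweighting
#' rounds); `loss = "l2"` fits the plain weighted least-squares criterion
#' instead, and both agree on noiseless data. The number of interior knots
#' is chosen from `knot_grid` by cross-validation on the support pairs
#' (folds shuffled with `seed`, loss weighted by the coupling), with knots
#' placed at weighted quantiles of the support RTx.
#'
#' @param coupling a [coupling()] (or nonnegative matrix).
#' @param rt_x,rt_y retention-time vectors of study 1 (rows) and study 2
#'   (columns), minutes.
#' @param order spline degree (default cubic).
#' @param knot_grid candidate interior-knot counts.
#' @param cv_folds number of cross-validation folds.
#' @param seed seed for the fold shuffle.
#' @param loss `"l1"` (default) or `"l2"`.
#' @return a `drift_model`: list with `order`, `knots` (interior),
#'   `boundary`, `coefficients`, `cv_table`, `cv_score`.
#' @export
fit_drift <- function(coupling, rt_x, rt_y, order = 3,
                      knot_grid = c(3, 5, 7, 10, 15), cv_folds = 10,
                      seed = 1L, loss = c("l1", "l2")) {
  loss <- match.arg(loss)
  P <- as_coupling_matrix(coupling)
  stopifnot(nrow(P) == length(rt_x), ncol(P) == length(rt_y))
  sup <- which(P > 0, arr.ind = TRUE)
  w <- P[sup]
  x <- rt_x[sup[, 1]]
  y <- rt_y[sup[, 2]]
  npairs <- length(w)
  feasible <- knot_grid[npairs >= order + knot_grid + 2]
  if (npairs < order + min(knot_grid) + 2 || length(feasible) == 0) {
    stop("fit_drift: too few coupling support pairs (", npairs,
         ") for the requested spline; relaxing rho or eps yields a denser coupling")
  }
  boundary <- range(rt_x)

  # Folds are shuffled in value order of the support pairs (not in their
  # enumeration order), so the fit is equivariant under feature
  # permutations.
  folds <- integer(npairs)
  folds[order(x, y, w)] <- with_preserved_seed({
    set.seed(seed)
    sample(rep_len(seq_len(min(cv_folds, npairs)), npairs))
  })
  fold_err <- vapply(feasible, function(k) {
    vapply(sort(unique(folds)), function(f) {
      test <- folds == f
      fit <- spline_wfit(x[!test], y[!test], w[!test], order, k, boundary,
                         loss)
      pred <- spline_eval(fit, x[test], order, boundary)
      sum(w[test] * abs(pred - y[test])^(if (loss == "l1") 1 else 2)) /
        sum(w[test])
    }, numeric(1))
  }, numeric(length(unique(folds))))
  fold_err <- matrix(fold_err, ncol = length(feasible))
  cv_err <- colMeans(fold_err)
  k_best <- feasible[which.min(cv_err)] # ties resolve to fewer knots

  fit <- spline_wfit(x, y, w, order, k_best, boundary, loss)
  structure(
    list(order = as.integer(order), knots = fit$knots, boundary = boundary,
         coefficients = fit$coefficients,
         cv_table = data.frame(knots = feasible, cv_error = cv_err),
         cv_score = min(cv_err)),
    class = "drift_model"
  )
}

# Weighted quantile of x at probabilities p.
weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(p, function(pr) x[which.min(abs(cw - pr))], numeric(1))
}

# Fit a single B-spline with k interior knots at weighted quantiles.
# IRLS rounds approximate the weighted L1 loss.
spline_wfit <- function(x, y, w, order, k, boundary, loss) {
  probs <- seq_len(k) / (k + 1)
  knots <- weighted_quantile(x, w, probs)
  eps_b <- 1e-8 * diff(boundary)
  knots <- pmin(pmax(knots, boundary[1] + eps_b), boundary[2] - eps_b)
  B <- drift_basis(x, order, knots, boundary)
  ww <- w
  rounds <- if (loss == "l1") 3 else 1
  coefs <- NULL
  for (r in seq_len(rounds)) {
    fit <- stats::lm.wfit(B, y, ww)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    if (loss == "l1" && r < rounds) {
      resid <- abs(y - drop(B %*% coefs))
      # Huberized reweighting: flooring at a tenth of the typical residual
      # bounds the weights, so near-zero residuals cannot force the spline
      # to interpolate them.
      delta <- max(0.1 * weighted_quantile(resid, w, 0.5), 1e-9)
      ww <- w / pmax(resid, delta)
    }
  }
  list(coefficients = coefs, knots = knots)
}

drift_basis <- function(x, order, knots, boundary) {
  x <- pmin(pmax(x, boundary[1]), boundary[2]) # clamp: no wild extrapolation
  cbind(1, splines::bs(x, knots = knots, degree = order,
                       Boundary.knots = boundary))
}

spline_eval <- function(fit_or_model, x, order = NULL, boundary = NULL) {
  if (inherits(fit_or_model, "drift_model")) {
    m <- fit_or_model
    B <- drift_basis(x, m$order, m$knots, m$boundary)
    drop(B %*% m$coefficients)
  } else {
    drop(drift_basis(x, order, fit_or_model$knots, boundary) %*%
           fit_or_model$coefficients)
  }
}

#' Predict study-2 retention times from a fitted drift model
#'
#' @param object a `drift_model` from [fit_drift()].
#' @param x study-1 retention times (clamped to the fitted range).
#' @param ... unused.
#' @return predicted study-2 retention times.
#' @export
predict.drift_model <- function(object, x, ...) {
  spline_eval(object, x)
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "<drift_model> degree %d B-spline, %d interior knots (CV loss %.4g) on RT [%.2f, %.2f]\n",
    x$order, length(x$knots), x$cv_score, x$boundary[1], x$boundary[2]
  ))
  invisible(x)
}

#' Residual statistics of a drift fit
#'
#' For every support pair (i, j) of the coupling, the residual is
#' `|f(RTx[i]) - RTy[j]|`. Summaries follow the robust filtering rule:
#' `PI = 1.96 * std(residuals)` (population standard deviation, an
#' approximate 95 percent prediction interval), `mu_r` the median residual,
#' and `MAD = median(|residuals - mu_r|)`.
#'
#' @param drift a `drift_model`.
#' @param coupling a [coupling()] or matrix.
#' @param rt_x,rt_y retention-time vectors.
#' @return a `residual_stats`: list with `pairs` (two-column index matrix),
#'   `residuals`, `PI`, `MAD`, `mu_r`.
#' @export
compute_residual_stats <- function(drift, coupling, rt_x, rt_y) {
  P <- as_coupling_matrix(coupling)
  sup <- which(P > 0, arr.ind = TRUE)
  if (nrow(sup) == 0) stop("compute_residual_stats: empty coupling support")
  r <- abs(predict(drift, rt_x[sup[, 1]]) - rt_y[sup[, 2]])
  mu_r <- stats::median(r)
  structure(
    list(pairs = unname(sup[, 1:2, drop = FALSE]), residuals = unname(r),
         PI = 1.96 * sqrt(mean((r - mean(r))^2)),
         MAD = stats::median(abs(r - mu_r)), mu_r = mu_r),
    class = "residual_stats"
  )
}

#' Filter a coupling by drift residuals
#'
#' Zeroes every support entry whose residual exceeds `mu_r + r_thresh`.
#' Survival is inclusive (`residual <= mu_r + r_thresh + 1e-12`) so that a
#' perfect drift fit, where all residuals and the MAD are zero, keeps all
#' pairs.
#'
#' @param coupling a [coupling()] or matrix.
#' @param stats a `residual_stats` for the same coupling.
#' @param r_thresh nonnegative residual threshold (minutes).
#' @return the filtered coupling, same class as the input surviving entries
#'   unchanged.
#' @export
filter_coupling <- function(coupling, stats, r_thresh) {
  stopifnot(r_thresh >= 0)
  P <- as_coupling_matrix(coupling)
  drop_idx <- stats$residuals > stats$mu_r + r_thresh + 1e-12
  P[stats$pairs[drop_idx, , drop = FALSE]] <- 0
  if (inherits(coupling, "coupling")) {
    coupling$pi <- P
    coupling
  } else {
    P
  }
}

#' Drift estimation and two-stage outlier filtering
#'
#' The full retention-time refinement: the drift is fitted and pairs
#' outside the 95 percent prediction interval are discarded
#' (`r_thresh = PI`), twice; the drift is then re-estimated a final time
#' and the stricter `r_thresh = 2 * MAD` cut is applied. Repeated
#' estimation makes the drift fit robust to the gross outliers present in
#' the raw coupling.
#'
#' @param coupling a [coupling()].
#' @param rt_x,rt_y retention-time vectors.
#' @param config an [alignment_config()] supplying spline order, knot grid,
#'   CV folds and seed.
#' @return list with `coupling` (filtered) and `drift` (final
#'   `drift_model`).
#' @export
drift_filter_pipeline <- function(coupling, rt_x, rt_y,
                                  config = alignment_config()) {
  fit_args <- function(stage) {
    list(order = config$spline_order, knot_grid = config$knot_grid,
         cv_folds = config$cv_folds, seed = config$seed + stage)
  }
  for (stage in 1:2) {
    drift <- do.call(fit_drift, c(list(coupling, rt_x, rt_y), fit_args(stage)))
    stats <- compute_residual_stats(drift, coupling, rt_x, rt_y)
    coupling <- filter_coupling(coupling, stats, stats$PI)
  }
  drift <- do.call(fit_drift, c(list(coupling, rt_x, rt_y), fit_args(3)))
  stats <- compute_residual_stats(drift, coupling, rt_x, rt_y)
  coupling <- filter_coupling(coupling, stats, 2 * stats$MAD)
  list(coupling = coupling, drift = drift)
}

#' Drift diagnostics table
#'
#' Per support pair of the (pre-filter) coupling: both retention times, the
#' coupling weight, the residual under the supplied drift model and whether
#' the pair survives the given threshold. Useful for drift plots.
#'
#' @param drift a `drift_model`.
#' @param coupling a [coupling()] or matrix.
#' @param rt_x,rt_y retention-time vectors.
#' @param r_thresh residual threshold used for the `kept` flag (defaults to
#'   `2 * MAD`).
#' @return a data.frame with columns `rt_x`, `rt_y`, `weight`, `residual`,
#'   `kept`.
#' @export
drift_diagnostics <- function(drift, coupling, rt_x, rt_y, r_thresh = NULL) {
  P <- as_coupling_matrix(coupling)
  stats <- compute_residual_stats(drift, coupling, rt_x, rt_y)
  if (is.null(r_thresh)) r_thresh <- 2 * stats$MAD
  data.frame(
    rt_x = rt_x[stats$pairs[, 1]], rt_y = rt_y[stats$pairs[, 2]],
    weight = P[stats$pairs], residual = stats$residuals,
    kept = stats$residuals <= stats$mu_r + r_thresh + 1e-12
  )
}
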