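#' Alignment configuration
#'
#' Collects the tunable parameters of the alignment pipeline. Defaults
#' follow the method's standard settings: marginal relaxation rho = 0.05 and
#' entropic weight eps = 0.005 (the smallest values under which the solver
#' converges reliably), m/z tolerance 0.01 Da, cubic drift splines with the
#' knot count chosen by 10-fold cross-validation, and no coupling
#' thresholding (tau = 0). Setting tau = 0.3 gives the thresholded variant
#' (see [gmt_config()]).
#'
#' @param metric distance between intensity profiles: `"normalized_euclidean"`
#'   (default; equals the cosine distance up to a factor after
#'   [center_scale()]) or `"cosine"`.
#' @param center_scale standardize each feature's intensities before
#'   computing distances (recommended across studies with incomparable
#'   intensity scales).
#' @param rho positive marginal-relaxation weight; larger values push more
#'   features to be matched.
#' @param eps positive entropic weight; larger values smooth the coupling
#'   and stabilize the solver at the price of less concentrated matches.
#' @param m_gap m/z compatibility tolerance. Interpreted in Da when
#'   `mz_mode = "da"` (default), or parts-per-million of the study-1 m/z
#'   when `mz_mode = "ppm"`.
#' @param mz_mode `"da"` or `"ppm"`, see `m_gap`.
#' @param tau coupling threshold in \[0, 1\]; entries below
#'   `tau * max(coupling)` are dropped before one-to-one extraction. 0
#'   disables thresholding.
#' @param spline_order B-spline degree for the RT drift fit.
#' @param knot_grid candidate interior-knot counts for drift-fit model
#'   selection.
#' @param cv_folds cross-validation folds for knot selection.
#' @param max_outer,max_inner,tol solver iteration limits and convergence
#'   tolerance (relative max-abs change of the coupling between outer
#'   iterations).
#' @param seed integer seed controlling the cross-validation fold shuffle
#'   (the transport solver itself is deterministic).
#' @return a list of class `alignment_config`.
#' @export
alignment_config <- function(metric = c("normalized_euclidean", "cosine"),
                             center_scale = TRUE,
                             rho = 0.05,
                             eps = 0.005,
                             m_gap = 0.01,
                             mz_mode = c("da", "ppm"),
                             tau = 0,
                             spline_order = 3,
                             knot_grid = c(3, 5, 7, 10, 15),
                             cv_folds = 10,
                             max_outer = 200,
                             max_inner = 500,
                             tol = 1e-6,
                             seed = 1L) {
  metric <- match.arg(metric)
  mz_mode <- match.arg(mz_mode)
  stopifnot(rho > 0, eps > 0, m_gap > 0, tau >= 0, tau <= 1,
            spline_order >= 1, cv_folds >= 2, max_outer >= 1,
            max_inner >= 1, tol > 0)
  structure(
    list(
      metric = metric, center_scale = center_scale, rho = rho, eps = eps,
      m_gap = m_gap, mz_mode = mz_mode, tau = tau,
      spline_order = as.integer(spline_order),
      knot_grid = as.integer(knot_grid), cv_folds = as.integer(cv_folds),
      max_outer = as.integer(max_outer), max_inner = as.integer(max_inner),
      tol = tol, seed = as.integer(seed)
    ),
    class = "alignment_config"
  )
}

#' Preset configurations for the two pipeline variants
#'
#' `gm_config()` is the plain pipeline (no coupling thresholding);
#' `gmt_config()` additionally drops coupling entries below 0.3 times the
#' maximum before one-to-one extraction, trading a little recall for
#' precision in noisy settings.
#'
#' @param ... overrides passed to [alignment_config()].
#' @return an `alignment_config`.
#' @export
gm_config <- function(...) alignment_config(...)

#' @rdname gm_config
#' @export
gmt_config <- function(...) {
  args <- list(...)
  if (is.null(args$tau)) args$tau <- 0.3
  do.call(alignment_config, args)
}

#' Simulation split configuration
#'
#' Parameters of the ground-truth generator that splits one base feature
#' table into two overlapping noisy studies. Defaults are the medium-noise
#' study conditions: m/z noise uniform on \[-0.01, 0.01\] Da, RT noise
#' uniform on \[-0.5, 0.5\] min on top of the systematic drift
#' f(x) = 1.1 x + 1.3 sin(1.2 x), and Gaussian intensity noise with
#' standard deviation 0.5 added independently in both studies.
#'
#' @param overlap fraction lambda of base features shared by the two
#'   studies (0.25 / 0.5 / 0.75 are the low / medium / high settings).
#' @param sigma_m half-width of the uniform m/z noise, Da.
#' @param sigma_rt half-width of the uniform RT noise, minutes (0.2 / 0.5 /
#'   1 are the low / medium / high settings).
#' @param sigma_fi standard deviation of the Gaussian intensity noise
#'   (0.1 / 0.5 / 1 are the low / medium / high settings).
#' @param apply_drift apply the systematic RT drift to study 2.
#' @param seed master seed; independent sub-streams are derived from it for
#'   the split and for each noise source.
#' @param n1 optional override for the study-1 sample count (defaults to
#'   floor(n/2)).
#' @return a list of class `split_config`.
#' @export
split_config <- function(overlap = 0.5, sigma_m = 0.01, sigma_rt = 0.5,
                         sigma_fi = 0.5, apply_drift = TRUE, seed = 1L,
                         n1 = NULL) {
  stopifnot(overlap >= 0, overlap <= 1, sigma_m >= 0, sigma_rt >= 0,
            sigma_fi >= 0)
  structure(
    list(
      overlap = overlap, sigma_m = sigma_m, sigma_rt = sigma_rt,
      sigma_fi = sigma_fi, apply_drift = isTRUE(apply_drift),
      seed = as.integer(seed), n1 = if (is.null(n1)) NULL else as.integer(n1)
    ),
    class = "split_config"
  )
}

# Derive k reproducible sub-seeds from a master seed without disturbing the
# caller's RNG state. Fixed slot order keeps streams stable when one
# consumer is added or removed.
subseeds <- function(seed, k) {
  with_preserved_seed({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, k)
  })
}

# Evaluate `expr` and restore the global RNG state afterwards.
with_preserved_seed <- function(expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
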