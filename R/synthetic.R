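#' Systematic retention-time drift used in simulations
#'
#' The nonlinear map applied to study-2 retention times,
#' `f(x) = 1.1 x + 1.3 sin(1.2 x)`, emulating the smooth inter-study drift
#' observed between LC-MS experiments run under different chromatographic
#' conditions.
#'
#' @param x retention times, minutes.
#' @return drifted retention times.
#' @examples
#' rt_drift_function(1.0) # 2.3117
#' @export
rt_drift_function <- function(x) 1.1 * x + 1.3 * sin(1.2 * x)

#' Fabricate a base feature table with correlated intensities
#'
#' Generates a synthetic stand-in for a real normalized LC-MS feature
#' table, so the simulation framework runs without any external download.
#' Intensities follow a block factor model: features are assigned to
#' `n_blocks` latent factors and feature i's profile is
#' `mu_i + s_i * (l_i * F_block(i) + sqrt(1 - l_i^2) * noise)` with loading
#' `l_i ~ U(0.3, 0.95)`, lognormal per-feature scale `s_i` (median 1) and
#' mean `mu_i ~ N(12, 2)` on a log-abundance-like scale. Blocks emulate the
#' strongly correlated groups (adducts, isotopologues, pathway neighbours)
#' that make real correlation structure informative but locally ambiguous.
#'
#' m/z values are drawn uniformly on \[70, 1000\] Da. A fraction
#' `frac_spaced` of features is guaranteed pairwise m/z gaps larger than
#' `2 * sigma_m`; the remainder is planted within `2 * sigma_m` of an
#' existing feature, emulating near-isobaric crowding. Retention times are
#' uniform on \[0.5, 12\] minutes.
#'
#' @param p,n number of features and samples (both at least 2).
#' @param n_blocks number of latent correlation blocks (default: one block
#'   per ~20 features).
#' @param seed integer seed; identical seeds give identical tables.
#' @param frac_spaced fraction of features with guaranteed m/z spacing.
#' @param sigma_m m/z noise half-width the spacing guarantee refers to, Da.
#' @return a [feature_table()].
#' @export
generate_base_table <- function(p, n, n_blocks = max(1L, round(p / 20)),
                                seed = 1L, frac_spaced = 0.75,
                                sigma_m = 0.01) {
  stopifnot(p >= 2, n >= 2, n_blocks >= 1)
  with_preserved_seed({
    set.seed(seed)
    block <- sample.int(n_blocks, p, replace = TRUE)
    loading <- stats::runif(p, 0.3, 0.95)
    factors <- matrix(stats::rnorm(n_blocks * n), n_blocks, n)
    noise <- matrix(stats::rnorm(p * n), p, n)
    z <- loading * factors[block, , drop = FALSE] +
      sqrt(1 - loading^2) * noise
    scales <- exp(stats::rnorm(p, 0, 0.4))
    mus <- stats::rnorm(p, 12, 2)
    intens <- mus + scales * z

    n_spaced <- max(2L, round(frac_spaced * p))
    n_spaced <- min(n_spaced, p)
    mz <- stats::runif(n_spaced, 70, 1000)
    for (iter in 1:100) { # redraw colliding values until spacing holds
      gaps_ok <- c(TRUE, diff(sort(mz)) > 2 * sigma_m)
      bad <- sort(mz)[!gaps_ok]
      if (length(bad) == 0) break
      mz[mz %in% bad] <- stats::runif(length(bad), 70, 1000)
    }
    n_near <- p - n_spaced
    if (n_near > 0) {
      anchor <- sample(mz, n_near, replace = TRUE)
      mz <- c(mz, anchor + stats::runif(n_near, -2 * sigma_m, 2 * sigma_m))
    }
    rt <- stats::runif(p, 0.5, 12)

    feature_table(
      feature_ids = sprintf("F%05d", seq_len(p)), mz = mz, rt = rt,
      intensities = intens, sample_ids = sprintf("S%04d", seq_len(n))
    )
  })
}

#' Split a base table into two overlapping ground-truth studies
#'
#' Samples are divided disjointly: `n1 = floor(n/2)` random samples form
#' study 1 and the rest form study 2. Features are divided with overlap
#' `lambda`: `s = round(lambda * p)` randomly chosen features go into both
#' studies (s is decremented by 1 when `p - s` is odd, so the remaining
#' study-specific features split equally and `p1 = p2`). Feature order
#' within each study is shuffled. No noise is applied here; see
#' [apply_noise()].
#'
#' @param base a [feature_table()] with at least 4 features.
#' @param config a [split_config()].
#' @return a `ground_truth_pair`: list with `study1`, `study2`
#'   ([feature_table()]s), the binary ground-truth matching `m_star`
#'   (p1 x p2), and `config`.
#' @export
split_dataset <- function(base, config = split_config()) {
  validate_feature_table(base)
  p <- n_features(base)
  n <- n_samples(base)
  stopifnot(p >= 4)
  arith <- split_arithmetic(p, n, config$overlap, config$n1)
  seeds <- subseeds(config$seed, 5L)

  with_preserved_seed({
    set.seed(seeds[1])
    samp1 <- sort(sample.int(n, arith$n1))
    samp2 <- setdiff(seq_len(n), samp1)
    shared <- sample.int(p, arith$s)
    rest <- sample(setdiff(seq_len(p), shared))
    only1 <- rest[seq_len(arith$k_specific)]
    only2 <- rest[arith$k_specific + seq_len(arith$k_specific)]
    feats1 <- sample(c(shared, only1))
    feats2 <- sample(c(shared, only2))

    take <- function(feat_idx, sample_idx) {
      feature_table(
        feature_ids = base$feature_ids[feat_idx], mz = base$mz[feat_idx],
        rt = base$rt[feat_idx],
        intensities = base$intensities[feat_idx, sample_idx, drop = FALSE],
        sample_ids = base$sample_ids[sample_idx]
      )
    }
    m_star <- matrix(0L, arith$p1, arith$p2)
    m_star[cbind(match(shared, feats1), match(shared, feats2))] <- 1L

    structure(
      list(study1 = take(feats1, samp1), study2 = take(feats2, samp2),
           m_star = m_star, config = config),
      class = "ground_truth_pair"
    )
  })
}

#' Split arithmetic for the ground-truth generator
#'
#' Computes the deterministic counts implied by a split: the shared feature
#' count `s = round(overlap * p)` (decremented by one when `p - s` is odd
#' so the study-specific remainder splits evenly), the per-study feature
#' counts `p1 = p2 = s + (p - s)/2`, and the sample counts
#' `n1 = floor(n/2)`, `n2 = n - n1`.
#'
#' @param p,n base table feature and sample counts.
#' @param overlap shared-feature fraction lambda.
#' @param n1 optional explicit study-1 sample count.
#' @return list with `s`, `k_specific`, `p1`, `p2`, `n1`, `n2`.
#' @examples
#' split_arithmetic(4712, 499, 0.5) # s = 2356, p1 = p2 = 3534, n1 = 249
#' @export
split_arithmetic <- function(p, n, overlap, n1 = NULL) {
  s <- round(overlap * p)
  if ((p - s) %% 2 == 1) s <- s - 1
  if (s < 0) stop("split_arithmetic: overlap too small for this p")
  k_specific <- (p - s) / 2
  if (is.null(n1)) n1 <- floor(n / 2)
  list(s = s, k_specific = k_specific, p1 = s + k_specific,
       p2 = s + k_specific, n1 = n1, n2 = n - n1)
}

#' Apply the simulation noise model to a ground-truth pair
#'
#' Study-2 m/z values receive uniform noise on \[-sigma_m, sigma_m\].
#' Study-2 retention times are first deviated by the systematic drift
#' [rt_drift_function()] (when `apply_drift` is on) and then perturbed by
#' uniform noise on \[-sigma_rt, sigma_rt\]. Finally, independent Gaussian
#' noise with standard deviation `sigma_fi` is added to the intensities of
#' both studies. The ground-truth matching is unchanged. Each noise source
#' draws from its own sub-stream of the master seed, so switching one
#' source off does not shift the others.
#'
#' @param pair a `ground_truth_pair` from [split_dataset()].
#' @param config a [split_config()] (defaults to the pair's own).
#' @return the perturbed `ground_truth_pair`.
#' @export
apply_noise <- function(pair, config = pair$config) {
  stopifnot(inherits(pair, "ground_truth_pair"))
  seeds <- subseeds(config$seed, 5L)
  s1 <- pair$study1
  s2 <- pair$study2
  with_preserved_seed({
    set.seed(seeds[2])
    if (config$sigma_m > 0) {
      s2$mz <- s2$mz +
        stats::runif(n_features(s2), -config$sigma_m, config$sigma_m)
    }
    set.seed(seeds[3])
    if (config$apply_drift) s2$rt <- rt_drift_function(s2$rt)
    if (config$sigma_rt > 0) {
      s2$rt <- pmax(0, s2$rt +
        stats::runif(n_features(s2), -config$sigma_rt, config$sigma_rt))
    }
    set.seed(seeds[4])
    if (config$sigma_fi > 0) {
      s1$intensities <- s1$intensities +
        stats::rnorm(length(s1$intensities), 0, config$sigma_fi)
    }
    set.seed(seeds[5])
    if (config$sigma_fi > 0) {
      s2$intensities <- s2$intensities +
        stats::rnorm(length(s2$intensities), 0, config$sigma_fi)
    }
  })
  pair$study1 <- s1
  pair$study2 <- s2
  pair$config <- config
  pair
}

#' Generate one noisy ground-truth study pair
#'
#' Convenience wrapper: [split_dataset()] followed by [apply_noise()].
#'
#' @param base a [feature_table()].
#' @param config a [split_config()].
#' @return a `ground_truth_pair`.
#' @export
simulate_study_pair <- function(base, config = split_config()) {
  apply_noise(split_dataset(base, config), config)
}

#' Benchmark alignment methods on simulated ground-truth pairs
#'
#' For every split configuration in `grid` and every repetition, a noisy
#' ground-truth pair is generated (each repetition gets its own sub-seed)
#' and every method is scored against the known matching. Methods are
#' given either as `alignment_config` objects -- in which case configs that
#' differ only in their threshold `tau` share a single transport solve and
#' drift fit, since thresholding is a cheap post-processing step -- or as
#' functions `f(t1, t2)` returning a binary matching matrix.
#'
#' @param base the base [feature_table()] to split.
#' @param grid list of [split_config()]s (their `seed` fields are
#'   overridden by per-repetition sub-seeds derived from `seed`).
#' @param n_reps repetitions per configuration.
#' @param methods named list of `alignment_config`s or matching functions.
#' @param seed master seed.
#' @return a data.frame with one row per (configuration, repetition,
#'   method): overlap and noise levels, confusion counts, precision, recall
#'   and F1.
#' @export
run_benchmark <- function(base, grid, n_reps = 5,
                          methods = list(gm = gm_config(),
                                         gmt = gmt_config()),
                          seed = 1L) {
  if (inherits(grid, "split_config")) grid <- list(grid)
  stopifnot(length(methods) > 0, !is.null(names(methods)))
  rep_seeds <- matrix(subseeds(seed, length(grid) * n_reps),
                      nrow = length(grid))
  rows <- list()
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    for (r in seq_len(n_reps)) {
      cfg$seed <- rep_seeds[ci, r]
      pair <- simulate_study_pair(base, cfg)
      matchings <- benchmark_matchings(pair$study1, pair$study2, methods)
      for (mname in names(methods)) {
        counts <- confusion_counts(matchings[[mname]], pair$m_star)
        prf <- precision_recall_f1(counts)
        rows[[length(rows) + 1]] <- data.frame(
          method = mname, overlap = cfg$overlap, sigma_rt = cfg$sigma_rt,
          sigma_fi = cfg$sigma_fi, rep = r, tp = counts$tp, fp = counts$fp,
          fn = counts$fn, precision = prf["precision"],
          recall = prf["recall"], f1 = prf["f1"],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Run all methods on one pair, sharing solver work between alignment
# configs that differ only in tau.
benchmark_matchings <- function(t1, t2, methods) {
  out <- vector("list", length(methods))
  names(out) <- names(methods)
  cfg_idx <- which(vapply(methods, inherits, logical(1), "alignment_config"))
  if (length(cfg_idx) > 0) {
    key <- vapply(methods[cfg_idx], function(cfg) {
      cfg$tau <- 0
      paste(deparse(unclass(cfg)), collapse = "")
    }, character(1))
    for (k in unique(key)) {
      members <- cfg_idx[key == k]
      base_cfg <- methods[[members[1]]]
      base_cfg$tau <- 0
      aln <- gw_align(t1, t2, base_cfg)
      for (m in members) {
        out[[m]] <- extract_matching(
          threshold_coupling(aln$coupling, methods[[m]]$tau)
        )
      }
    }
  }
  for (m in setdiff(seq_along(methods), cfg_idx)) {
    out[[m]] <- validate_matching(methods[[m]](t1, t2))
  }
  out
}

#' Summarize a benchmark report
#'
#' Mean precision, recall and F1 per (method, overlap, noise) condition.
#'
#' @param report output of [run_benchmark()].
#' @return a data.frame with one row per condition and method.
#' @export
summarize_benchmark <- function(report) {
  agg <- stats::aggregate(
    report[, c("precision", "recall", "f1")],
    by = report[, c("method", "overlap", "sigma_rt", "sigma_fi")],
    FUN = mean
  )
  agg[order(agg$method, agg$overlap, agg$sigma_rt), ]
}
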