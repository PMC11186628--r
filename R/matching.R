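#' Threshold a coupling
#'
#' Sets every entry smaller than `tau * max(pi)` to zero. With `tau = 0`
#' the coupling is returned unchanged; `tau = 1` keeps only entries equal
#' to the maximum.
#'
#' @param coupling a [coupling()] or matrix.
#' @param tau threshold fraction in \[0, 1\].
#' @return coupling of the same class with small entries zeroed.
#' @export
threshold_coupling <- function(coupling, tau) {
  stopifnot(tau >= 0, tau <= 1)
  P <- as_coupling_matrix(coupling)
  if (tau > 0 && length(P) > 0) {
    P[P < tau * max(P)] <- 0
  }
  if (inherits(coupling, "coupling")) {
    coupling$pi <- P
    coupling
  } else {
    P
  }
}

#' Extract a one-to-one matching from a coupling
#'
#' Keeps exactly those pairs (i, j) whose coupling entry is positive and is
#' the unique maximum of both its row and its column; all other entries are
#' discarded. Ties for a row or column maximum drop all tied candidates (no
#' arbitrary choice is made), preserving the at-most-one-per-row-and-column
#' invariant.
#'
#' @param coupling a [coupling()] or nonnegative matrix.
#' @return binary matching matrix (base matrix of 0/1) of the same
#'   dimensions.
#' @examples
#' extract_matching(rbind(c(0.5, 0.1), c(0.2, 0.4))) # identity
#' @export
extract_matching <- function(coupling) {
  P <- as_coupling_matrix(coupling)
  if (any(P < 0)) stop("extract_matching: coupling must be nonnegative")
  M <- matrix(0L, nrow(P), ncol(P))
  if (length(P) == 0 || max(P) == 0) return(M)
  row_max <- apply(P, 1, max)
  col_max <- apply(P, 2, max)
  row_ties <- rowSums(P == row_max) > 1
  col_ties <- colSums(sweep(P, 2, col_max, "==")) > 1
  hit <- P > 0 & P == row_max & sweep(P, 2, col_max, "==") &
    !row_ties & !matrix(col_ties, nrow(P), ncol(P), byrow = TRUE)
  M[hit] <- 1L
  M
}

#' Validate a partial matching matrix
#'
#' @param m binary matrix with at most one nonzero entry per row and per
#'   column.
#' @return `m` (as integer 0/1 matrix), invisibly erroring otherwise.
#' @export
validate_matching <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("matching matrix must be binary")
  if (any(rowSums(m) > 1) || any(colSums(m) > 1)) {
    stop("matching matrix must have at most one match per row and column")
  }
  storage.mode(m) <- "integer"
  invisible(m)
}

#' Align two feature tables
#'
#' The full pipeline: (optional) per-feature standardization, intra-study
#' distance matrices, m/z admissibility mask, unbalanced
#' Gromov-Wasserstein coupling, retention-time drift estimation with
#' two-stage outlier filtering, optional thresholding (`tau > 0`), and
#' one-to-one extraction. The plain and thresholded variants are available
#' as presets through [gm_config()] / [gmt_config()] or the `preset`
#' shortcut.
#'
#' @param t1,t2 two [feature_table()]s (study 1 and study 2).
#' @param config an [alignment_config()].
#' @param preset optional shortcut: `"gm"` (no thresholding) or `"gmt"`
#'   (`tau = 0.3`), overriding `config$tau`.
#' @return an object of class `gw_alignment`: list with `matching` (binary
#'   p1 x p2 matrix), `coupling` (filtered [coupling()]), `coupling_raw`
#'   (solver output before drift filtering), `drift` (`drift_model` or NULL
#'   when the coupling is empty), `report` (`ugw_report`), `config`, and
#'   the two tables' feature ids.
#' @examples
#' base <- generate_base_table(p = 30, n = 40, seed = 7)
#' pair <- simulate_study_pair(base, split_config(overlap = 1, sigma_m = 0,
#'   sigma_rt = 0, sigma_fi = 0, apply_drift = FALSE, seed = 7))
#' aln <- gw_align(pair$study1, pair$study2)
#' sum(aln$matching) # all 30 features recovered
#' @export
gw_align <- function(t1, t2, config = alignment_config(), preset = NULL) {
  validate_feature_table(t1)
  validate_feature_table(t2)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("gm", "gmt"))
    config$tau <- if (preset == "gmt") 0.3 else 0
  }
  s1 <- if (config$center_scale) center_scale(t1) else t1
  s2 <- if (config$center_scale) center_scale(t2) else t2
  D1 <- pairwise_distance(s1$intensities, config$metric)
  D2 <- pairwise_distance(s2$intensities, config$metric)
  mask <- build_mz_mask(t1$mz, t2$mz, config$m_gap, config$mz_mode)
  sol <- ugw_solve(D1, D2, mask, rho = config$rho, eps = config$eps,
                   max_outer = config$max_outer,
                   max_inner = config$max_inner, tol = config$tol)
  coupling_raw <- sol$coupling
  drift <- NULL
  cp <- coupling_raw
  if (sum(cp$pi > 0) > 0) {
    refined <- drift_filter_pipeline(cp, t1$rt, t2$rt, config)
    cp <- refined$coupling
    drift <- refined$drift
  }
  cp_thr <- threshold_coupling(cp, config$tau)
  structure(
    list(matching = extract_matching(cp_thr), coupling = cp,
         coupling_raw = coupling_raw, drift = drift, report = sol$report,
         config = config, feature_ids_x = t1$feature_ids,
         feature_ids_y = t2$feature_ids),
    class = "gw_alignment"
  )
}

#' @export
print.gw_alignment <- function(x, ...) {
  cat(sprintf(
    "<gw_alignment> %d x %d features, %d matched pairs (tau = %g)\n",
    nrow(x$matching), ncol(x$matching), sum(x$matching), x$config$tau
  ))
  if (!is.null(x$drift)) print(x$drift)
  invisible(x)
}

#' Write matched pairs to CSV
#'
#' One row per matched pair with both feature ids, m/z values, retention
#' times, and the (filtered) coupling weight at the matched cell.
#'
#' @param matching binary matching matrix.
#' @param coupling the [coupling()] the matching was extracted from.
#' @param t1,t2 the two feature tables.
#' @param path output path.
#' @return the matches as a data.frame, invisibly.
#' @export
write_matches <- function(matching, coupling, t1, t2, path) {
  matching <- validate_matching(matching)
  P <- as_coupling_matrix(coupling)
  if (!all(dim(matching) == c(n_features(t1), n_features(t2))) ||
      !all(dim(P) == dim(matching))) {
    stop("write_matches: dimension mismatch between matching, coupling and tables")
  }
  idx <- which(matching == 1L, arr.ind = TRUE)
  df <- data.frame(
    feature_id_1 = t1$feature_ids[idx[, 1]],
    feature_id_2 = t2$feature_ids[idx[, 2]],
    mz_1 = t1$mz[idx[, 1]], mz_2 = t2$mz[idx[, 2]],
    rt_1 = t1$rt[idx[, 1]], rt_2 = t2$rt[idx[, 2]],
    weight = P[idx], stringsAsFactors = FALSE
  )
  df <- df[order(df$feature_id_1), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a coupling as a labeled dense CSV
#'
#' @param coupling a [coupling()] or matrix.
#' @param t1,t2 feature tables supplying row and column labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coupling <- function(coupling, t1, t2, path) {
  P <- as_coupling_matrix(coupling)
  dimnames(P) <- list(t1$feature_ids, t2$feature_ids)
  utils::write.csv(P, path, row.names = TRUE)
  invisible(path)
}

#' Pool matched studies into one intensity matrix
#'
#' Builds the combined matrix used for downstream analyses across studies:
#' rows are the reference study's features, columns are the reference
#' samples followed by each other study's samples. For a reference feature
#' matched in another study, that study's columns carry the matched
#' feature's intensities; for an unmatched reference feature they are all
#' missing (NA, serialized as empty cells in CSV).
#'
#' @param reference the reference [feature_table()].
#' @param others list of other feature tables.
#' @param matchings list of binary matching matrices, one per other study,
#'   with rows indexing the reference features.
#' @return a `pooled_table`: list with `intensities` (reference features x
#'   pooled samples, NA where unmatched), `sample_ids`, `study` (per-column
#'   study label), `feature_ids`.
#' @export
pool_datasets <- function(reference, others, matchings) {
  validate_feature_table(reference)
  if (inherits(others, "feature_table")) others <- list(others)
  if (is.matrix(matchings)) matchings <- list(matchings)
  stopifnot(length(others) == length(matchings))
  p_ref <- n_features(reference)
  blocks <- list(reference$intensities)
  sample_ids <- reference$sample_ids
  study <- rep("reference", n_samples(reference))
  labels <- if (is.null(names(others))) {
    paste0("study", seq_along(others) + 1)
  } else {
    names(others)
  }
  for (k in seq_along(others)) {
    other <- others[[k]]
    validate_feature_table(other)
    m <- validate_matching(matchings[[k]])
    if (nrow(m) != p_ref || ncol(m) != n_features(other)) {
      stop("pool_datasets: matching ", k, " has inconsistent dimensions")
    }
    block <- matrix(NA_real_, p_ref, n_samples(other))
    idx <- which(m == 1L, arr.ind = TRUE)
    block[idx[, 1], ] <- other$intensities[idx[, 2], , drop = FALSE]
    blocks[[k + 1]] <- block
    sample_ids <- c(sample_ids, paste(labels[k], other$sample_ids, sep = "."))
    study <- c(study, rep(labels[k], n_samples(other)))
  }
  structure(
    list(intensities = do.call(cbind, blocks), sample_ids = sample_ids,
         study = study, feature_ids = reference$feature_ids),
    class = "pooled_table"
  )
}

#' Write a pooled table to CSV
#'
#' @param x a `pooled_table`.
#' @param path output path; missing values become empty cells.
#' @return `path`, invisibly.
#' @export
write_pooled_table <- function(x, path) {
  df <- as.data.frame(x$intensities)
  names(df) <- x$sample_ids
  df <- cbind(feature_id = x$feature_ids, df, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
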