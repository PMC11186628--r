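#' Construct a feature table
#'
#' The central container for one untargeted LC-MS study: one row per
#' metabolic feature carrying its mass-to-charge ratio (m/z, Da), retention
#' time (RT, minutes) and intensity profile across that study's samples.
#' Intensities must be complete; the package deliberately refuses tables
#' with missing values rather than imputing silently, since imputation is a
#' study-specific preprocessing decision.
#'
#' @param feature_ids character vector of feature identifiers (opaque
#'   strings, kept verbatim through the pipeline).
#' @param mz numeric vector of mass-to-charge ratios in Da; strictly
#'   positive.
#' @param rt numeric vector of retention times in minutes; nonnegative.
#' @param intensities numeric matrix, features x samples, no missing values.
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   column names of `intensities` or `S1..Sn`.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `feature_ids`, `mz`, `rt`, `intensities`, `sample_ids`.
#' @examples
#' tab <- feature_table(
#'   feature_ids = c("a", "b"), mz = c(100.1, 240.2), rt = c(1.5, 3.2),
#'   intensities = matrix(1:6, nrow = 2)
#' )
#' tab
#' @export
feature_table <- function(feature_ids, mz, rt, intensities,
                          sample_ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- colnames(intensities)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(intensities)))
  }
  obj <- structure(
    list(
      feature_ids = as.character(feature_ids),
      mz = as.numeric(mz),
      rt = as.numeric(rt),
      intensities = unname(intensities),
      sample_ids = as.character(sample_ids)
    ),
    class = "feature_table"
  )
  validate_feature_table(obj)
  obj
}

#' Validate feature-table invariants
#'
#' Checks the structural invariants: consistent lengths, strictly positive
#' m/z, nonnegative RT and complete intensities.
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  p <- length(x$feature_ids)
  if (length(x$mz) != p || length(x$rt) != p || nrow(x$intensities) != p) {
    stop("feature_table: feature_ids, mz, rt and intensity rows must have equal length")
  }
  if (ncol(x$intensities) != length(x$sample_ids)) {
    stop("feature_table: number of intensity columns must equal length(sample_ids)")
  }
  if (anyNA(x$mz) || any(x$mz <= 0)) stop("feature_table: mz must be strictly positive")
  if (anyNA(x$rt) || any(x$rt < 0)) stop("feature_table: rt must be nonnegative")
  if (anyNA(x$intensities) || !all(is.finite(x$intensities))) {
    stop("feature_table: intensities contain missing or non-finite values; ",
         "impute the table upstream before alignment")
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples\n  m/z range: [%.4f, %.4f] Da; RT range: [%.2f, %.2f] min\n",
    n_features(x), n_samples(x), min(x$mz), max(x$mz), min(x$rt), max(x$rt)
  ))
  invisible(x)
}

#' Number of features / samples in a feature table
#'
#' @param x a `feature_table`.
#' @return integer count.
#' @export
n_features <- function(x) length(x$feature_ids)

#' @rdname n_features
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Read a feature table from CSV
#'
#' Expects a header row with one column for the feature identifier, one for
#' m/z, one for RT; all remaining columns are treated as sample intensity
#' columns in file order.
#'
#' @param path path to a comma-separated UTF-8 file.
#' @param id_col,mz_col,rt_col column names for the identifier, m/z and RT.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, id_col = "feature_id", mz_col = "mz",
                               rt_col = "rt") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(id_col, mz_col, rt_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path))
    }
  }
  sample_cols <- setdiff(names(df), c(id_col, mz_col, rt_col))
  if (length(sample_cols) == 0) stop("no sample intensity columns found in ", path)
  intens <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(intens) <- "double"
  feature_table(
    feature_ids = df[[id_col]], mz = df[[mz_col]], rt = df[[rt_col]],
    intensities = intens, sample_ids = sample_cols
  )
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]; round trips preserve all fields up to
#' float formatting (15 significant digits).
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  validate_feature_table(x)
  intens <- x$intensities
  colnames(intens) <- x$sample_ids
  df <- data.frame(
    feature_id = x$feature_ids, mz = x$mz, rt = x$rt,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(intens, check.names = FALSE))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Center and scale feature intensities
#'
#' Standardizes every feature's intensity profile to mean zero and unit
#' standard deviation, using the population convention (divisor n). With
#' that convention a standardized profile u satisfies ||u||^2 = n, so the
#' normalized Euclidean distance between standardized profiles equals
#' sqrt(2 * d_cos) with d_cos the cosine distance of the raw profiles.
#' Standardization removes between-study differences in intensity scale
#' while preserving the correlation structure the alignment relies on.
#'
#' @param x a `feature_table`.
#' @return a `feature_table` with standardized intensities; m/z and RT are
#'   untouched.
#' @examples
#' tab <- feature_table("a", 100, 1, matrix(c(1, 2, 3), 1))
#' center_scale(tab)$intensities # (-1.2247, 0, 1.2247)
#' @export
center_scale <- function(x) {
  validate_feature_table(x)
  n <- n_samples(x)
  mu <- rowMeans(x$intensities)
  centered <- x$intensities - mu
  sds <- sqrt(rowMeans(centered^2))
  zero_var <- sds <= 0
  if (any(zero_var)) {
    stop("center_scale: zero-variance feature(s): ",
         paste(x$feature_ids[zero_var], collapse = ", "))
  }
  x$intensities <- centered / sds
  x
}
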