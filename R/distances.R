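#' Pairwise distances between feature intensity profiles
#'
#' Builds the intra-study distance matrix the transport solver works on.
#' Two metrics are supported:
#' \describe{
#'   \item{normalized_euclidean}{d(u, v) = ||u - v|| / sqrt(n), the
#'     Euclidean distance divided by the square root of the sample count.
#'     On profiles standardized by [center_scale()] this equals
#'     sqrt(2 * d_cos) entrywise.}
#'   \item{cosine}{d(u, v) = 1 - corr(u, v), one minus the Pearson
#'     correlation; entries lie in \[0, 2\].}
#' }
#'
#' @param intensities numeric matrix, features x samples, at least two
#'   samples.
#' @param metric `"normalized_euclidean"` or `"cosine"`.
#' @return a `distance_matrix`: list with the symmetric nonnegative `values`
#'   matrix (zero diagonal) and the `metric` used.
#' @examples
#' x <- rbind(c(0, 0), c(3, 4))
#' pairwise_distance(x)$values[1, 2] # 5 / sqrt(2)
#' @export
pairwise_distance <- function(intensities,
                              metric = c("normalized_euclidean", "cosine")) {
  metric <- match.arg(metric)
  intensities <- as.matrix(intensities)
  n <- ncol(intensities)
  if (n < 2) stop("pairwise_distance: need at least two samples")
  if (metric == "normalized_euclidean") {
    d <- as.matrix(stats::dist(intensities)) / sqrt(n)
  } else {
    sds <- apply(intensities, 1, stats::sd)
    if (any(sds <= 0)) {
      stop("pairwise_distance: constant intensity row(s); ",
           "the cosine distance is undefined for zero-variance features")
    }
    d <- 1 - stats::cor(t(intensities))
  }
  d[d < 0] <- 0 # clamp negative round-off
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(list(values = unname(d), metric = metric),
            class = "distance_matrix")
}

# Accept either a distance_matrix or a plain matrix; return the validated
# numeric matrix.
as_distance_values <- function(d, arg = "D") {
  if (inherits(d, "distance_matrix")) d <- d$values
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(arg, " must be square")
  if (any(!is.finite(d)) || any(d < 0)) {
    stop(arg, " must be finite and nonnegative")
  }
  if (max(abs(d - t(d))) > 1e-8) stop(arg, " must be symmetric")
  unname(d)
}
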