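#' m/z compatibility mask
#'
#' Marks which cross-study feature pairs are allowed to match: pair (i, j)
#' is admissible when the m/z values agree within `m_gap`, inclusively at
#' the boundary. In `"da"` mode the tolerance is absolute (Daltons); in
#' `"ppm"` mode it is `m_gap` parts-per-million of the study-1 m/z.
#'
#' @param mz_x,mz_y m/z vectors of the two studies, Da.
#' @param m_gap positive tolerance.
#' @param mz_mode `"da"` (default) or `"ppm"`.
#' @return logical matrix, `length(mz_x)` x `length(mz_y)`.
#' @export
build_mz_mask <- function(mz_x, mz_y, m_gap = 0.01,
                          mz_mode = c("da", "ppm")) {
  mz_mode <- match.arg(mz_mode)
  stopifnot(m_gap > 0)
  delta <- abs(outer(mz_x, mz_y, "-"))
  # small relative slack keeps the boundary inclusive under float round-off
  slack <- 1 + 1e-12
  if (mz_mode == "da") {
    delta <= m_gap * slack
  } else {
    delta <= m_gap * 1e-6 * mz_x * slack
  }
}

#' Construct a coupling object
#'
#' A coupling is a nonnegative soft-matching matrix between the features of
#' two studies, together with the reference marginals it is relaxed
#' towards. Reference marginals default to the uniform probability vectors
#' 1/p1 and 1/p2.
#'
#' @param pi nonnegative p1 x p2 matrix.
#' @param a,b reference marginals (positive, typically uniform).
#' @return an object of class `coupling`.
#' @export
coupling <- function(pi, a = NULL, b = NULL) {
  pi <- as.matrix(pi)
  if (any(!is.finite(pi)) || any(pi < 0)) {
    stop("coupling: entries must be finite and nonnegative")
  }
  if (is.null(a)) a <- rep(1 / nrow(pi), nrow(pi))
  if (is.null(b)) b <- rep(1 / ncol(pi), ncol(pi))
  stopifnot(length(a) == nrow(pi), length(b) == ncol(pi), all(a > 0),
            all(b > 0))
  structure(list(pi = unname(pi), a = as.numeric(a), b = as.numeric(b)),
            class = "coupling")
}

#' @export
print.coupling <- function(x, ...) {
  cat(sprintf(
    "<coupling> %d x %d, total mass %.4f, %d nonzero entries\n",
    nrow(x$pi), ncol(x$pi), sum(x$pi), sum(x$pi > 0)
  ))
  invisible(x)
}

as_coupling_matrix <- function(x) {
  if (inherits(x, "coupling")) x$pi else as.matrix(x)
}

# KL(mu | nu) = sum mu log(mu/nu) - m(mu) + m(nu), 0 log 0 := 0.
kl_div <- function(mu, nu) {
  pos <- mu > 0
  sum(mu[pos] * log(mu[pos] / nu[pos])) - sum(mu) + sum(nu)
}

#' Unbalanced Gromov-Wasserstein objective
#'
#' Evaluates the regularized objective
#' `E(pi) + rho KL(pi_1 (x) pi_1 | a (x) a) + rho KL(pi_2 (x) pi_2 | b (x) b)
#'  + eps KL(pi (x) pi | (a (x) b)^(x)2)`,
#' where `E` sums the pairwise distortion `|Dx[i,k] - Dy[j,l]|^q
#' pi[i,j] pi[k,l]` with `q = 2` for the squared distortion the solver
#' minimizes (default) or `q = 1` for the absolute distortion
#' (`distortion = "abs"`; dense evaluation, small problems only).
#'
#' @param pi a [coupling()] or nonnegative matrix.
#' @param Dx,Dy intra-study distance matrices ([pairwise_distance()] output
#'   or plain matrices).
#' @param rho,eps positive regularization weights.
#' @param distortion `"squared"` or `"abs"`.
#' @return the objective value (scalar).
#' @examples
#' D <- matrix(0, 2, 2)
#' ugw_objective(matrix(0, 2, 2), D, D, rho = 0.05, eps = 0.005) # 2*rho+eps
#' @export
ugw_objective <- function(pi, Dx, Dy, rho = 0.05, eps = 0.005,
                          distortion = c("squared", "abs")) {
  distortion <- match.arg(distortion)
  cp <- if (inherits(pi, "coupling")) pi else coupling(pi)
  Dx <- as_distance_values(Dx, "Dx")
  Dy <- as_distance_values(Dy, "Dy")
  P <- cp$pi
  stopifnot(nrow(P) == nrow(Dx), ncol(P) == nrow(Dy))
  mu <- rowSums(P)
  nu <- colSums(P)
  if (distortion == "squared") {
    E <- drop(mu %*% (Dx^2) %*% mu) + drop(nu %*% (Dy^2) %*% nu) -
      2 * sum(P * (Dx %*% P %*% Dy))
  } else {
    # dense O(p1^2 p2^2) tensor evaluation
    E <- 0
    sup <- which(P > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(sup))) {
      i <- sup[r, 1]; j <- sup[r, 2]
      E <- E + P[i, j] * sum(abs(outer(Dx[i, ], Dy[j, ], "-")) * P)
    }
  }
  m <- sum(P)
  kl_tensor <- function(kl, m) 2 * m * kl + (m - 1)^2
  E +
    rho * kl_tensor(kl_div(mu, cp$a), m) +
    rho * kl_tensor(kl_div(nu, cp$b), m) +
    eps * kl_tensor(kl_div(as.vector(P), as.vector(outer(cp$a, cp$b))), m)
}

#' Solve the masked unbalanced Gromov-Wasserstein problem
#'
#' Finds a nonnegative coupling between the features of two studies that
#' preserves intra-study distance structure, with KL relaxation of the
#' marginals (weight `rho`) so that only a subset of features need be
#' matched, entropic smoothing (weight `eps`), and hard zeros at
#' m/z-incompatible pairs. Optimization alternates unbalanced Sinkhorn
#' scaling steps on a bi-convex relaxation of the objective; the mask is
#' enforced inside every Sinkhorn iteration and the returned coupling is
#' hard-zeroed at masked cells. Rows and columns with no admissible partner
#' are removed before optimization (their coupling entries are structural
#' zeros) and reinserted afterwards, which substantially shrinks the
#' problem under a sparse m/z mask.
#'
#' The solver is deterministic; `seed` is accepted for interface symmetry
#' with the stochastic parts of the pipeline and is not used.
#'
#' @param Dx,Dy intra-study distance matrices.
#' @param mask logical p1 x p2 admissibility matrix (default: all pairs
#'   admissible); see [build_mz_mask()].
#' @param rho,eps positive regularization weights.
#' @param max_outer,max_inner iteration caps for the outer alternating loop
#'   and the inner Sinkhorn loop.
#' @param tol convergence tolerance on the max-abs change of the coupling
#'   between outer iterations, relative to `max(1, max(pi))`.
#' @param distortion `"squared"` (default) uses the squared distance
#'   difference, which factorizes and scales to thousands of features;
#'   `"abs"` uses the absolute difference with a dense tensorized cost and
#'   is intended for small cross-checks only.
#' @param seed unused; see Details.
#' @return list with elements `coupling` (a [coupling()]) and `report`
#'   (class `ugw_report`): `objective_trace` holds the bi-convex relaxed
#'   objective the alternation minimizes, evaluated once per outer
#'   iteration (it coincides with the coupling's own objective once the two
#'   relaxation factors meet); `final_objective` is the regularized
#'   objective of the returned coupling itself; `factor_gap` the max-abs
#'   disagreement between the two relaxation factors at exit; plus
#'   `n_outer_iterations`, `converged`, `final_mass`.
#' @export
ugw_solve <- function(Dx, Dy, mask = NULL, rho = 0.05, eps = 0.005,
                      max_outer = 200, max_inner = 500, tol = 1e-6,
                      distortion = c("squared", "abs"), seed = NULL) {
  distortion <- match.arg(distortion)
  Dx <- as_distance_values(Dx, "Dx")
  Dy <- as_distance_values(Dy, "Dy")
  stopifnot(rho > 0, eps > 0)
  if (distortion == "abs" && as.double(nrow(Dx)) * ncol(Dy) > 250000) {
    stop("ugw_solve: the dense 'abs' distortion is limited to small instances")
  }
  p1 <- nrow(Dx)
  p2 <- nrow(Dy)
  if (is.null(mask)) mask <- matrix(TRUE, p1, p2)
  mask <- as.matrix(mask)
  stopifnot(nrow(mask) == p1, ncol(mask) == p2)
  a <- rep(1 / p1, p1)
  b <- rep(1 / p2, p2)

  keep1 <- which(rowSums(mask) > 0)
  keep2 <- which(colSums(mask) > 0)
  if (length(keep1) == 0 || length(keep2) == 0) {
    cp <- coupling(matrix(0, p1, p2), a, b)
    report <- structure(
      list(objective_trace = 2 * rho + eps, n_outer_iterations = 0L,
           converged = TRUE, final_mass = 0,
           final_objective = 2 * rho + eps, factor_gap = 0),
      class = "ugw_report"
    )
    return(list(coupling = cp, report = report))
  }

  res <- if (distortion == "squared") {
    .ugw_core(
      Dx[keep1, keep1, drop = FALSE], Dy[keep2, keep2, drop = FALSE],
      mask[keep1, keep2, drop = FALSE] * 1L, a[keep1], b[keep2],
      rho, eps, as.integer(max_outer), as.integer(max_inner), tol
    )
  } else {
    ugw_iterate_abs(
      Dx[keep1, keep1, drop = FALSE], Dy[keep2, keep2, drop = FALSE],
      mask[keep1, keep2, drop = FALSE], a[keep1], b[keep2],
      rho, eps, max_outer, max_inner, tol
    )
  }

  pi_full <- matrix(0, p1, p2)
  pi_full[keep1, keep2] <- res$pi
  pi_full[!mask] <- 0
  cp <- coupling(pi_full, a, b)
  report <- structure(
    list(objective_trace = as.numeric(res$objective_trace),
         n_outer_iterations = res$n_outer_iterations,
         converged = res$converged, final_mass = res$final_mass,
         final_objective = res$final_objective,
         factor_gap = res$factor_gap),
    class = "ugw_report"
  )
  list(coupling = cp, report = report)
}

# Reference alternating-minimization loop for the absolute distortion
# |Dx[i,k] - Dy[j,l]|, with the tensorized cost evaluated densely. Mirrors
# the compiled squared-distortion solver (two-factor relaxation, exact
# Sinkhorn half updates); small instances only.
ugw_iterate_abs <- function(Dx, Dy, mask, a, b, rho, eps, max_outer,
                            max_inner, tol) {
  p1 <- nrow(Dx)
  p2 <- nrow(Dy)
  ab <- as.vector(outer(a, b))
  lse <- function(z) {
    mx <- max(z)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(z - mx)))
  }
  bi_obj <- function(P, G) {
    E <- 0
    sup <- which(P > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(sup))) {
      i <- sup[r, 1]; j <- sup[r, 2]
      E <- E + P[i, j] * sum(abs(outer(Dx[i, ], Dy[j, ], "-")) * G)
    }
    mp <- sum(P); mg <- sum(G)
    cross <- (mp - 1) * (mg - 1)
    E +
      rho * (mg * kl_div(rowSums(P), a) + mp * kl_div(rowSums(G), a) + cross) +
      rho * (mg * kl_div(colSums(P), b) + mp * kl_div(colSums(G), b) + cross) +
      eps * (mg * kl_div(as.vector(P), ab) + mp * kl_div(as.vector(G), ab) +
               cross)
  }
  half_update <- function(ref) {
    m <- sum(ref)
    Tcost <- matrix(0, p1, p2)
    for (i in seq_len(p1)) {
      Tcost[i, ] <- vapply(seq_len(p2), function(j) {
        sum(abs(outer(Dx[i, ], Dy[j, ], "-")) * ref)
      }, numeric(1))
    }
    kconst <- rho * kl_div(rowSums(ref), a) + rho * kl_div(colSums(ref), b) +
      eps * kl_div(as.vector(ref), ab) + (2 * rho + eps) * (m - 1)
    C <- Tcost + kconst
    C[!mask] <- Inf
    epsp <- eps * m
    kap <- (rho * m) / (rho * m + epsp)
    u <- numeric(p1)
    v <- numeric(p2)
    for (inner in seq_len(max_inner)) {
      u_old <- u
      u <- -kap * epsp * vapply(seq_len(p1), function(i) {
        lse(log(b) + (v - C[i, ]) / epsp)
      }, numeric(1))
      u[!is.finite(u)] <- 0
      v <- -kap * epsp * vapply(seq_len(p2), function(j) {
        lse(log(a) + (u - C[, j]) / epsp)
      }, numeric(1))
      v[!is.finite(v)] <- 0
      if (max(abs(u - u_old)) < 1e-10 + 1e-7 * max(1, max(abs(u)))) break
    }
    out <- outer(a, b) * exp((outer(u, v, "+") - C) / epsp)
    out[!mask] <- 0
    out
  }

  pi <- outer(a, b)
  pi[!mask] <- 0
  gam <- pi
  trace <- bi_obj(pi, gam)
  converged <- FALSE
  outer_it <- 0
  for (outer_it in seq_len(max_outer)) {
    pi_prev <- pi
    gam_prev <- gam
    if (sum(pi) <= 0 || sum(gam) <= 0) { converged <- TRUE; break }
    pi <- half_update(gam)
    gam <- half_update(pi)
    # equal-mass projection along the distortion-invariant direction,
    # with a descent safeguard (see the compiled solver)
    mp <- sum(pi)
    mg <- sum(gam)
    if (mp > 0 && mg > 0 && abs(log(mp / mg)) > 1e-12) {
      before <- bi_obj(pi, gam)
      s <- sqrt(mg / mp)
      if (bi_obj(s * pi, gam / s) <= before + 1e-12 * (1 + abs(before))) {
        pi <- s * pi
        gam <- gam / s
      }
    }
    trace <- c(trace, bi_obj(pi, gam))
    delta <- max(abs(pi - pi_prev), abs(gam - gam_prev))
    if (delta < tol * max(1, pi, gam)) {
      converged <- TRUE
      break
    }
  }
  out <- (pi + gam) / 2
  out[!mask] <- 0
  list(pi = out, objective_trace = trace,
       n_outer_iterations = min(outer_it, max_outer), converged = converged,
       final_mass = sum(out), final_objective = bi_obj(out, out),
       factor_gap = max(abs(pi - gam)))
}

#' @export
print.ugw_report <- function(x, ...) {
  cat(sprintf(
    "<ugw_report> %d outer iterations, converged: %s, final mass %.4f\n  objective: %.6g -> %.6g\n",
    x$n_outer_iterations, x$converged, x$final_mass,
    x$objective_trace[1], x$objective_trace[length(x$objective_trace)]
  ))
  invisible(x)
}
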