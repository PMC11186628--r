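test_that("m/z mask applies the tolerance inclusively", {
  mask <- build_mz_mask(c(100, 100.02), c(100.005, 100.02), m_gap = 0.01)
  expect_equal(mask, rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
  # boundary is inclusive
  expect_true(build_mz_mask(100, 100.01, m_gap = 0.01)[1, 1])
  # identical m/z vectors keep at least the diagonal under a tiny gap
  mz <- c(100, 200, 300)
  expect_true(all(diag(build_mz_mask(mz, mz, m_gap = 1e-9))))
  # ppm mode scales with the mass
  expect_true(build_mz_mask(500, 500.002, m_gap = 5, mz_mode = "ppm")[1, 1])
  expect_false(build_mz_mask(100, 100.002, m_gap = 5, mz_mode = "ppm")[1, 1])
})

test_that("objective of the zero coupling is 2*rho + eps", {
  D <- matrix(0, 3, 3)
  for (rho in c(0.05, 0.5)) {
    for (eps in c(0.005, 0.1)) {
      expect_equal(ugw_objective(matrix(0, 3, 4), D, matrix(0, 4, 4),
                                 rho = rho, eps = eps),
                   2 * rho + eps, tolerance = 1e-12)
    }
  }
})

test_that("1x1 objective matches its closed form", {
  g <- function(c2) c2 * log(c2) - c2 + 1
  for (c in c(0.3, 1, 1.7)) {
    expect_equal(
      ugw_objective(matrix(c, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                    rho = 0.05, eps = 0.005),
      0.05 * 2 * g(c^2) + 0.005 * g(c^2), tolerance = 1e-10
    )
  }
})

test_that("distortion term vanishes for a perfect scaled permutation", {
  tab <- make_table(p = 8, n = 20, seed = 5)
  D <- pairwise_distance(tab$intensities)$values
  perm <- withr_seed(6, sample(8))
  P <- matrix(0, 8, 8)
  P[cbind(seq_len(8), match(seq_len(8), perm))] <- 1 / 8
  kl_only <- ugw_objective(P, D, D[perm, perm], rho = 0.05, eps = 0.005)
  # subtracting the three KL terms leaves E = 0: compare against the same
  # coupling on isometric spaces where E is analytically zero
  zeroD <- matrix(0, 8, 8)
  expect_equal(kl_only,
               ugw_objective(P, zeroD, zeroD, rho = 0.05, eps = 0.005),
               tolerance = 1e-10)
  expect_error(ugw_objective(matrix(-1, 1, 1), matrix(0, 1, 1),
                             matrix(0, 1, 1)), "nonnegative")
})

test_that("solver recovers identity on duplicated studies", {
  tab <- make_table(p = 10, n = 40, seed = 42)
  D <- pairwise_distance(center_scale(tab)$intensities)$values
  expect_true(distances_distinct(D))
  res <- ugw_solve(D, D)
  expect_true(res$report$converged)
  M <- extract_matching(res$coupling)
  expect_equal(M, diag(1L, 10), ignore_attr = TRUE)
})

test_that("solver recovers a planted permutation", {
  tab <- make_table(p = 10, n = 40, seed = 42)
  D <- pairwise_distance(center_scale(tab)$intensities)$values
  perm <- withr_seed(7, sample(10))
  res <- ugw_solve(D, D[perm, perm])
  M <- extract_matching(res$coupling)
  hit <- which(M == 1L, arr.ind = TRUE)
  expect_equal(nrow(hit), 10)
  expect_equal(hit[order(hit[, 1]), 2], match(seq_len(10), perm))
})

test_that("fully masked problem returns the zero coupling", {
  D <- pairwise_distance(make_table(p = 5, n = 12, seed = 1)$intensities)$values
  res <- ugw_solve(D, D, mask = matrix(FALSE, 5, 5))
  expect_equal(res$coupling$pi, matrix(0, 5, 5))
  expect_true(res$report$converged)
  expect_equal(res$report$final_mass, 0)
})

test_that("masked cells are exactly zero in the returned coupling", {
  tab <- make_table(p = 8, n = 25, seed = 2)
  D <- pairwise_distance(tab$intensities)$values
  mask <- matrix(TRUE, 8, 8)
  mask[1, ] <- FALSE
  mask[, 3] <- FALSE
  mask[5, 6] <- FALSE
  res <- ugw_solve(D, D, mask = mask)
  expect_true(all(res$coupling$pi[!mask] == 0))
  expect_gt(res$report$final_mass, 0)
})

test_that("objective trace is non-increasing and matches ugw_objective", {
  set.seed(33)
  for (r in 1:10) {
    p1 <- sample(5:12, 1)
    p2 <- sample(5:12, 1)
    D1 <- pairwise_distance(matrix(rnorm(p1 * 20), p1, 20))$values
    D2 <- pairwise_distance(matrix(rnorm(p2 * 20), p2, 20))$values
    res <- ugw_solve(D1, D2)
    tr <- res$report$objective_trace
    expect_true(all(is.finite(tr)))
    tol <- 1e-6 * (1 + abs(tr[-length(tr)]))
    expect_true(all(diff(tr) <= tol))
    expect_equal(res$report$final_objective,
                 ugw_objective(res$coupling, D1, D2, rho = 0.05, eps = 0.005),
                 tolerance = 1e-8)
  }
})

test_that("scaling both distance matrices preserves the argmin support", {
  tab <- make_table(p = 9, n = 30, seed = 8)
  D <- pairwise_distance(center_scale(tab)$intensities)$values
  M0 <- extract_matching(ugw_solve(D, D)$coupling)
  for (c in c(0.5, 2)) {
    Mc <- extract_matching(ugw_solve(c * D, c * D)$coupling)
    expect_equal(Mc, M0)
  }
})

test_that("coupling mass is non-decreasing in rho", {
  tab <- make_table(p = 9, n = 30, seed = 12)
  D <- pairwise_distance(center_scale(tab)$intensities)$values
  masses <- vapply(c(0.005, 0.05, 0.5), function(rho) {
    ugw_solve(D, D, rho = rho)$report$final_mass
  }, numeric(1))
  expect_true(all(diff(masses) >= -1e-8))
})

test_that("dense absolute-distortion mode agrees with the fast solver", {
  tab <- make_table(p = 10, n = 30, seed = 9)
  D <- pairwise_distance(center_scale(tab)$intensities)$values
  perm <- withr_seed(10, sample(10))
  fast <- ugw_solve(D, D[perm, perm])
  slow <- ugw_solve(D, D[perm, perm], distortion = "abs")
  expect_true(slow$report$converged)
  tr <- slow$report$objective_trace
  expect_true(all(diff(tr) <= 1e-6 * (1 + abs(tr[-length(tr)]))))
  expect_equal(extract_matching(slow$coupling),
               extract_matching(fast$coupling))
})
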