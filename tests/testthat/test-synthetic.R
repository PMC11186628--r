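test_that("split arithmetic matches the published design", {
  a <- split_arithmetic(p = 4712, n = 499, overlap = 0.5)
  expect_equal(a$n1, 249)
  expect_equal(a$n2, 250)
  expect_equal(a$s, 2356)
  expect_equal(a$p1, 3534)
  expect_equal(a$p2, 3534)
  # parity rule: odd remainder decrements the shared count
  b <- split_arithmetic(p = 11, n = 10, overlap = 0.5)
  expect_equal((11 - b$s) %% 2, 0)
  expect_equal(b$p1, b$p2)
})

test_that("split produces disjoint samples and a valid ground truth", {
  base <- make_table(p = 40, n = 21, seed = 6)
  pair <- split_dataset(base, split_config(overlap = 0.5, seed = 9))
  s1 <- pair$study1
  s2 <- pair$study2
  expect_length(intersect(s1$sample_ids, s2$sample_ids), 0)
  expect_equal(n_samples(s1), 10)
  expect_equal(n_samples(s2), 11)
  expect_equal(n_features(s1), n_features(s2))
  validate_matching(pair$m_star)
  expect_equal(sum(pair$m_star), 20)
  # matched positions point at the same base feature
  hit <- which(pair$m_star == 1L, arr.ind = TRUE)
  expect_equal(s1$feature_ids[hit[, 1]], s2$feature_ids[hit[, 2]])

  # full overlap: every feature shared, m_star a permutation matching
  full <- split_dataset(base, split_config(overlap = 1, seed = 9))
  expect_equal(sum(full$m_star), 40)
  expect_true(all(rowSums(full$m_star) == 1) &&
                all(colSums(full$m_star) == 1))
})

test_that("noise model respects its stated distributions", {
  base <- make_table(p = 30, n = 16, seed = 7)
  cfg0 <- split_config(overlap = 1, sigma_m = 0, sigma_rt = 0, sigma_fi = 0,
                       apply_drift = FALSE, seed = 3)
  pair0 <- split_dataset(base, cfg0)
  clean <- apply_noise(pair0, cfg0)
  expect_equal(clean$study2$mz, pair0$study2$mz)
  expect_equal(clean$study2$rt, pair0$study2$rt)
  expect_equal(clean$study1$intensities, pair0$study1$intensities)

  cfg <- split_config(overlap = 1, sigma_m = 0.01, sigma_rt = 0.5,
                      sigma_fi = 0.5, apply_drift = TRUE, seed = 3)
  noisy <- apply_noise(pair0, cfg)
  expect_true(all(abs(noisy$study2$mz - pair0$study2$mz) <= 0.01))
  drifted <- rt_drift_function(pair0$study2$rt)
  expect_true(all(abs(noisy$study2$rt - drifted) <= 0.5 + 1e-12))
  expect_false(identical(noisy$study1$intensities,
                         pair0$study1$intensities))
  expect_equal(noisy$m_star, pair0$m_star)
})

test_that("the systematic drift evaluates to its closed form", {
  expect_equal(rt_drift_function(1.0), 1.1 + 1.3 * sin(1.2),
               tolerance = 1e-12)
  expect_equal(round(rt_drift_function(1.0), 4), 2.3117)
  expect_equal(rt_drift_function(0), 0)
})

test_that("generation is deterministic in the seed", {
  t1 <- generate_base_table(p = 50, n = 40, seed = 123)
  t2 <- generate_base_table(p = 50, n = 40, seed = 123)
  expect_identical(t1, t2)
  expect_false(identical(t1$intensities,
                         generate_base_table(p = 50, n = 40, seed = 124)$intensities))
  validate_feature_table(t1)
  pair_a <- simulate_study_pair(t1, split_config(seed = 5))
  pair_b <- simulate_study_pair(t1, split_config(seed = 5))
  expect_identical(pair_a, pair_b)
})

test_that("fewer blocks mean stronger average correlation", {
  t_one <- generate_base_table(p = 60, n = 120, n_blocks = 1, seed = 9)
  t_many <- generate_base_table(p = 60, n = 120, n_blocks = 25, seed = 9)
  mean_abs_cor <- function(tab) {
    cc <- abs(stats::cor(t(tab$intensities)))
    mean(cc[upper.tri(cc)])
  }
  expect_gt(mean_abs_cor(t_one), mean_abs_cor(t_many))
})

test_that("benchmark achieves exact recovery in the noiseless limit", {
  base <- generate_base_table(p = 40, n = 50, seed = 31)
  grid <- list(split_config(overlap = 1, sigma_m = 0, sigma_rt = 0,
                            sigma_fi = 0, apply_drift = FALSE))
  rep1 <- run_benchmark(base, grid, n_reps = 2, seed = 8)
  expect_equal(nrow(rep1), 4) # |grid| * reps * |methods|
  expect_true(all(rep1$precision == 1))
  expect_true(all(rep1$recall[rep1$method == "gm"] == 1))
  # thresholding may drop weakly coupled but correct pairs by design
  expect_true(all(rep1$recall[rep1$method == "gmt"] >= 0.85))
  rep2 <- run_benchmark(base, grid, n_reps = 2, seed = 8)
  expect_identical(rep1, rep2)
  s <- summarize_benchmark(rep1)
  expect_equal(nrow(s), 2)
  expect_equal(s$recall[s$method == "gm"], 1)
})

test_that("function-valued methods are scored through the same contract", {
  base <- generate_base_table(p = 30, n = 40, seed = 32)
  grid <- list(split_config(overlap = 1, sigma_m = 0, sigma_rt = 0,
                            sigma_fi = 0, apply_drift = FALSE))
  naive <- function(t1, t2) {
    # m/z nearest-neighbour matcher as an external comparator
    M <- matrix(0L, n_features(t1), n_features(t2))
    j <- vapply(t1$mz, function(m) which.min(abs(t2$mz - m)), integer(1))
    ok <- abs(t1$mz - t2$mz[j]) <= 0.01 & !duplicated(j)
    M[cbind(which(ok), j[ok])] <- 1L
    M
  }
  rep1 <- run_benchmark(base, grid, n_reps = 1,
                        methods = list(nn = naive), seed = 2)
  expect_equal(nrow(rep1), 1)
  expect_gt(rep1$recall, 0.9) # distinct m/z: nearest neighbour is exact
})
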