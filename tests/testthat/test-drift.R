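test_that("noiseless identity drift is recovered", {
  rtx <- withr_seed(1, sort(runif(100, 0.5, 12)))
  cp <- coupling(diag(100) / 100)
  d <- fit_drift(cp, rtx, rtx)
  xs <- seq(min(rtx), max(rtx), length.out = 300)
  expect_lt(max(abs(predict(d, xs) - xs)), 1e-3)
})

test_that("the systematic nonlinear drift is recovered within 0.05 min", {
  rtx <- withr_seed(2, sort(runif(200, 0.5, 12)))
  rty <- rt_drift_function(rtx)
  d <- fit_drift(coupling(diag(200) / 200), rtx, rty)
  xs <- seq(min(rtx) + 0.3, max(rtx) - 0.3, length.out = 400)
  expect_lt(max(abs(predict(d, xs) - rt_drift_function(xs))), 0.05)
  # L1 and L2 loss agree on noiseless data
  d2 <- fit_drift(coupling(diag(200) / 200), rtx, rty, loss = "l2")
  expect_lt(max(abs(predict(d2, xs) - predict(d, xs))), 0.02)
})

test_that("zero-weight pairs do not influence the fit", {
  rtx <- withr_seed(3, sort(runif(80, 1, 10)))
  rty <- rt_drift_function(rtx)
  P <- diag(80) / 80
  P[80, 80] <- 0 # column 80 has no support: its rt_y is never seen
  d0 <- fit_drift(coupling(P), rtx, rty, seed = 5)
  rty2 <- rty
  rty2[80] <- rty2[80] + 1e6 # arbitrary perturbation at zero weight
  d1 <- fit_drift(coupling(P), rtx, rty2, seed = 5)
  expect_equal(d0$coefficients, d1$coefficients, tolerance = 1e-12)
  expect_error(fit_drift(coupling(matrix(1e-3, 2, 2)), c(1, 2), c(1, 2)),
               "too few")
})

test_that("residual statistics follow the PI/MAD definitions", {
  rtx <- c(1, 2, 3, 4)
  rty <- c(1, 2, 3, 14) # residuals 0,0,0,10 under an identity drift
  d <- structure(
    list(order = 1L, knots = numeric(0), boundary = c(0, 20),
         coefficients = c(0, 20), cv_table = NULL, cv_score = 0),
    class = "drift_model"
  ) # degree-1 spline through (0,0)-(20,20): the identity
  expect_equal(predict(d, c(1, 4)), c(1, 4), tolerance = 1e-9)
  st <- compute_residual_stats(d, coupling(diag(4) / 4), rtx, rty)
  expect_equal(sort(st$residuals), c(0, 0, 0, 10), tolerance = 1e-9)
  expect_equal(st$mu_r, 0)
  expect_equal(st$PI, 1.96 * sqrt(75 / 4), tolerance = 1e-9) # 8.4870
  expect_equal(st$MAD, 0)

  # constant residuals: MAD = 0, mu_r = c
  rty_c <- rtx + 2
  st2 <- compute_residual_stats(d, coupling(diag(4) / 4), rtx, rty_c)
  expect_equal(st2$mu_r, 2, tolerance = 1e-9)
  expect_equal(st2$MAD, 0, tolerance = 1e-9)
  expect_equal(st2$PI, 0, tolerance = 1e-9)
})

test_that("residual filtering keeps pairs within mu_r + r_thresh", {
  rtx <- c(1, 2, 3, 4)
  rty <- c(1, 2, 3, 14)
  d <- structure(
    list(order = 1L, knots = numeric(0), boundary = c(0, 20),
         coefficients = c(0, 20), cv_table = NULL, cv_score = 0),
    class = "drift_model"
  )
  cp <- coupling(diag(4) / 4)
  st <- compute_residual_stats(d, cp, rtx, rty)
  out <- filter_coupling(cp, st, st$PI)
  expect_equal(which(diag(out$pi) == 0), 4L) # only the residual-10 pair
  # all residuals zero with r_thresh = 0 keeps everything (<= convention)
  st0 <- compute_residual_stats(d, cp, rtx, rtx)
  expect_equal(filter_coupling(cp, st0, 0)$pi, cp$pi)
  # infinite threshold never filters
  expect_equal(filter_coupling(cp, st, Inf)$pi, cp$pi)
})

test_that("PI/MAD pipeline removes planted outliers, keeps clean pairs", {
  # Clean pairs carry bounded two-sided RT jitter whose magnitude
  # distribution is U-shaped, so the robust cut mu_r + 2 MAD sits about 25%
  # beyond the largest clean residual; planted outliers exceed the cut
  # roughly tenfold.
  n <- 1000
  rtx <- withr_seed(4, sort(runif(n, 0.5, 12)))
  mag <- withr_seed(5, {
    seg <- sample(1:3, n, TRUE, prob = c(0.4, 0.2, 0.4))
    u <- runif(n)
    sgn <- sample(c(-1, 1), n, TRUE)
    sgn * 0.5 * ifelse(seg == 1, 0.2 * u,
                       ifelse(seg == 2, 0.2 + 0.6 * u, 0.8 + 0.2 * u))
  })
  rty <- rt_drift_function(rtx) + mag
  planted <- withr_seed(6, sample(n, 50))
  rty[planted] <- rty[planted] + 6 # gross RT-incompatible residuals
  cp <- coupling(diag(n) / n)
  res <- drift_filter_pipeline(cp, rtx, rty)
  kept <- which(diag(res$coupling$pi) > 0)
  expect_length(intersect(kept, planted), 0)
  clean <- setdiff(seq_len(n), planted)
  expect_gte(length(intersect(kept, clean)) / length(clean), 0.95)
  # support shrinks monotonically and survivors keep their values
  expect_true(all(res$coupling$pi[res$coupling$pi > 0] ==
                    cp$pi[res$coupling$pi > 0]))
})

test_that("noiseless linear drift pipeline removes nothing", {
  n <- 120
  rtx <- withr_seed(7, sort(runif(n, 0.5, 12)))
  rty <- 2 + 1.05 * rtx # exactly representable by the spline basis
  cp <- coupling(diag(n) / n)
  res <- drift_filter_pipeline(cp, rtx, rty)
  expect_equal(sum(res$coupling$pi > 0), n)
})

test_that("pipeline is equivariant under feature permutation", {
  n <- 80
  rtx <- withr_seed(8, sort(runif(n, 1, 10)))
  rty <- rt_drift_function(rtx) + withr_seed(9, runif(n, -0.1, 0.1))
  P <- diag(n) / n
  P[2, 5] <- P[5, 2] <- 1e-4 # a couple of off-diagonal support pairs
  base <- drift_filter_pipeline(coupling(P), rtx, rty)
  perm <- withr_seed(10, sample(n))
  res_p <- drift_filter_pipeline(coupling(P[perm, ]), rtx[perm], rty)
  expect_equal(res_p$coupling$pi, base$coupling$pi[perm, ],
               tolerance = 1e-12)
})
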