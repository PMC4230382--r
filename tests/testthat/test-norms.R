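test_that("method-of-moments fit matches the worked example", {
  nrm <- fit_norm(c(2, 5, 9, 14))
  # scaled values 0.10 0.25 0.45 0.70: m = 0.375, v = 0.050625
  expect_equal(nrm$alpha, 1.3611111, tolerance = 1e-6)
  expect_equal(nrm$beta, 2.2685185, tolerance = 1e-6)
  expect_false(nrm$degenerate)
})

test_that("zero variance and boundary-only samples are degenerate", {
  expect_true(fit_norm(c(12, 12, 12, 12))$degenerate)
  expect_true(fit_norm(c(0, 0, 20, 20))$degenerate)
  expect_true(fit_norm(c(0, 0, 0, 20))$degenerate)
})

test_that("fit validation rejects bad input", {
  expect_error(fit_norm(c(1, 2, 3)), "4-vector")
  expect_error(fit_norm(c(1, 2, 3, 21)), "0")
  expect_error(fit_norm(c(1, 2, 3, NA)), "4-vector")
})

test_that("moment fit agrees with a numerical oracle and preserves the mean", {
  set.seed(4)
  for (i in 1:300) {
    h <- sample(1:19, 4, replace = TRUE)
    if (var(h) == 0) next
    nrm <- fit_norm(h)
    expect_false(nrm$degenerate)
    ab <- oracle_beta_moments(h / 20)
    expect_equal(nrm$alpha, ab[1], tolerance = 1e-9)
    expect_equal(nrm$beta, ab[2], tolerance = 1e-9)
    # method-of-moments property: fitted mean equals the sample mean
    expect_equal(20 * nrm$alpha / (nrm$alpha + nrm$beta), mean(h),
                 tolerance = 1e-9)
  }
})

test_that("maximum-likelihood fitting is available and sane", {
  h <- c(3, 6, 10, 15)
  mm <- fit_norm(h)
  ml <- fit_norm(h, method = "mle")
  expect_false(ml$degenerate)
  expect_equal(ml$alpha, mm$alpha, tolerance = 0.5)
  expect_equal(ml$beta, mm$beta, tolerance = 0.5)
})

test_that("rank is the beta CDF with exact endpoints and symmetry", {
  nrm <- fit_norm(c(2, 5, 9, 14))
  expect_identical(rank_in_norm(0, nrm), 0)
  expect_identical(rank_in_norm(20, nrm), 1)
  expect_equal(rank_in_norm(12, nrm),
               pbeta(0.6, nrm$alpha, nrm$beta))
  # symmetric norm: midpoint ranks exactly 0.5
  sym <- fit_norm(c(6, 9, 11, 14))
  expect_equal(sym$alpha, sym$beta, tolerance = 1e-9)
  expect_equal(rank_in_norm(10, sym), 0.5)
})

test_that("rank is non-decreasing in the harvest value", {
  set.seed(5)
  for (i in 1:50) {
    h <- sample(1:19, 4, replace = TRUE)
    if (var(h) == 0) next
    r <- rank_in_norm(0:20, fit_norm(h))
    expect_true(all(diff(r) >= 0))
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("a harvest of 12 ranks lower under an over-harvesting norm", {
  over_norm <- fit_norm(c(14, 16, 18, 12))   # aggressive round
  under_norm <- fit_norm(c(2, 4, 6, 12))     # conservative round
  expect_lt(rank_in_norm(12, over_norm), rank_in_norm(12, under_norm))
})

test_that("degenerate norms fall back to the midrank convention", {
  nrm <- fit_norm(c(12, 12, 12, 12))
  expect_equal(rank_in_norm(12, nrm), 0.5)
  expect_equal(rank_in_norm(5, nrm), 0)
  expect_equal(rank_in_norm(15, nrm), 1)
  bd <- fit_norm(c(0, 0, 20, 20))
  expect_equal(rank_in_norm(0, bd), 0.25)
  expect_equal(rank_in_norm(20, bd), 0.75)
})

test_that("rank features are the rank and its exact powers", {
  rf <- build_rank_features(14, c(2, 5, 9, 14))
  expect_gt(rf[["rank"]], 0.5)  # largest of four distinct harvests
  expect_identical(rf[["rank2"]], rf[["rank"]]^2)
  expect_identical(rf[["rank3"]], rf[["rank"]]^3)
  expect_equal(build_rank_features(7, c(7, 7, 7, 7))[["rank"]], 0.5)
  expect_error(build_rank_features(4, c(2, 5, 9, 14)), "one of")
})

test_that("the largest of four distinct harvests always ranks above 0.5", {
  set.seed(6)
  for (i in 1:100) {
    h <- sample(1:19, 4)  # distinct
    rf <- build_rank_features(max(h), h)
    expect_gt(rf[["rank"]], 0.5)
  }
})
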