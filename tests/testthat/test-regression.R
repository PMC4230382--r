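# Synthetic trial tables with exactly known generating coefficients and
# continuous responses (no game dynamics), for estimator checks.
make_rows <- function(n = 800, noise_sd = 0, gen = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(gen))
    gen <- c(int = 0.5, trt = -0.4, prev = -0.6, res = 0.01, over = 0.8,
             r1 = -3, r2 = 8, r3 = -6, t1 = 2, t2 = -5, t3 = 4)
  trt <- rep(c(0, 1), each = n / 2)
  prev <- sample(0:20, n, replace = TRUE)
  res <- sample(50:300, n, replace = TRUE)
  over <- rbinom(n, 1, 0.5)
  r <- runif(n)
  mu <- gen["int"] + gen["trt"] * trt + gen["prev"] * prev +
    gen["res"] * res + gen["over"] * over +
    (gen["r1"] + gen["t1"] * trt) * r +
    (gen["r2"] + gen["t2"] * trt) * r^2 +
    (gen["r3"] + gen["t3"] * trt) * r^3
  data.frame(
    delta_harvest = mu + rnorm(n, 0, noise_sd),
    own_prev_harvest = prev, resource_before = res, over_present = over,
    rank = r, rank2 = r^2, rank3 = r^3,
    treatment = ifelse(trt == 1, "T_minus", "T_plus"),
    participant_id = rep(sprintf("p%02d", 1:16), length.out = n),
    stringsAsFactors = FALSE
  )
}

test_that("designs contain exactly the specified model terms", {
  rows <- make_rows(100)
  d1 <- build_design(rows, "model1")
  expect_identical(colnames(d1$X),
                   c("(Intercept)", "treatment_T_minus", "prev_harvest",
                     "resource", "over_present",
                     "treatment_T_minus:prev_harvest",
                     "treatment_T_minus:resource",
                     "treatment_T_minus:over_present"))
  d2 <- build_design(rows, "model2")
  expect_identical(colnames(d2$X),
                   c("(Intercept)", "treatment_T_minus", "prev_harvest",
                     "resource", "over_present", "rank", "rank2", "rank3",
                     "treatment_T_minus:rank", "treatment_T_minus:rank2",
                     "treatment_T_minus:rank3"))
  expect_equal(d2$y, rows$delta_harvest)
})

test_that("designs exclude first trials and warm-up rows", {
  cs <- simulate_cohort(n_per_group = 2, seed = 3, config = flat_config())
  d <- build_design(cs$trials, "model2")
  expect_true(all(!is.na(d$y)))
  expect_false(any(d$rows$environment == "warmup"))
  expect_false(any(d$rows$trial_index == 1))
  expect_true(all(d$rows$rank >= 0 & d$rows$rank <= 1))
})

test_that("degenerate inputs raise informative design errors", {
  rows <- make_rows(100)
  first_only <- rows
  first_only$delta_harvest <- NA_real_
  expect_error(build_design(first_only, "model1"), "no usable rows")
  one_grp <- rows[rows$treatment == "T_plus", ]
  expect_error(build_design(one_grp, "model1"), "both treatment")
  expect_error(build_design(rows[, -1], "model1"), "missing required")
})

test_that("noiseless data are recovered exactly", {
  gen <- c(int = 0.5, trt = -0.4, prev = -0.6, res = 0.01, over = 0.8,
           r1 = -3, r2 = 8, r3 = -6, t1 = 2, t2 = -5, t3 = 4)
  fit <- harvest_lm(make_rows(600, noise_sd = 0, gen = gen), "model2",
                    n_boot = 5, seed = 1)
  expect_equal(unname(fit$coefficients),
               unname(gen[c("int", "trt", "prev", "res", "over",
                            "r1", "r2", "r3", "t1", "t2", "t3")]),
               tolerance = 1e-8)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)
})

test_that("estimates are invariant to row order and duplication", {
  rows <- make_rows(400, noise_sd = 2)
  fit <- harvest_lm(rows, "model2", n_boot = 2, seed = 1)
  perm <- harvest_lm(rows[sample(nrow(rows)), ], "model2", n_boot = 2,
                     seed = 1)
  expect_equal(fit$coefficients, perm$coefficients, tolerance = 1e-10)
  doubled <- harvest_lm(rbind(rows, rows), "model2", n_boot = 2, seed = 1)
  expect_equal(fit$coefficients, doubled$coefficients, tolerance = 1e-10)
})

test_that("rank-deficient designs name the collinear terms", {
  rows <- make_rows(200)
  rows$rank <- 1
  rows$rank2 <- 1
  rows$rank3 <- 1
  expect_error(harvest_lm(rows, "model2", n_boot = 2), "rank2")
})

test_that("standardized coefficients ignore affine rescaling of the resource", {
  rows <- make_rows(500, noise_sd = 1)
  fit <- harvest_lm(rows, "model2", n_boot = 2, seed = 1)
  rescaled <- rows
  rescaled$resource_before <- rows$resource_before * 1000
  fit2 <- harvest_lm(rescaled, "model2", n_boot = 2, seed = 1)
  expect_equal(fit$std_coefficients, fit2$std_coefficients,
               tolerance = 1e-8)
  expect_equal(fit$coefficients[["resource"]],
               fit2$coefficients[["resource"]] * 1000, tolerance = 1e-8)
})

test_that("bootstrap intervals are ordered and bracket stable estimates", {
  rows <- make_rows(800, noise_sd = 2)
  fit <- harvest_lm(rows, "model2", n_boot = 200, seed = 2)
  expect_true(all(fit$ci[, "lower"] <= fit$ci[, "upper"]))
  expect_true(all(fit$ci[, "lower"] <= fit$coefficients &
                  fit$coefficients <= fit$ci[, "upper"]))
  perc <- harvest_lm(rows, "model2", n_boot = 200, seed = 2,
                     ci_type = "percentile")
  expect_true(all(perc$ci[, "lower"] <= perc$ci[, "upper"]))
})

test_that("bootstrap intervals widen with the noise level", {
  widths <- vapply(c(0.5, 4), function(s) {
    fit <- harvest_lm(make_rows(600, noise_sd = s, seed = 5), "model2",
                      n_boot = 150, seed = 3)
    mean(fit$ci[, "upper"] - fit$ci[, "lower"])
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("fit accessors and the report table are consistent", {
  rows <- make_rows(400, noise_sd = 1)
  fit <- harvest_lm(rows, "model1", n_boot = 20, seed = 1)
  expect_equal(nobs(fit), 400)
  expect_equal(fitted(fit) + residuals(fit), rows$delta_harvest)
  expect_equal(unname(predict(fit, rows)), unname(fitted(fit)))
  tab1 <- summarize_fit(fit)
  expect_equal(tab1$term, fit$terms)
  expect_true(all(c("estimate", "se", "ci_lower", "ci_upper",
                    "std_estimate", "p_value", "stars") %in% names(tab1)))
  tab2 <- summarize_fit(harvest_lm(rows, "model2", n_boot = 20, seed = 1))
  expect_true(all(c("rank", "rank2", "rank3") %in% tab2$term))
  expect_output(print(summary(harvest_lm(rows, "model1", n_boot = 20))),
                "model1")
})

test_that("fits on simulated control cohorts recover the coefficient signs", {
  set.seed(17)
  hits <- replicate(5, {
    cs <- simulate_cohort(n_per_group = 8, seed = sample.int(1e6, 1))
    fit <- harvest_lm(cs, "model1", n_boot = 2)
    fit$coefficients[["prev_harvest"]] < 0 &&
      fit$coefficients[["over_present"]] > 0
  })
  expect_true(all(hits))
})
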