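test_that("schedules satisfy the block design and adjacency constraints", {
  for (seed in 1:150) {
    sch <- generate_schedule(seed = seed)
    expect_equal(sch$total_trials, 109)
    expect_equal(sch$blocks$environment[1], "warmup")
    expect_equal(sch$blocks$length, c(5, rep(13, 8)))
    main <- sch$blocks$environment[-1]
    counts <- table(main)
    expect_true(all(counts == 2) && length(counts) == 4)
    a <- main[-8]; b <- main[-1]
    expect_false(any((a == "one_over" & b == "two_over") |
                     (a == "two_over" & b == "one_over")))
    expect_false(any((a == "one_under" & b == "two_under") |
                     (a == "two_under" & b == "one_under")))
  }
})

test_that("schedules are a pure function of the seed", {
  expect_identical(generate_schedule(seed = 99), generate_schedule(seed = 99))
})

test_that("salient roles match each environment's definition", {
  sch <- generate_schedule(seed = 5)
  for (b in seq_len(nrow(sch$blocks))) {
    roles <- sch$roles[b, ]
    env <- sch$blocks$environment[b]
    n_over <- sum(roles == "over")
    n_under <- sum(roles == "under")
    switch(env,
      warmup = expect_equal(unname(roles), rep("maintain", 3)),
      one_over = expect_equal(c(n_over, n_under), c(1, 0)),
      two_over = expect_equal(c(n_over, n_under), c(2, 0)),
      one_under = expect_equal(c(n_over, n_under), c(0, 1)),
      two_under = expect_equal(c(n_over, n_under), c(0, 2)))
    if (env %in% c("one_over", "two_over", "one_under", "two_under"))
      expect_true(all(roles[roles != "over" & roles != "under"] == "neutral"))
  }
})

test_that("maintain level is the root of the expected-update equation", {
  cfg <- engine_config()
  lev <- calibrate_roles(cfg, 230)
  # trio of maintainers: exactly zero expected drift
  expect_equal(expected_resource_change(3 * lev$maintain, 230, cfg), 0,
               tolerance = 1e-9)
  expect_equal(lev$maintain, 230 / 18, tolerance = 1e-9)
  expect_gt(lev$over, lev$maintain)
  expect_lt(lev$under, lev$maintain)
})

test_that("role trios impose the intended drift directions", {
  cfg <- engine_config()
  lev <- calibrate_roles(cfg, 230)
  drift <- function(trio) expected_resource_change(sum(trio), 230, cfg)
  over_one <- drift(c(lev$over, lev$neutral, lev$neutral))
  over_two <- drift(c(lev$over, lev$over, lev$neutral))
  under_one <- drift(c(lev$under, lev$neutral, lev$neutral))
  neutral_trio <- drift(rep(lev$neutral, 3))
  expect_lt(over_one, 0)
  expect_lt(over_two, over_one)
  expect_gt(under_one, 0)
  # neutral partners: gentle downward pressure, milder than the over trio
  expect_lt(neutral_trio, 0)
  expect_gt(neutral_trio, over_one)
})

test_that("calibration errors when the cap cannot express over-harvesting", {
  expect_error(calibrate_roles(engine_config(harvest_cap = 10L), 230),
               "calibration")
  expect_error(calibrate_roles(engine_config(), 0), "positive")
})

test_that("confederate harvests stay within bounds and respect emptiness", {
  expect_equal(confederate_harvest("over", 0), 0L)
  set.seed(8)
  for (i in 1:100) {
    h <- confederate_harvest(sample(c("over", "under", "neutral",
                                      "maintain"), 1),
                             sample(0:500, 1))
    expect_true(h >= 0 && h <= 20)
  }
  # jitter 0 gives the deterministic rounded level
  expect_equal(confederate_harvest("maintain", 230, jitter = 0L), 13L)
})

test_that("confederate-only blocks move the resource as described", {
  cfg <- engine_config()
  set.seed(11)
  block_change <- function(env) {
    roles <- switch(env,
      one_over = c("over", "neutral", "neutral"),
      two_over = c("over", "over", "neutral"),
      one_under = c("under", "neutral", "neutral"),
      two_under = c("under", "under", "neutral"),
      warmup = rep("maintain", 3))
    st <- new_game(cfg)
    n <- if (env == "warmup") 5 else 13
    for (i in seq_len(n)) {
      req <- c(0L, vapply(roles, confederate_harvest, integer(1),
                          current_resource = st$resource, config = cfg))
      st <- game_step(st, req, cfg)$state
      if (st$terminated) break
    }
    st$resource - cfg$initial_resource
  }
  overs <- replicate(150, block_change(sample(c("one_over", "two_over"), 1)))
  unders <- replicate(150, block_change(sample(c("one_under",
                                                 "two_under"), 1)))
  expect_lt(mean(overs), 0)
  expect_gt(mean(unders), 0)
  # warm-up partners keep the resource near its starting level
  warm <- replicate(100, block_change("warmup"))
  expect_true(all(abs(warm) <= 0.1 * cfg$initial_resource))
})
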