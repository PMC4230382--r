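test_that("harvests reduce the resource and credit player points", {
  st <- new_game()
  r <- apply_harvests(st, c(20, 20, 20, 20))
  expect_equal(r$state$resource, 150)
  expect_equal(r$fulfilled, rep(20L, 4))
  expect_equal(r$state$cumulative_points, rep(20L, 4))

  r0 <- apply_harvests(new_game(engine_config(initial_resource = 100L)),
                       c(0, 0, 0, 0))
  expect_equal(r0$state$resource, 100)
  expect_false(r0$state$terminated)
})

test_that("joint over-requests are apportioned and exhaust the game", {
  cfg <- engine_config(initial_resource = 10L)
  r <- apply_harvests(new_game(cfg), c(20, 20, 0, 0), cfg)
  expect_equal(r$fulfilled, oracle_largest_remainder(c(20, 20, 0, 0), 10))
  expect_equal(sum(r$fulfilled), 10)
  expect_equal(r$state$resource, 0)
  expect_true(r$state$terminated)
  expect_equal(r$state$termination_reason, "exhausted")
})

test_that("all shortfall rules fulfil exactly the remaining resource", {
  set.seed(7)
  for (i in 1:200) {
    req <- sample(0:20, 4, replace = TRUE)
    res <- sample.int(max(sum(req) - 1, 1), 1)
    if (sum(req) <= res || sum(req) == 0) next
    for (rule in c("proportional", "equal_split", "clip_in_order")) {
      cfg <- engine_config(initial_resource = res, shortfall_rule = rule)
      f <- apply_harvests(new_game(cfg), req, cfg)$fulfilled
      expect_equal(sum(f), res)
      expect_true(all(f <= req & f >= 0))
      if (rule == "proportional")
        expect_equal(f, oracle_largest_remainder(req, res))
    }
  }
})

test_that("harvest validation rejects bad requests and dead games", {
  st <- new_game()
  expect_error(apply_harvests(st, c(21, 0, 0, 0)), "request")
  expect_error(apply_harvests(st, c(-1, 0, 0, 0)), "request")
  expect_error(apply_harvests(st, c(1, 2, 3)), "4-vector")
  dead <- apply_harvests(new_game(engine_config(initial_resource = 5L)),
                         c(5, 0, 0, 0),
                         engine_config(initial_resource = 5L))$state
  expect_error(apply_harvests(dead, c(1, 0, 0, 0)), "terminated")
})

test_that("replenishment implements the damped rectangular update", {
  # forced increment: round(150/3 + (2/3) * (100 + 20)) = 130
  expect_equal(replenish(150, 100, increment = 20), 130)
  expect_equal(replenish(0, 0), 0)
  expect_error(replenish(-1, 10), "non-negative")
  expect_error(replenish(150, 100, increment = 30), "increment")

  set.seed(1)
  incs <- replicate(300, draw_replenish_increment(100))
  expect_true(all(incs >= 17 & incs <= 23))
  expect_setequal(unique(incs), 17:23)
})

test_that("termination rules fire at exhaustion and at the trial limit", {
  cfg <- engine_config()
  st <- new_game(cfg)
  st$trial_index <- 108L
  out <- game_step(st, c(0, 0, 0, 0), cfg)
  expect_true(out$state$terminated)
  expect_equal(out$state$termination_reason, "max_trials")

  cfg2 <- engine_config(initial_resource = 30L)
  out2 <- game_step(new_game(cfg2), c(10, 10, 10, 0), cfg2)
  expect_true(out2$state$terminated)
  expect_equal(out2$state$termination_reason, "exhausted")
  expect_true(is.na(out2$increment))
})

test_that("an unharvested resource grows by 17-23% when undamped", {
  cfg <- engine_config(initial_resource = 100L, previous_weight = 0)
  set.seed(2)
  for (i in 1:20) {
    out <- game_step(new_game(cfg), c(0, 0, 0, 0), cfg)
    expect_gte(out$state$resource, 117)
    expect_lte(out$state$resource, 123)
  }
})

test_that("trajectories are deterministic given the seed", {
  cfg <- engine_config()
  run <- function() {
    set.seed(42)
    simulate_resource_path(cfg, c(5, 5, 5, 5), 200)
  }
  expect_identical(run(), run())
})

test_that("each trial's resource matches the damped update to rounding", {
  cfg <- engine_config()
  set.seed(3)
  path <- simulate_resource_path(cfg, c(6, 5, 5, 4), 80)
  done <- !is.na(path$increment)
  expected <- with(path[done, ],
    cfg$previous_weight * resource_before +
      (1 - cfg$previous_weight) *
        (resource_before - total_fulfilled + increment))
  expect_true(all(abs(path$resource_after[done] - expected) <= 0.5))
})

test_that("raising one request lowers the post-harvest resource", {
  st <- new_game()
  lo <- apply_harvests(st, c(5, 5, 5, 5))$state$resource
  hi <- apply_harvests(st, c(9, 5, 5, 5))$state$resource
  expect_lt(hi, lo)
  expect_lt(expected_resource_change(24, 230),
            expected_resource_change(20, 230))
})

test_that("engine configuration is validated", {
  expect_error(engine_config(replenish_low_frac = 0.3,
                             replenish_high_frac = 0.2), "replenish")
  expect_error(engine_config(previous_weight = 1), "previous_weight")
  expect_error(engine_config(initial_resource = 0), "initial_resource")
  expect_error(engine_config(resource_cap = 10), "resource_cap")
})
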