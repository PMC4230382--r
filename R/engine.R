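#' Engine configuration for the resource-dilemma game
#'
#' Parameters of the four-player common-pool resource game: a shared resource
#' (initially 230 points) from which each player may harvest up to 20 points
#' per harvesting opportunity.  After all harvests the resource is replenished
#' by an integer drawn uniformly ("rectangular distribution") between 17% and
#' 23% of the post-harvest remainder, and the replenished value is damped by
#' mixing in one third of the resource value that opened the trial:
#' \deqn{R_{t+1} = \mathrm{round}\{ w R_t + (1-w)(R_t - H_t + u_t) \},}
#' where \eqn{H_t} is the group's total fulfilled harvest, \eqn{u_t} the
#' rectangular draw and \eqn{w = 1/3}.  The game terminates when the resource
#' reaches 0 or after \code{max_trials} harvesting opportunities.
#'
#' @param initial_resource starting resource value in points.
#' @param harvest_cap maximum points a single player may request per trial.
#' @param replenish_low_frac,replenish_high_frac bounds of the rectangular
#'   replenishment draw, as proportions of the post-harvest resource.
#' @param previous_weight weight \eqn{w} on the previous (pre-harvest)
#'   resource value in the damped update.
#' @param max_trials number of harvesting opportunities after which the game
#'   terminates automatically.
#' @param resource_cap optional ceiling on the resource value after
#'   replenishment (default unbounded).  The damped update grows the
#'   resource by ~13% per trial net of harvests, so trajectories in which
#'   harvesting falls behind can grow without limit; a cap provides a
#'   bounded regime for long-running simulation studies.
#' @param shortfall_rule how to fulfil requests when they jointly exceed the
#'   remaining resource: proportional largest-remainder apportionment
#'   (\code{"proportional"}), an equal integer split (\code{"equal_split"}),
#'   or sequential clipping in player order (\code{"clip_in_order"}).
#' @return an object of class \code{"engine_config"} (a validated list).
#' @examples
#' cfg <- engine_config()
#' cfg$initial_resource
#' @export
engine_config <- function(initial_resource = 230L,
                          harvest_cap = 20L,
                          replenish_low_frac = 0.17,
                          replenish_high_frac = 0.23,
                          previous_weight = 1 / 3,
                          max_trials = 109L,
                          resource_cap = Inf,
                          shortfall_rule = c("proportional", "equal_split",
                                             "clip_in_order")) {
  shortfall_rule <- match.arg(shortfall_rule)
  if (!is_count(initial_resource) || initial_resource < 1)
    stopf("'initial_resource' must be a positive integer")
  if (!is_count(harvest_cap) || harvest_cap < 1)
    stopf("'harvest_cap' must be a positive integer")
  if (!(replenish_low_frac > 0 && replenish_low_frac <= replenish_high_frac &&
        replenish_high_frac < 1))
    stopf("need 0 < replenish_low_frac <= replenish_high_frac < 1")
  if (!(previous_weight >= 0 && previous_weight < 1))
    stopf("'previous_weight' must be in [0, 1)")
  if (!is_count(max_trials) || max_trials < 1)
    stopf("'max_trials' must be a positive integer")
  if (!(is.numeric(resource_cap) && length(resource_cap) == 1L &&
        resource_cap >= initial_resource))
    stopf("'resource_cap' must be a number >= initial_resource")
  structure(list(initial_resource = as.integer(initial_resource),
                 harvest_cap = as.integer(harvest_cap),
                 replenish_low_frac = replenish_low_frac,
                 replenish_high_frac = replenish_high_frac,
                 previous_weight = previous_weight,
                 max_trials = as.integer(max_trials),
                 resource_cap = resource_cap,
                 shortfall_rule = shortfall_rule),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat("Resource-dilemma engine configuration\n")
  cat(sprintf("  initial resource : %d points\n", x$initial_resource))
  cat(sprintf("  per-harvest cap  : %d points\n", x$harvest_cap))
  cat(sprintf("  replenishment    : uniform integers in [%.0f%%, %.0f%%] of remainder\n",
              100 * x$replenish_low_frac, 100 * x$replenish_high_frac))
  cat(sprintf("  damping weight   : %.4f on previous resource\n",
              x$previous_weight))
  cat(sprintf("  max trials       : %d, shortfall rule: %s\n",
              x$max_trials, x$shortfall_rule))
  invisible(x)
}

#' Create a fresh game state
#'
#' @param config an [engine_config()].
#' @return an object of class \code{"game_state"}: resource value, per-player
#'   cumulative points (4-vector), trial index, termination flag and reason
#'   (\code{"running"}, \code{"exhausted"} or \code{"max_trials"}).
#' @export
new_game <- function(config = engine_config()) {
  stopifnot(inherits(config, "engine_config"))
  structure(list(resource = config$initial_resource,
                 cumulative_points = integer(4),
                 trial_index = 0L,
                 terminated = FALSE,
                 termination_reason = "running"),
            class = "game_state")
}

#' @export
print.game_state <- function(x, ...) {
  cat(sprintf("Game state: trial %d, resource %d, points [%s]%s\n",
              x$trial_index, x$resource,
              paste(x$cumulative_points, collapse = ", "),
              if (x$terminated)
                sprintf(" -- terminated (%s)", x$termination_reason) else ""))
  invisible(x)
}

# Apportion `resource` points among integer requests that exceed it.
allocate_shortfall <- function(requests, resource, rule) {
  n <- length(requests)
  switch(rule,
    proportional = {
      total <- sum(requests)
      quota <- resource * requests / total
      base <- floor(quota)
      extra <- resource - sum(base)
      if (extra > 0) {
        ord <- order(-(quota - base), seq_len(n))
        base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
      }
      as.integer(base)
    },
    equal_split = {
      left <- resource
      out <- integer(n)
      req <- requests
      while (left > 0 && any(req > 0)) {
        active <- which(req > 0)
        share <- left %/% length(active)
        if (share == 0) {
          take <- active[seq_len(left)]
          out[take] <- out[take] + 1L
          req[take] <- req[take] - 1L
          left <- 0L
        } else {
          give <- pmin(req[active], share)
          out[active] <- out[active] + give
          req[active] <- req[active] - give
          left <- left - sum(give)
        }
      }
      out
    },
    clip_in_order = {
      left <- resource
      out <- integer(n)
      for (i in seq_len(n)) {
        out[i] <- min(requests[i], left)
        left <- left - out[i]
      }
      out
    })
}

#' Apply one round of harvests to the game state
#'
#' Reduces the resource by the group's total fulfilled harvest and credits
#' each player's cumulative points.  When the joint request exceeds the
#' remaining resource, the shortfall rule of the configuration decides the
#' split (the fulfilled harvests then sum exactly to the pre-harvest
#' resource, which is driven to 0 and the game terminates as exhausted).
#'
#' @param state a [new_game()] state, not yet terminated.
#' @param requests integer 4-vector of requested harvests, each in
#'   \code{[0, harvest_cap]}.
#' @param config an [engine_config()].
#' @return a list with elements \code{state} (updated game state) and
#'   \code{fulfilled} (integer 4-vector of fulfilled harvests).
#' @examples
#' st <- new_game()
#' apply_harvests(st, c(20, 20, 20, 20))$state$resource  # 150
#' @export
apply_harvests <- function(state, requests, config = engine_config()) {
  stopifnot(inherits(state, "game_state"), inherits(config, "engine_config"))
  if (state$terminated)
    stopf("cannot harvest from a terminated game (reason: %s)",
          state$termination_reason)
  if (length(requests) != 4L || anyNA(requests) ||
      any(requests != trunc(requests)))
    stopf("'requests' must be an integer 4-vector")
  if (any(requests < 0 | requests > config$harvest_cap))
    stopf("each request must lie in [0, %d]", config$harvest_cap)
  requests <- as.integer(requests)

  if (sum(requests) <= state$resource) {
    fulfilled <- requests
  } else {
    fulfilled <- allocate_shortfall(requests, state$resource,
                                    config$shortfall_rule)
  }
  state$resource <- state$resource - sum(fulfilled)
  state$cumulative_points <- state$cumulative_points + fulfilled
  if (state$resource == 0L) {
    state$terminated <- TRUE
    state$termination_reason <- "exhausted"
  }
  list(state = state, fulfilled = fulfilled)
}

#' Draw a replenishment increment
#'
#' Uniform draw over the integer set from \code{round(low_frac * R)} to
#' \code{round(high_frac * R)} inclusive, where \code{R} is the post-harvest
#' resource.  Uses the current R random-number stream.
#'
#' @param post_harvest_resource non-negative integer resource after harvests.
#' @param config an [engine_config()].
#' @return a single non-negative integer.
#' @export
draw_replenish_increment <- function(post_harvest_resource,
                                     config = engine_config()) {
  if (!is_count(post_harvest_resource))
    stopf("'post_harvest_resource' must be a non-negative integer")
  lo <- round_half_up(config$replenish_low_frac * post_harvest_resource)
  hi <- round_half_up(config$replenish_high_frac * post_harvest_resource)
  # numeric (not integer) so that extreme resource values cannot overflow
  lo + sample.int(hi - lo + 1, 1L) - 1
}

#' Replenish the resource after a round of harvests
#'
#' Implements the damped replenishment update
#' \eqn{R_{new} = \mathrm{round}\{w R_{prev} + (1-w)(R_{post} + u)\}} with
#' \eqn{u} the rectangular integer increment.  \code{R_{prev}} is the
#' resource value that opened the harvesting opportunity; the one-third
#' weighting of the previous value damps trial-to-trial fluctuations.
#'
#' @param previous_resource resource value before this trial's harvests.
#' @param post_harvest_resource resource value after subtracting harvests.
#' @param config an [engine_config()].
#' @param increment optional forced increment (e.g. for deterministic
#'   analyses); when \code{NULL} it is drawn with
#'   [draw_replenish_increment()].  Must lie within the rectangular bounds.
#' @return the new resource value, a non-negative integer.
#' @examples
#' replenish(150, 100, increment = 20)  # round(150/3 + (2/3) * 120) = 130
#' @export
replenish <- function(previous_resource, post_harvest_resource,
                      config = engine_config(), increment = NULL) {
  if (!is_count(previous_resource) || !is_count(post_harvest_resource))
    stopf("resource values must be non-negative integers")
  lo <- round_half_up(config$replenish_low_frac * post_harvest_resource)
  hi <- round_half_up(config$replenish_high_frac * post_harvest_resource)
  if (is.null(increment)) {
    increment <- draw_replenish_increment(post_harvest_resource, config)
  } else if (!is_count(increment) || increment < lo || increment > hi) {
    stopf("'increment' must be an integer in [%d, %d]", lo, hi)
  }
  w <- config$previous_weight
  round_half_up(w * previous_resource +
                  (1 - w) * (post_harvest_resource + increment))
}

#' Advance the game by one harvesting opportunity
#'
#' Composes [apply_harvests()] and [replenish()], increments the trial index
#' and applies the two termination rules: exhaustion (resource reduced to 0,
#' in which case no replenishment occurs) and the automatic end of the game
#' after \code{max_trials} harvests.
#'
#' @inheritParams apply_harvests
#' @param increment optional forced replenishment increment (see
#'   [replenish()]).
#' @return a list with elements \code{state}, \code{fulfilled} and
#'   \code{increment} (\code{NA} when the game ended by exhaustion before
#'   replenishment).
#' @export
game_step <- function(state, requests, config = engine_config(),
                      increment = NULL) {
  previous <- state$resource
  h <- apply_harvests(state, requests, config)
  state <- h$state
  if (!state$terminated) {
    if (is.null(increment))
      increment <- draw_replenish_increment(state$resource, config)
    state$resource <- min(replenish(previous, state$resource, config,
                                    increment),
                          config$resource_cap)
  } else {
    increment <- NA_integer_
  }
  state$trial_index <- state$trial_index + 1L
  if (!state$terminated && state$trial_index >= config$max_trials) {
    state$terminated <- TRUE
    state$termination_reason <- "max_trials"
  }
  list(state = state, fulfilled = h$fulfilled, increment = increment)
}

#' Simulate the resource path under fixed harvest requests
#'
#' Convenience wrapper used to study the resource dynamics in isolation:
#' plays the same request vector every trial for up to \code{n_trials}
#' opportunities (overriding the configuration's trial limit) and returns
#' the trajectory.  Note that the expected update is linear in the resource
#' with slope \eqn{w + (1-w)(1+\bar\rho) > 1}, so the constant-harvest
#' fixed point \eqn{R^* = 6H} (for \eqn{w = 1/3}, mean multiplier 1.2) is
#' unstable: stochastic paths wander off unless the draw is held at its
#' mean via degenerate replenishment bounds.
#'
#' @param config an [engine_config()].
#' @param requests integer 4-vector of per-player requests used every trial.
#' @param n_trials number of harvesting opportunities to simulate.
#' @return a data frame with columns \code{trial}, \code{resource_before},
#'   \code{total_fulfilled}, \code{increment}, \code{resource_after}.
#' @examples
#' cfg <- engine_config(initial_resource = 120, replenish_low_frac = 0.2,
#'                      replenish_high_frac = 0.2, max_trials = 50)
#' path <- simulate_resource_path(cfg, c(5, 5, 5, 5), 50)
#' mean(path$resource_after)  # stays at the fixed point 6 * 20 = 120
#' @export
simulate_resource_path <- function(config, requests, n_trials) {
  config$max_trials <- as.integer(n_trials)
  state <- new_game(config)
  out <- data.frame(trial = seq_len(n_trials), resource_before = NA_integer_,
                    total_fulfilled = NA_integer_, increment = NA_integer_,
                    resource_after = NA_integer_)
  for (i in seq_len(n_trials)) {
    out$resource_before[i] <- state$resource
    stp <- game_step(state, requests, config)
    state <- stp$state
    out$total_fulfilled[i] <- sum(stp$fulfilled)
    out$increment[i] <- stp$increment
    out$resource_after[i] <- state$resource
    if (state$terminated) {
      out <- out[seq_len(i), ]
      break
    }
  }
  out
}

#' Expected one-trial resource change
#'
#' Evaluates the expected damped update
#' \eqn{E[R'] - R = w R + (1-w)(1+\bar\rho)(R - H) - R} for a given total
#' harvest \eqn{H}, where \eqn{\bar\rho} is the midpoint of the rectangular
#' replenishment bounds.  Used to calibrate confederate harvest levels.
#'
#' @param total_harvest total points harvested by the group this trial.
#' @param resource current resource value.
#' @param config an [engine_config()].
#' @return expected change in the resource (points, possibly fractional).
#' @export
expected_resource_change <- function(total_harvest, resource,
                                     config = engine_config()) {
  w <- config$previous_weight
  mult <- 1 + (config$replenish_low_frac + config$replenish_high_frac) / 2
  post <- max(resource - total_harvest, 0)
  w * resource + (1 - w) * mult * post - resource
}
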