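#' Simulate one participant's resource-dilemma game
#'
#' Plays a full game of one synthetic participant (player 1) against three
#' scripted confederates whose roles follow a pseudorandom environment
#' schedule.  Each harvesting opportunity proceeds as in the experiment:
#' all four players request privately, harvests are fulfilled against the
#' resource, the resource is replenished, and the trial-level record keeps
#' the participant's harvest, its change from the previous opportunity
#' (\code{delta_harvest}), and the rank of the previous harvest within the
#' beta-distribution social norm fitted to all four players' last harvests.
#'
#' The participant's first request (no history yet) is half the harvest cap.
#' The \code{over_present} indicator is 1 in over-harvesting environments,
#' 0 in under-harvesting environments and \code{NA} during warm-up (warm-up
#' rows are excluded from the regression design; the agent itself sees 0).
#'
#' @param params an [agent_params()] policy for the participant.
#' @param config an [engine_config()].
#' @param seed optional integer seed making the game reproducible.
#' @param schedule optional [generate_schedule()] object; drawn fresh when
#'   \code{NULL}.
#' @param game_id,participant_id identifiers stamped on every row.
#' @param jitter,offsets confederate policy options, see
#'   [confederate_harvest()].
#' @param n_env_repeats repetitions of each environment in the schedule
#'   (2 reproduces the experiment's 109-trial game; larger values give
#'   longer games for estimator-validation studies, extending the trial
#'   limit to match).
#' @return a list with elements \code{trials} (one data-frame row per
#'   harvesting opportunity) and \code{outcome} (single-row data frame:
#'   total participant points, final resource, exhaustion flag, trials
#'   completed, termination reason).
#' @examples
#' g <- simulate_game(default_agent_params("T_plus"), seed = 1)
#' nrow(g$trials) <= 109
#' @export
simulate_game <- function(params, config = engine_config(), seed = NULL,
                          schedule = NULL, game_id = 1L,
                          participant_id = "P1", jitter = 1L,
                          offsets = c(over = 1.5, neutral = 0.5, under = 8),
                          n_env_repeats = 2L) {
  stopifnot(inherits(params, "agent_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- generate_schedule(n_repeats = n_env_repeats)
  if (schedule$total_trials > config$max_trials) {
    config$max_trials <- as.integer(schedule$total_trials)
  }
  state <- new_game(config)
  n_max <- schedule$total_trials
  cap <- config$harvest_cap

  col_na <- rep(NA_real_, n_max)
  rec <- list(trial_index = seq_len(n_max),
              environment = schedule$trials$environment,
              resource_before = rep(NA_integer_, n_max),
              own_request = rep(NA_integer_, n_max),
              own_harvest = rep(NA_integer_, n_max),
              own_prev_harvest = rep(NA_integer_, n_max),
              delta_harvest = col_na,
              over_present = rep(NA_integer_, n_max),
              rank = col_na, rank2 = col_na, rank3 = col_na,
              norm_alpha = col_na, norm_beta = col_na,
              norm_degenerate = rep(NA, n_max),
              conf_harvest_1 = rep(NA_integer_, n_max),
              conf_harvest_2 = rep(NA_integer_, n_max),
              conf_harvest_3 = rep(NA_integer_, n_max),
              total_harvest = rep(NA_integer_, n_max),
              increment = rep(NA_integer_, n_max),
              resource_after = rep(NA_integer_, n_max))

  last_harvests <- NULL  # fulfilled harvests of the previous opportunity
  n_done <- 0L
  for (i in seq_len(n_max)) {
    env <- schedule$trials$environment[i]
    block <- schedule$trials$block[i]
    roles <- schedule$roles[block, ]
    rec$resource_before[i] <- state$resource

    conf_req <- vapply(roles, confederate_harvest, integer(1),
                       current_resource = state$resource, config = config,
                       jitter = jitter, offsets = offsets)
    over_ind <- if (env %in% over_environments) 1L
                else if (env %in% under_environments) 0L else NA_integer_

    if (is.null(last_harvests)) {
      own_req <- as.integer(min(round_half_up(cap / 2), state$resource, cap))
    } else {
      norm <- fit_norm(last_harvests, support_max = cap)
      r <- rank_in_norm(last_harvests[1], norm)
      rf <- c(rank = r, rank2 = r^2, rank3 = r^3)
      own_req <- agent_step(params, last_harvests[1], rf, state$resource,
                            over_present = if (is.na(over_ind)) 0L
                                           else over_ind,
                            harvest_cap = cap)
      rec$rank[i] <- r
      rec$rank2[i] <- r^2
      rec$rank3[i] <- r^3
      rec$norm_alpha[i] <- norm$alpha
      rec$norm_beta[i] <- norm$beta
      rec$norm_degenerate[i] <- norm$degenerate
      rec$own_prev_harvest[i] <- last_harvests[1]
    }

    stp <- game_step(state, c(own_req, conf_req), config)
    state <- stp$state
    f <- stp$fulfilled
    rec$own_request[i] <- own_req
    rec$own_harvest[i] <- f[1]
    if (!is.null(last_harvests))
      rec$delta_harvest[i] <- f[1] - last_harvests[1]
    rec$over_present[i] <- over_ind
    rec$conf_harvest_1[i] <- f[2]
    rec$conf_harvest_2[i] <- f[3]
    rec$conf_harvest_3[i] <- f[4]
    rec$total_harvest[i] <- sum(f)
    rec$increment[i] <- stp$increment
    rec$resource_after[i] <- state$resource
    last_harvests <- f
    n_done <- i
    if (state$terminated) break
  }

  trials <- data.frame(game_id = game_id, participant_id = participant_id,
                       treatment = params$treatment,
                       lapply(rec, function(v) v[seq_len(n_done)]),
                       stringsAsFactors = FALSE)
  outcome <- data.frame(game_id = game_id, participant_id = participant_id,
                        treatment = params$treatment,
                        total_points_participant = state$cumulative_points[1],
                        final_resource = state$resource,
                        exhausted = state$termination_reason == "exhausted",
                        n_trials_completed = n_done,
                        termination_reason = state$termination_reason,
                        stringsAsFactors = FALSE)
  list(trials = trials, outcome = outcome)
}

#' Simulate a synthetic two-treatment cohort
#'
#' Runs one independent game per synthetic participant: \code{n_per_group}
#' participants with the \code{T_plus} parameter set and the same number
#' with the \code{T_minus} set, each against three scripted confederates on
#' a freshly drawn environment schedule.  With a fixed \code{seed} the whole
#' cohort is reproducible.
#'
#' @param n_per_group participants per treatment group (>= 1).
#' @param params_T_plus,params_T_minus [agent_params()] sets for the two
#'   groups.
#' @param config an [engine_config()].
#' @param seed optional integer seed.
#' @param jitter,offsets confederate policy options, see
#'   [confederate_harvest()].
#' @param n_env_repeats repetitions of each environment per game (see
#'   [simulate_game()]).
#' @return an object of class \code{"cohort_sim"}: list with \code{trials}
#'   (tidy trial-level table over all games) and \code{outcomes} (one row
#'   per game).
#' @examples
#' cs <- simulate_cohort(n_per_group = 2, seed = 1)
#' table(cs$outcomes$treatment)
#' @export
simulate_cohort <- function(n_per_group = 16L,
                            params_T_plus = default_agent_params("T_plus"),
                            params_T_minus = default_agent_params("T_minus"),
                            config = engine_config(), seed = NULL,
                            jitter = 1L,
                            offsets = c(over = 1.5, neutral = 0.5, under = 8),
                            n_env_repeats = 2L) {
  if (!is_count(n_per_group) || n_per_group < 1)
    stopf("'n_per_group' must be a positive integer")
  stopifnot(inherits(params_T_plus, "agent_params"),
            inherits(params_T_minus, "agent_params"))
  if (!is.null(seed)) set.seed(seed)
  specs <- rbind(
    data.frame(treatment = "T_plus", idx = seq_len(n_per_group)),
    data.frame(treatment = "T_minus", idx = seq_len(n_per_group))
  )
  trials <- vector("list", nrow(specs))
  outcomes <- vector("list", nrow(specs))
  for (g in seq_len(nrow(specs))) {
    p <- if (specs$treatment[g] == "T_plus") params_T_plus else params_T_minus
    pid <- sprintf("%s_%02d", specs$treatment[g], specs$idx[g])
    game <- simulate_game(p, config = config, game_id = g,
                          participant_id = pid, jitter = jitter,
                          offsets = offsets, n_env_repeats = n_env_repeats)
    trials[[g]] <- game$trials
    outcomes[[g]] <- game$outcome
  }
  structure(list(trials = do.call(rbind, trials),
                 outcomes = do.call(rbind, outcomes)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  tab <- table(x$outcomes$treatment)
  cat(sprintf("Simulated cohort: %d games (%s), %d trial rows\n",
              nrow(x$outcomes),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              nrow(x$trials)))
  ex <- tapply(x$outcomes$exhausted, x$outcomes$treatment, mean)
  cat(sprintf("  exhaustion rate: %s\n",
              paste(sprintf("%s %.2f", names(ex), ex), collapse = ", ")))
  invisible(x)
}
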