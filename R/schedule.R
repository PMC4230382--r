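#' @title Social-environment schedule and confederate policies
#' @description Internal constants for the four confederate-defined social
#'   environments plus the warm-up phase.
#' @keywords internal
#' @name environments
NULL

main_environments <- c("one_over", "two_over", "one_under", "two_under")
over_environments <- c("one_over", "two_over")
under_environments <- c("one_under", "two_under")

#' Generate the pseudorandom environment schedule of a game
#'
#' A game consists of 5 warm-up harvesting opportunities followed by eight
#' 13-trial blocks: exactly two repetitions of each of the four social
#' environments (one/two over-harvesters, one/two under-harvesters), for a
#' total of 5 + 8 x 13 = 109 harvesting opportunities.  Block order is drawn
#' by rejection sampling over permutations until the adjacency constraints
#' hold: a one-overharvester block is never immediately preceded or followed
#' by a two-overharvesters block, and likewise for the underharvester blocks.
#' Each block also randomly assigns which of the three confederates take the
#' salient over/under roles; the remaining confederates are neutral
#' (mildly over-harvesting), and all three maintain the resource during the
#' warm-up.
#'
#' @param seed optional integer seed; when supplied the schedule is a pure
#'   function of it.
#' @param n_warmup warm-up trials at the start of the game.
#' @param block_length trials per social-environment block.
#' @param n_repeats repetitions of each of the four environments.
#' @return an object of class \code{"harvest_schedule"}: a list with
#'   \code{blocks} (data frame: block, environment, length), \code{roles}
#'   (character matrix, one row per block, one column per confederate),
#'   \code{trials} (data frame: trial, block, environment) and
#'   \code{total_trials}.
#' @examples
#' sch <- generate_schedule(seed = 1)
#' sch$total_trials  # 109
#' @export
generate_schedule <- function(seed = NULL, n_warmup = 5L, block_length = 13L,
                              n_repeats = 2L) {
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(main_environments, n_repeats)
  repeat {
    perm <- sample(labels)
    a <- perm[-length(perm)]
    b <- perm[-1]
    bad <- (a == "one_over" & b == "two_over") |
      (a == "two_over" & b == "one_over") |
      (a == "one_under" & b == "two_under") |
      (a == "two_under" & b == "one_under")
    if (!any(bad)) break
  }
  blocks <- data.frame(
    block = seq_len(length(perm) + 1L),
    environment = c("warmup", perm),
    length = c(n_warmup, rep(block_length, length(perm))),
    stringsAsFactors = FALSE
  )
  roles <- t(vapply(blocks$environment, assign_roles, character(3)))
  rownames(roles) <- NULL
  colnames(roles) <- paste0("confederate_", 1:3)
  trials <- data.frame(
    trial = seq_len(sum(blocks$length)),
    block = rep(blocks$block, blocks$length),
    environment = rep(blocks$environment, blocks$length),
    stringsAsFactors = FALSE
  )
  structure(list(blocks = blocks, roles = roles, trials = trials,
                 total_trials = nrow(trials)),
            class = "harvest_schedule")
}

# Randomly pick which confederates carry the salient role of a block.
assign_roles <- function(environment) {
  roles <- rep("neutral", 3)
  if (environment == "warmup") return(rep("maintain", 3))
  n_salient <- if (environment %in% c("two_over", "two_under")) 2L else 1L
  salient <- sample.int(3L, n_salient)
  roles[salient] <- if (environment %in% over_environments) "over" else "under"
  roles
}

#' @export
print.harvest_schedule <- function(x, ...) {
  cat(sprintf("Harvest schedule: %d trials in %d blocks\n",
              x$total_trials, nrow(x$blocks)))
  cat(paste(sprintf("  block %d: %-10s (%d trials)", x$blocks$block,
                    x$blocks$environment, x$blocks$length),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Calibrate confederate harvest levels against the engine dynamics
#'
#' The exact scripted confederate harvests are derived from the expected
#' resource update rather than taken as given.  With damping weight \eqn{w}
#' and mean replenishment multiplier \eqn{1+\bar\rho}, a trio of playing
#' partners harvesting \eqn{m = R\bar\rho / (3(1+\bar\rho))} points each
#' (\eqn{R/18} at the defaults) imposes exactly zero expected drift on the
#' resource, which is the warm-up "maintain" level.  The salient and neutral
#' roles are fixed offsets from \eqn{m}: neutral slightly above (so that the
#' playing partners alone exert gentle downward pressure), over well above,
#' under well below.  Offsets were chosen so that, against the engine's
#' expected dynamics, a confederate trio shrinks the resource in
#' over-harvesting environments and grows it in under-harvesting
#' environments, while the schedule-average confederate extraction leaves
#' headroom for a moderate participant harvest.
#'
#' @param config an [engine_config()].
#' @param reference_resource resource value (> 0) at which to calibrate.
#' @param offsets named numeric vector of role offsets (points) relative to
#'   the maintain level: \code{over}, \code{neutral}, \code{under} (the
#'   under offset is subtracted).
#' @param strict when \code{TRUE}, raise a calibration error if the harvest
#'   cap cannot express an over-harvesting level above maintenance; when
#'   \code{FALSE}, silently saturate levels at the cap (used trial-by-trial
#'   inside simulations, where the resource may transiently exceed the
#'   calibratable range).
#' @return a list with numeric elements \code{over}, \code{under},
#'   \code{neutral}, \code{maintain} (points, possibly fractional) and
#'   \code{zero_drift_total} (the trio total with zero expected drift).
#' @examples
#' calibrate_roles(engine_config(), 230)$maintain  # ~12.78 = 230/18
#' @export
calibrate_roles <- function(config = engine_config(), reference_resource,
                            offsets = c(over = 1.5, neutral = 0.5, under = 8),
                            strict = TRUE) {
  if (!is.numeric(reference_resource) || length(reference_resource) != 1L ||
      !is.finite(reference_resource) || reference_resource <= 0)
    stopf("'reference_resource' must be a positive number")
  rho <- (config$replenish_low_frac + config$replenish_high_frac) / 2
  m <- reference_resource * rho / (3 * (1 + rho))
  cap <- config$harvest_cap
  if (strict && cap <= m)
    stopf(paste("calibration error: harvest cap %d cannot exceed the",
                "maintain level %.2f at resource %s"),
          cap, m, format(reference_resource))
  list(over = min(cap, m + offsets[["over"]]),
       under = max(0, m - offsets[["under"]]),
       neutral = min(cap, m + offsets[["neutral"]]),
       maintain = min(cap, m),
       zero_drift_total = 3 * m)
}

#' Emit one confederate harvest
#'
#' Looks up the confederate's calibrated role level at the current resource
#' value, adds a small uniform integer jitter (behavioural noise) and clips
#' the result to the valid harvest range.  An empty resource yields a
#' harvest of 0.
#'
#' @param role one of \code{"over"}, \code{"under"}, \code{"neutral"},
#'   \code{"maintain"}.
#' @param current_resource current resource value (non-negative integer).
#' @param config an [engine_config()].
#' @param jitter half-width (points) of the uniform integer jitter; 0 gives
#'   a deterministic level.
#' @param offsets passed to [calibrate_roles()].
#' @return an integer harvest request in \code{[0, harvest_cap]}.
#' @export
confederate_harvest <- function(role, current_resource,
                                config = engine_config(), jitter = 1L,
                                offsets = c(over = 1.5, neutral = 0.5,
                                            under = 8)) {
  role <- match.arg(role, c("over", "under", "neutral", "maintain"))
  if (!is_count(current_resource))
    stopf("'current_resource' must be a non-negative integer")
  if (current_resource == 0L) return(0L)
  levels <- calibrate_roles(config, current_resource, offsets, strict = FALSE)
  level <- round_half_up(levels[[role]])
  if (jitter > 0)
    level <- level + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
  as.integer(clip(level, 0L, config$harvest_cap))
}
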