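#' Synthetic participant policy parameters
#'
#' A synthetic participant adjusts its harvest from one opportunity to the
#' next by a linear function of the same regressors the downstream
#' harvest-adjustment model fits, plus Gaussian noise:
#' \deqn{\Delta H = b_0 + b_{prev} H_{n-1} + b_{res} R + b_{over} O +
#'       c_1 r + c_2 r^2 + c_3 r^3 + \epsilon,}
#' where \eqn{H_{n-1}} is the player's own last harvest, \eqn{R} the current
#' resource, \eqn{O} an indicator for the presence of over-harvesting
#' co-players, and \eqn{r} the relative rank of the last harvest in the
#' group's social norm.  The requested harvest is
#' \code{round(H_prev + delta)} clipped to \code{[0, cap]} (round first,
#' then clip).
#'
#' @param intercept baseline adjustment (points).
#' @param coef_prev_harvest coefficient on the own preceding harvest
#'   (negative values give self-correction after large harvests).
#' @param coef_resource coefficient on the current resource value.
#' @param coef_over_present coefficient on the over-harvesters indicator.
#' @param coef_rank1,coef_rank2,coef_rank3 cubic rank-polynomial
#'   coefficients.
#' @param noise_sd standard deviation (points) of the Gaussian adjustment
#'   noise; must be non-negative.
#' @param treatment \code{"T_plus"} or \code{"T_minus"} tag.
#' @return an object of class \code{"agent_params"}.
#' @seealso [default_agent_params()] for the calibrated treatment sets.
#' @export
agent_params <- function(intercept = 0, coef_prev_harvest = 0,
                         coef_resource = 0, coef_over_present = 0,
                         coef_rank1 = 0, coef_rank2 = 0, coef_rank3 = 0,
                         noise_sd = 0,
                         treatment = c("T_plus", "T_minus")) {
  treatment <- match.arg(treatment)
  vals <- c(intercept, coef_prev_harvest, coef_resource, coef_over_present,
            coef_rank1, coef_rank2, coef_rank3, noise_sd)
  if (!is.numeric(vals) || anyNA(vals) || !all(is.finite(vals)))
    stopf("agent parameters must be finite numbers")
  if (noise_sd < 0) stopf("'noise_sd' must be non-negative")
  structure(list(intercept = intercept,
                 coef_prev_harvest = coef_prev_harvest,
                 coef_resource = coef_resource,
                 coef_over_present = coef_over_present,
                 coef_rank1 = coef_rank1, coef_rank2 = coef_rank2,
                 coef_rank3 = coef_rank3, noise_sd = noise_sd,
                 treatment = treatment),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("Agent parameters (%s):\n", x$treatment))
  cat(sprintf("  intercept %.3f, prev harvest %.3f, resource %.4f, over present %.3f\n",
              x$intercept, x$coef_prev_harvest, x$coef_resource,
              x$coef_over_present))
  cat(sprintf("  rank cubic (%.2f, %.2f, %.2f), noise sd %.2f\n",
              x$coef_rank1, x$coef_rank2, x$coef_rank3, x$noise_sd))
  invisible(x)
}

#' Default treatment-dependent agent parameter sets
#'
#' Calibrated parameter sets standing in for the two treatment groups of the
#' tryptophan study.  They reproduce the qualitative sign pattern of the
#' published regressions, not the printed standardized coefficients (those
#' are estimates on the unavailable human data): the control set
#' (\code{"T_plus"}) has strong self-correction (large negative coefficient
#' on the own preceding harvest), a positive response to over-harvesting
#' co-players, and a cubic rank response producing upward adjustments after
#' bottom-ranked harvests and downward adjustments after top-ranked ones;
#' the depleted set (\code{"T_minus"}) has attenuated self-correction, a
#' higher baseline harvest, and a flattened rank response.  Under the
#' default game configuration the depleted set exhausts the resource more
#' often and accumulates fewer points.
#'
#' @param treatment \code{"T_plus"} or \code{"T_minus"}.
#' @return an [agent_params()] object.
#' @examples
#' default_agent_params("T_plus")$coef_prev_harvest   # negative
#' @export
default_agent_params <- function(treatment = c("T_plus", "T_minus")) {
  treatment <- match.arg(treatment)
  if (treatment == "T_plus") {
    agent_params(intercept = 0, coef_prev_harvest = -0.7,
                 coef_resource = 0.02, coef_over_present = 0.6,
                 coef_rank1 = -6, coef_rank2 = 18, coef_rank3 = -16,
                 noise_sd = 2, treatment = "T_plus")
  } else {
    agent_params(intercept = 0.2, coef_prev_harvest = -0.5,
                 coef_resource = 0.02, coef_over_present = 0.5,
                 coef_rank1 = 3.6, coef_rank2 = -5.4, coef_rank3 = 2.6,
                 noise_sd = 2, treatment = "T_minus")
  }
}

#' Draw one synthetic participant harvest request
#'
#' @param params an [agent_params()] object.
#' @param own_last_harvest the player's own previous harvest (points).
#' @param rank_features named vector from [build_rank_features()] (elements
#'   \code{rank}, \code{rank2}, \code{rank3}).
#' @param resource current resource value.
#' @param over_present 0/1 indicator for over-harvesting co-players.
#' @param harvest_cap per-harvest cap (points).
#' @return an integer harvest request in \code{[0, harvest_cap]}.
#' @examples
#' agent_step(agent_params(), own_last_harvest = 7,
#'            rank_features = c(rank = 0.5, rank2 = 0.25, rank3 = 0.125),
#'            resource = 150, over_present = 0)  # 7: identity policy
#' @export
agent_step <- function(params, own_last_harvest, rank_features, resource,
                       over_present, harvest_cap = 20L) {
  stopifnot(inherits(params, "agent_params"))
  if (!over_present %in% c(0, 1)) stopf("'over_present' must be 0 or 1")
  delta <- params$intercept +
    params$coef_prev_harvest * own_last_harvest +
    params$coef_resource * resource +
    params$coef_over_present * over_present +
    params$coef_rank1 * rank_features[["rank"]] +
    params$coef_rank2 * rank_features[["rank2"]] +
    params$coef_rank3 * rank_features[["rank3"]]
  if (params$noise_sd > 0)
    delta <- delta + stats::rnorm(1, 0, params$noise_sd)
  as.integer(clip(round_half_up(own_last_harvest + delta), 0L, harvest_cap))
}
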