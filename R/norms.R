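#' Fit a descriptive social norm to a round of harvests
#'
#' The group's descriptive social norm at a harvesting opportunity is the
#' beta distribution, scaled to the harvest support \code{[0, 20]}, fitted to
#' the four players' harvests from that opportunity.  The default estimator
#' is closed-form method of moments on the harvests rescaled to \code{[0,1]}:
#' with sample mean \eqn{m} and population (n-divisor) variance \eqn{v},
#' \deqn{\alpha = m\,c, \quad \beta = (1-m)\,c, \quad c = m(1-m)/v - 1.}
#' Moment feasibility (\eqn{v < m(1-m)}) is assessed on the raw rescaled
#' values; sets with zero variance or infeasible moments (e.g. harvests all
#' at the support boundaries) are flagged \code{degenerate} and later ranked
#' by the midrank fallback instead of a beta CDF.  For feasible sets the fit
#' itself uses values clipped to \code{[eps, 1-eps]} so that boundary
#' harvests of 0 or 20 keep the likelihood and moments finite.
#'
#' @param harvests numeric vector of exactly four harvests in
#'   \code{[0, support_max]}.
#' @param method \code{"moments"} (closed form, default) or \code{"mle"}
#'   (numerical maximum likelihood, moments-initialised).
#' @param eps boundary clipping applied to the rescaled values before
#'   fitting.
#' @param support_max upper end of the harvest support.
#' @return an object of class \code{"beta_norm"}: list with \code{alpha},
#'   \code{beta} (NA when degenerate), \code{degenerate}, \code{harvests},
#'   \code{support}, \code{method}.
#' @examples
#' fit_norm(c(2, 5, 9, 14))       # alpha ~ 1.361, beta ~ 2.269
#' fit_norm(c(12, 12, 12, 12))    # degenerate: zero variance
#' @export
fit_norm <- function(harvests, method = c("moments", "mle"), eps = 1e-3,
                     support_max = 20) {
  method <- match.arg(method)
  if (length(harvests) != 4L || anyNA(harvests) || !is.numeric(harvests))
    stopf("'harvests' must be a numeric 4-vector")
  if (any(harvests < 0 | harvests > support_max))
    stopf("harvests must lie in [0, %s]", format(support_max))
  x_raw <- harvests / support_max
  m <- mean(x_raw)
  v <- mean((x_raw - m)^2)  # population variance, stable for n = 4
  degenerate <- v <= 0 || v >= m * (1 - m)
  alpha <- beta <- NA_real_
  if (!degenerate) {
    x <- clip(x_raw, eps, 1 - eps)
    mm <- mean(x)
    vv <- mean((x - mm)^2)
    common <- mm * (1 - mm) / vv - 1
    alpha <- mm * common
    beta <- (1 - mm) * common
    if (method == "mle") {
      nll <- function(p) -sum(stats::dbeta(x, exp(p[1]), exp(p[2]),
                                           log = TRUE))
      opt <- stats::optim(log(c(alpha, beta)), nll, method = "BFGS")
      alpha <- exp(opt$par[1])
      beta <- exp(opt$par[2])
    }
  }
  structure(list(alpha = alpha, beta = beta, degenerate = degenerate,
                 harvests = as.numeric(harvests),
                 support = c(0, support_max), method = method),
            class = "beta_norm")
}

#' @export
print.beta_norm <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Degenerate social norm on [0, %g]: harvests [%s] (midrank fallback)\n",
                x$support[2], paste(x$harvests, collapse = ", ")))
  } else {
    cat(sprintf("Beta social norm on [0, %g]: alpha = %.4f, beta = %.4f (%s)\n",
                x$support[2], x$alpha, x$beta, x$method))
  }
  invisible(x)
}

#' Relative rank of a harvest within a social norm
#'
#' The rank of a harvest is its cumulative density within the fitted norm:
#' \code{pbeta(value / 20, alpha, beta)}.  A harvest of 0 ranks exactly 0
#' and a harvest of 20 exactly 1; under a symmetric norm the midpoint ranks
#' exactly 0.5.  For degenerate norms (zero variance or infeasible moments)
#' the fallback is the midrank convention within the four stored harvests:
#' (number strictly smaller + 0.5 x number of ties, self included) / 4.
#'
#' @param value numeric harvest value(s) within the support.
#' @param norm a [fit_norm()] object.
#' @return numeric rank(s) in \code{[0, 1]}.
#' @examples
#' rank_in_norm(12, fit_norm(c(2, 5, 9, 14)))
#' @export
rank_in_norm <- function(value, norm) {
  stopifnot(inherits(norm, "beta_norm"))
  if (anyNA(value) || any(value < norm$support[1] | value > norm$support[2]))
    stopf("'value' must lie in [%g, %g]", norm$support[1], norm$support[2])
  if (norm$degenerate) {
    vapply(value, function(v) {
      (sum(norm$harvests < v) + 0.5 * sum(norm$harvests == v)) /
        length(norm$harvests)
    }, numeric(1))
  } else {
    stats::pbeta(value / norm$support[2], norm$alpha, norm$beta)
  }
}

#' Rank features of a player's last harvest
#'
#' Fits the social norm to all four players' last harvests (own harvest
#' included) and returns the player's relative rank together with its square
#' and cube, the cubic-polynomial regressors of the harvest-adjustment
#' model.
#'
#' @param own_last_harvest the player's own last harvest; must be one of
#'   \code{all_last_harvests}.
#' @param all_last_harvests numeric 4-vector of all players' last harvests.
#' @param ... passed to [fit_norm()].
#' @return named numeric vector \code{c(rank, rank2, rank3)} with
#'   \code{rank2 == rank^2} and \code{rank3 == rank^3} exactly.
#' @examples
#' build_rank_features(14, c(2, 5, 9, 14))
#' @export
build_rank_features <- function(own_last_harvest, all_last_harvests, ...) {
  if (!own_last_harvest %in% all_last_harvests)
    stopf("'own_last_harvest' must be one of 'all_last_harvests'")
  norm <- fit_norm(all_last_harvests, ...)
  r <- rank_in_norm(own_last_harvest, norm)
  c(rank = r, rank2 = r^2, rank3 = r^3)
}
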