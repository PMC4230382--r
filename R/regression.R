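#' Build the harvest-adjustment design matrix
#'
#' Constructs the response (\code{delta_harvest}, the trial-to-trial change
#' in a participant's harvest) and the regressor matrix of the two
#' harvest-adjustment models.  Model 1 contains the participant's own
#' preceding harvest, the current resource value, the indicator for the
#' presence of one or two over-harvesting co-players (under-harvesting
#' environments are the referent), the depleted-treatment indicator
#' (\code{T_minus}, with \code{T_plus} as the referent) and the
#' treatment-by-regressor interactions.  Model 2 retains the structural main
#' effects (without their treatment interactions) and adds the cubic
#' rank polynomial of the last harvest within the group's social norm,
#' with treatment interactions for the three rank terms.
#'
#' First-trial rows (no preceding harvest) and warm-up rows (no over/under
#' environment defined) are excluded.
#'
#' @param rows a tidy trial-level data frame as produced by
#'   [simulate_cohort()] (columns \code{delta_harvest},
#'   \code{own_prev_harvest}, \code{resource_before}, \code{over_present},
#'   \code{rank}, \code{rank2}, \code{rank3}, \code{treatment},
#'   \code{participant_id}).
#' @param model \code{"model1"} or \code{"model2"}.
#' @return a list with \code{X} (numeric design matrix including intercept),
#'   \code{y} (response), \code{cluster} (participant ids), \code{rows}
#'   (the retained data rows) and \code{model}.
#' @export
build_design <- function(rows, model = c("model1", "model2")) {
  model <- match.arg(model)
  needed <- c("delta_harvest", "own_prev_harvest", "resource_before",
              "over_present", "treatment", "participant_id")
  if (model == "model2") needed <- c(needed, "rank", "rank2", "rank3")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols))
    stopf("missing required columns: %s", paste(missing_cols, collapse = ", "))
  keep <- !is.na(rows$delta_harvest) & !is.na(rows$over_present) &
    !is.na(rows$own_prev_harvest)
  if (model == "model2") keep <- keep & !is.na(rows$rank)
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L)
    stopf("no usable rows: need trials with a preceding harvest in a main (over/under) environment")
  if (length(unique(rows$treatment)) < 2L)
    stopf("both treatment groups must be present to model treatment terms")

  tminus <- as.numeric(rows$treatment == "T_minus")
  X <- cbind(`(Intercept)` = 1,
             treatment_T_minus = tminus,
             prev_harvest = rows$own_prev_harvest,
             resource = rows$resource_before,
             over_present = as.numeric(rows$over_present))
  if (model == "model1") {
    X <- cbind(X,
               `treatment_T_minus:prev_harvest` = tminus * rows$own_prev_harvest,
               `treatment_T_minus:resource` = tminus * rows$resource_before,
               `treatment_T_minus:over_present` = tminus * rows$over_present)
  } else {
    X <- cbind(X,
               rank = rows$rank, rank2 = rows$rank2, rank3 = rows$rank3,
               `treatment_T_minus:rank` = tminus * rows$rank,
               `treatment_T_minus:rank2` = tminus * rows$rank2,
               `treatment_T_minus:rank3` = tminus * rows$rank3)
  }
  list(X = X, y = rows$delta_harvest, cluster = rows$participant_id,
       rows = rows, model = model)
}

# Columns that are genuinely binary (0/1) are left unscaled when
# standardizing; everything else (except the intercept) is z-scored.
standardize_design <- function(X, y) {
  Xs <- X
  for (j in seq_len(ncol(X))[-1]) {
    v <- X[, j]
    if (all(v %in% c(0, 1))) next
    s <- stats::sd(v)
    if (s > 0) Xs[, j] <- (v - mean(v)) / s
  }
  list(X = Xs, y = (y - mean(y)) / stats::sd(y))
}

# Cluster-robust (CR1) standard errors for an OLS fit.
cluster_se <- function(X, residuals, xtx_inv, cluster) {
  idx <- split(seq_len(nrow(X)), cluster)
  G <- length(idx)
  scores <- vapply(idx, function(ix) {
    colSums(X[ix, , drop = FALSE] * residuals[ix])
  }, numeric(ncol(X)))
  meat <- tcrossprod(scores)
  n <- nrow(X); p <- ncol(X)
  adj <- G / (G - 1) * (n - 1) / (n - p)
  # numerical floor: with very few clusters the sandwich diagonal can dip
  # microscopically below zero
  sqrt(pmax(adj * diag(xtx_inv %*% meat %*% xtx_inv), 0))
}

# OLS with an informative error on rank deficiency.
ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("design matrix is rank-deficient; collinear terms: %s",
          paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  res <- as.numeric(y - X %*% coef)
  xtx_inv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  list(coefficients = coef, residuals = res,
       fitted = as.numeric(X %*% coef), xtx_inv = xtx_inv,
       df_residual = nrow(X) - ncol(X))
}

# One cluster-bootstrap resample: row indices plus the resampled cluster
# instance labels (each drawn copy of a participant counts as a distinct
# cluster), stratified by treatment group.
resample_clusters <- function(ids_by_group) {
  out_rows <- integer(0)
  out_cl <- integer(0)
  k <- 0L
  for (idlist in ids_by_group) {
    draws <- sample.int(length(idlist), replace = TRUE)
    for (d in draws) {
      k <- k + 1L
      rows <- idlist[[d]]
      out_rows <- c(out_rows, rows)
      out_cl <- c(out_cl, rep(k, length(rows)))
    }
  }
  list(rows = out_rows, cluster = out_cl)
}

#' Fit a harvest-adjustment regression
#'
#' Pooled ordinary-least-squares fit of the trial-to-trial harvest
#' adjustment (\eqn{\Delta}Harvest) on the Model 1 or Model 2 regressors
#' (see [build_design()]), with cluster-robust standard errors and 95%
#' confidence intervals from a participant-level (cluster) bootstrap: whole
#' participants are resampled with replacement, stratified by treatment
#' group so both groups remain represented in every resample.  By default
#' the intervals are studentized (bootstrap-t); plain percentile intervals
#' are available via \code{ci_type}.  Coefficients are reported on the raw
#' scale and as standardized coefficients (response and continuous
#' regressors z-scored; binary indicators untouched); standardization is
#' re-applied within each bootstrap resample.
#'
#' @param data a [simulate_cohort()] result or tidy trial-level data frame.
#' @param model \code{"model1"} or \code{"model2"}.
#' @param n_boot number of cluster-bootstrap resamples (>= 1).
#' @param seed optional integer seed for the bootstrap.
#' @param conf_level confidence level of the intervals.
#' @param ci_type \code{"studentized"} (default): cluster bootstrap-t
#'   intervals, each resample's coefficient studentized by its own
#'   cluster-robust standard error — the standard refinement for a modest
#'   number of clusters (here 16 per group); \code{"percentile"}: plain
#'   percentile intervals of the bootstrap coefficient distribution.
#' @param keep_boot keep the bootstrap coefficient draws for audit.
#' @return an object of class \code{"harvest_lm"} with components
#'   \code{coefficients}, \code{se}, \code{ci}, \code{std_coefficients},
#'   \code{std_se}, \code{std_ci}, \code{n_obs} (per treatment group),
#'   \code{residuals}, \code{fitted} and bookkeeping fields.  Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{confint},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{nobs} and
#'   \code{plot}.
#' @examples
#' \donttest{
#' cs <- simulate_cohort(n_per_group = 4, seed = 1)
#' fit <- harvest_lm(cs, model = "model1", n_boot = 50, seed = 2)
#' summary(fit)
#' }
#' @export
harvest_lm <- function(data, model = c("model1", "model2"), n_boot = 500L,
                       seed = NULL, conf_level = 0.95,
                       ci_type = c("studentized", "percentile"),
                       keep_boot = FALSE) {
  model <- match.arg(model)
  ci_type <- match.arg(ci_type)
  rows <- if (inherits(data, "cohort_sim")) data$trials else data
  if (!is.data.frame(rows)) stopf("'data' must be a data frame or cohort_sim")
  if (!is_count(n_boot) || n_boot < 1)
    stopf("'n_boot' must be a positive integer")
  d <- build_design(rows, model)
  fit <- ols_fit(d$X, d$y)
  fit$se <- cluster_se(d$X, fit$residuals, fit$xtx_inv, d$cluster)
  sd_xy <- standardize_design(d$X, d$y)
  fit_std <- ols_fit(sd_xy$X, sd_xy$y)
  fit_std$se <- cluster_se(sd_xy$X, fit_std$residuals, fit_std$xtx_inv,
                           d$cluster)

  if (!is.null(seed)) set.seed(seed)
  cl <- d$cluster
  trt <- d$rows$treatment
  groups <- split(seq_along(cl), trt)
  ids_by_group <- lapply(groups, function(ix) split(ix, cl[ix]))
  p <- ncol(d$X)
  boot_raw <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, colnames(d$X)))
  boot_std <- boot_raw
  t_raw <- boot_raw
  t_std <- boot_raw
  boot_one <- function(X, y, cluster) {
    fb <- .lm.fit(X, y)
    if (fb$rank < p) return(NULL)
    cb <- fb$coefficients
    cb[fb$pivot] <- fb$coefficients
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- cluster_se(X, y - as.numeric(X %*% cb), xtx_inv, cluster)
    list(coef = cb, se = se)
  }
  for (b in seq_len(n_boot)) {
    rs <- resample_clusters(ids_by_group)
    Xb <- d$X[rs$rows, , drop = FALSE]
    yb <- d$y[rs$rows]
    fb <- boot_one(Xb, yb, rs$cluster)
    if (is.null(fb)) next
    boot_raw[b, ] <- fb$coef
    t_raw[b, ] <- (fb$coef - fit$coefficients) / fb$se
    sb <- standardize_design(Xb, yb)
    fbs <- boot_one(sb$X, sb$y, rs$cluster)
    if (is.null(fbs)) next
    boot_std[b, ] <- fbs$coef
    t_std[b, ] <- (fbs$coef - fit_std$coefficients) / fbs$se
  }
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  make_ci <- function(est, se, boot, tstat) {
    if (ci_type == "percentile") {
      ci <- t(apply(boot, 2, stats::quantile, probs = probs, na.rm = TRUE))
    } else {
      tq <- apply(tstat, 2, stats::quantile, probs = rev(probs),
                  na.rm = TRUE)
      ci <- cbind(est - tq[1, ] * se, est - tq[2, ] * se)
    }
    dimnames(ci) <- list(colnames(boot), c("lower", "upper"))
    ci
  }
  ci <- make_ci(fit$coefficients, fit$se, boot_raw, t_raw)
  std_ci <- make_ci(fit_std$coefficients, fit_std$se, boot_std, t_std)

  structure(list(coefficients = fit$coefficients, se = fit$se, ci = ci,
                 std_coefficients = fit_std$coefficients,
                 std_se = fit_std$se, std_ci = std_ci,
                 residuals = fit$residuals, fitted = fit$fitted,
                 df_residual = fit$df_residual,
                 n_clusters = length(unique(cl)),
                 n_obs = table(trt), n_boot = n_boot,
                 conf_level = conf_level, model = model, ci_type = ci_type,
                 terms = colnames(d$X), cluster = cl, data = d$rows,
                 boot = if (keep_boot) list(raw = boot_raw, std = boot_std),
                 call = match.call()),
            class = "harvest_lm")
}

#' @export
print.harvest_lm <- function(x, digits = 3, ...) {
  cat(sprintf("Harvest-adjustment regression (%s), %d observations (%s)\n",
              x$model, sum(x$n_obs),
              paste(sprintf("%s: %d", names(x$n_obs), x$n_obs),
                    collapse = ", ")))
  cat(sprintf("Cluster bootstrap: %d resamples, %.0f%% %s CIs\n\n",
              x$n_boot, 100 * x$conf_level, x$ci_type))
  print(round(cbind(estimate = x$coefficients, se = x$se, x$ci), digits))
  invisible(x)
}

#' @export
coef.harvest_lm <- function(object, standardized = FALSE, ...) {
  if (standardized) object$std_coefficients else object$coefficients
}

#' @export
confint.harvest_lm <- function(object, parm, level, standardized = FALSE,
                               ...) {
  ci <- if (standardized) object$std_ci else object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.harvest_lm <- function(object, ...) object$residuals

#' @export
fitted.harvest_lm <- function(object, ...) object$fitted

#' @export
nobs.harvest_lm <- function(object, ...) sum(object$n_obs)

#' @export
predict.harvest_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  rows <- if (inherits(newdata, "cohort_sim")) newdata$trials else newdata
  d <- build_design(rows, object$model)
  as.numeric(d$X %*% object$coefficients)
}

#' Summarize a harvest-adjustment regression
#'
#' Produces the coefficient report: raw and standardized estimates, their
#' cluster-robust standard errors, the cluster-bootstrap confidence
#' intervals, t-test p-values (t on clusters - 1 degrees of freedom) and
#' significance stars (\code{* p < .05, ** p < .01, *** p < .0001}).
#'
#' @param object a [harvest_lm()] fit.
#' @param ... unused.
#' @return an object of class \code{"summary.harvest_lm"} whose
#'   \code{$table} is a data frame with one row per term;
#'   \code{as.data.frame()} extracts it (see [summarize_fit()]).
#' @export
summary.harvest_lm <- function(object, ...) {
  tval <- object$coefficients / object$se
  pval <- 2 * stats::pt(-abs(tval), object$n_clusters - 1)
  stars <- ifelse(pval < 1e-4, "***", ifelse(pval < .01, "**",
                  ifelse(pval < .05, "*", "")))
  tab <- data.frame(term = object$terms,
                    estimate = as.numeric(object$coefficients),
                    se = object$se,
                    ci_lower = object$ci[, "lower"],
                    ci_upper = object$ci[, "upper"],
                    std_estimate = as.numeric(object$std_coefficients),
                    std_se = object$std_se,
                    std_ci_lower = object$std_ci[, "lower"],
                    std_ci_upper = object$std_ci[, "upper"],
                    p_value = pval, stars = stars,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, model = object$model, n_obs = object$n_obs,
                 n_boot = object$n_boot, conf_level = object$conf_level),
            class = "summary.harvest_lm")
}

#' @export
print.summary.harvest_lm <- function(x, digits = 3, ...) {
  cat(sprintf("Harvest-adjustment regression (%s)\n", x$model))
  cat(sprintf("Observations: %s; %d bootstrap resamples (%.0f%% CIs)\n\n",
              paste(sprintf("%s %d", names(x$n_obs), x$n_obs),
                    collapse = ", "),
              x$n_boot, 100 * x$conf_level))
  out <- x$table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  print(out, row.names = FALSE)
  cat("\nSignif.: * p < .05, ** p < .01, *** p < .0001\n")
  invisible(x)
}

#' @export
as.data.frame.summary.harvest_lm <- function(x, ...) x$table

#' Coefficient report table of a fitted harvest regression
#'
#' Convenience wrapper returning [summary.harvest_lm()]'s report as a plain
#' data frame, ready to be written to CSV.
#'
#' @param fit a [harvest_lm()] fit.
#' @return a data frame with one row per model term.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "harvest_lm"))
  as.data.frame(summary(fit))
}

#' Plot the rank response of a Model 2 fit
#'
#' Scatterplot of harvest adjustments against the rank of the preceding
#' harvest, overlaid with each treatment group's fitted cubic polynomial
#' (structural regressors held at their group means).
#'
#' @param x a [harvest_lm()] fit with \code{model = "model2"}.
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.harvest_lm <- function(x, ...) {
  if (x$model != "model2")
    stopf("rank-response plot requires a model2 fit")
  rows <- x$data
  cols <- ifelse(rows$treatment == "T_minus",
                 grDevices::adjustcolor("firebrick", 0.35),
                 grDevices::adjustcolor("steelblue", 0.35))
  graphics::plot(rows$rank, rows$delta_harvest, col = cols, pch = 16,
                 xlab = "rank of last harvest in social norm",
                 ylab = expression(Delta * "Harvest"), ...)
  b <- x$coefficients
  r <- seq(0, 1, length.out = 101)
  for (grp in c("T_plus", "T_minus")) {
    sub <- rows[rows$treatment == grp, ]
    tm <- as.numeric(grp == "T_minus")
    base <- b["(Intercept)"] + b["treatment_T_minus"] * tm +
      b["prev_harvest"] * mean(sub$own_prev_harvest) +
      b["resource"] * mean(sub$resource_before) +
      b["over_present"] * mean(sub$over_present)
    curve_y <- base + (b["rank"] + tm * b["treatment_T_minus:rank"]) * r +
      (b["rank2"] + tm * b["treatment_T_minus:rank2"]) * r^2 +
      (b["rank3"] + tm * b["treatment_T_minus:rank3"]) * r^3
    graphics::lines(r, curve_y, lwd = 2,
                    col = if (grp == "T_minus") "firebrick" else "steelblue")
  }
  graphics::legend("topright", legend = c("T+", "T-"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
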