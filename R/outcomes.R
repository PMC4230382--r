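#' Pearson chi-square for a 2x2 contingency table
#'
#' Uncorrected Pearson statistic in closed form,
#' \deqn{\chi^2 = \frac{N (ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}, \quad df = 1,}
#' the form consistent with the published exhaustion comparison (a Yates
#' continuity correction would give a different value).
#'
#' @param table a 2x2 numeric matrix of non-negative counts, or the count
#'   \code{a} when \code{b}, \code{c}, \code{d} are given separately (rows:
#'   groups; columns: outcome present/absent).
#' @param b,c,d remaining cell counts when \code{table} is scalar \code{a}.
#' @return an object of class \code{"htest"} with the statistic, df = 1 and
#'   the upper-tail p-value.
#' @examples
#' chi_square_2x2(8, 8, 2, 14)   # 5.24: exhaustion by treatment group
#' @export
chi_square_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stopf("'table' must be 2x2")
    m <- table
  } else {
    m <- matrix(c(table, b, c, d), 2, 2, byrow = TRUE)
  }
  if (anyNA(m) || any(m < 0)) stopf("counts must be non-negative")
  n <- sum(m)
  if (n == 0) stopf("table total must be positive")
  margins <- c(rowSums(m), colSums(m))
  if (any(margins == 0))
    stopf("chi-square undefined: zero margin in the 2x2 table")
  stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 / prod(margins)
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = 1),
                 p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 method = "Pearson chi-square (2x2, no continuity correction)",
                 data.name = sprintf("2x2 table, N = %s", format(n))),
            class = "htest")
}

#' Cross-tabulate resource exhaustion by treatment group
#'
#' @param outcomes a game-outcome data frame (one row per game, columns
#'   \code{treatment} and \code{exhausted}), e.g.
#'   \code{simulate_cohort(...)$outcomes}.
#' @return a 2x2 integer matrix (rows \code{T_minus}, \code{T_plus};
#'   columns \code{exhausted}, \code{not_exhausted}).
#' @examples
#' \donttest{
#' cs <- simulate_cohort(n_per_group = 4, seed = 1)
#' exhaustion_table(cs$outcomes)
#' }
#' @export
exhaustion_table <- function(outcomes) {
  if (!all(c("treatment", "exhausted") %in% names(outcomes)))
    stopf("'outcomes' needs columns 'treatment' and 'exhausted'")
  groups <- c("T_minus", "T_plus")
  if (!all(groups %in% outcomes$treatment))
    stopf("both treatment groups must be present")
  m <- t(vapply(groups, function(g) {
    e <- outcomes$exhausted[outcomes$treatment == g]
    c(exhausted = sum(e), not_exhausted = sum(!e))
  }, integer(2)))
  rownames(m) <- groups
  m
}

#' Summarize endgame outcomes by treatment group
#'
#' Per-group means and standard errors of the participant's total harvested
#' points and of the final resource value, plus exhaustion counts and
#' proportions.  For a single-game group the standard error is undefined
#' and reported as \code{NA} with \code{se_defined = FALSE}.
#'
#' @param outcomes a game-outcome data frame (columns \code{treatment},
#'   \code{total_points_participant}, \code{final_resource},
#'   \code{exhausted}).
#' @return a data frame with one row per treatment group.
#' @export
summarize_outcomes <- function(outcomes) {
  needed <- c("treatment", "total_points_participant", "final_resource",
              "exhausted")
  if (!all(needed %in% names(outcomes)))
    stopf("'outcomes' needs columns: %s", paste(needed, collapse = ", "))
  if (nrow(outcomes) == 0L) stopf("'outcomes' is empty")
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                    else NA_real_
  groups <- split(outcomes, outcomes$treatment)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    o <- groups[[g]]
    data.frame(treatment = g, n_games = nrow(o),
               mean_total_points = mean(o$total_points_participant),
               se_total_points = se(o$total_points_participant),
               mean_final_resource = mean(o$final_resource),
               se_final_resource = se(o$final_resource),
               n_exhausted = sum(o$exhausted),
               prop_exhausted = mean(o$exhausted),
               se_defined = nrow(o) > 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
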