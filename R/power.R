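#' Dilute a complier-level effect to an intention-to-treat effect
#'
#' When only a fraction `pi_c` of participants change behaviour because of
#' the offer, a complier-level outcome effect `delta_complier` appears
#' between randomized arms as `pi_c * delta_complier` — the dilution that
#' drives sample size for trials powered on a downstream outcome.
#'
#' @param delta_complier effect among compliers, grams.
#' @param pi_c compliance gap (complier proportion) in (0, 1].
#' @return The intention-to-treat effect in grams.
#' @export
itt_effect <- function(delta_complier, pi_c) {
  if (any(pi_c <= 0) || any(pi_c > 1)) {
    stop("pi_c must lie in (0, 1]", call. = FALSE)
  }
  pi_c * delta_complier
}

#' Sample size for a two-sided two-sample t test
#'
#' Smallest per-group n achieving the target power against a mean difference
#' `delta` with common standard deviation `sd`, for a two-sided test at level
#' `alpha` with equal allocation.  The default solves the noncentral-t power
#' equation ([stats::power.t.test()]); `method = "normal"` uses the
#' closed-form normal approximation
#' \eqn{n = 2 \sigma^2 (z_{1-\alpha/2} + z_{power})^2 / \delta^2}.
#'
#' @param delta true mean difference (> 0), grams.
#' @param sd common standard deviation (> 0), grams.
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param method `"t"` (noncentral t, default) or `"normal"`.
#' @return Integer n per group (total is twice this).
#' @export
sample_size_two_sample_t <- function(delta, sd, alpha = 0.05, power = 0.80,
                                     method = c("t", "normal")) {
  method <- match.arg(method)
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- if (method == "t") {
    stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                        power = power, type = "two.sample",
                        alternative = "two.sided")$n
  } else {
    2 * (sd / delta)^2 * (stats::qnorm(1 - alpha / 2) +
                            stats::qnorm(power))^2
  }
  as.integer(ceiling(n - 1e-9))
}

#' Power of a two-sided two-sample t test at a given n
#'
#' @param n_per_group per-group sample size (>= 2).
#' @param delta true mean difference, grams.
#' @param sd common standard deviation, grams.
#' @param alpha two-sided significance level.
#' @return Achieved power under the noncentral-t alternative.
#' @export
power_at_n <- function(n_per_group, delta, sd, alpha = 0.05) {
  stopifnot(n_per_group >= 2)
  stats::power.t.test(n = n_per_group, delta = delta, sd = sd,
                      sig.level = alpha, type = "two.sample",
                      alternative = "two.sided")$power
}

#' Sample-size table over a grid of design assumptions
#'
#' Expands a grid of complier-level effects, compliance gaps and outcome
#' standard deviations, dilutes each effect to its intention-to-treat scale,
#' and returns the per-group and total sample sizes with the power achieved
#' at the returned (rounded-up) n.
#'
#' @param delta_complier vector of complier-level effects, grams.
#' @param pi_c vector of compliance gaps in (0, 1].
#' @param sd vector of common standard deviations, grams.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return A `data.frame` with one row per grid point: `delta_complier`,
#'   `pi_c`, `sd`, `delta_itt`, `n_per_group`, `n_total`, `achieved_power`.
#' @export
power_table <- function(delta_complier, pi_c, sd, alpha = 0.05,
                        power = 0.80) {
  g <- expand.grid(delta_complier = delta_complier, pi_c = pi_c, sd = sd,
                   KEEP.OUT.ATTRS = FALSE)
  g$delta_itt <- itt_effect(g$delta_complier, g$pi_c)
  g$n_per_group <- mapply(sample_size_two_sample_t, delta = g$delta_itt,
                          sd = g$sd, MoreArgs = list(alpha = alpha,
                                                     power = power))
  g$n_total <- 2L * g$n_per_group
  g$achieved_power <- mapply(power_at_n, n_per_group = g$n_per_group,
                             delta = g$delta_itt, sd = g$sd,
                             MoreArgs = list(alpha = alpha))
  g
}
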