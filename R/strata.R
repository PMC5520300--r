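#' Latent compliance-stratum proportions
#'
#' Under monotonicity (no defiers) the population splits into three principal
#' strata: hardened smokers (never-quitters), independent quitters
#' (always-quitters) and potential quitters (compliers, who quit only when
#' offered the incentive).  Because quitting is deterministic in (stratum,
#' arm), the incentives-arm continuing-smoker fraction estimates the hardened
#' smoker proportion and the control-arm quitter fraction the independent
#' quitter proportion; the complier proportion is the remainder — identical
#' to the between-arm difference in quit rates.
#'
#' @param xtab a `"trial_crosstab"` with both arms nonempty.
#' @return A list of class `"strata_proportions"`: `p_hs`, `p_iq`, `p_pq`
#'   (`p_defier` is fixed at 0) and a logical `valid`, `FALSE` when
#'   `p_pq <= 0` (possible in bootstrap resamples; such estimates are flagged
#'   rather than raised as errors so resampling can count them).
#' @export
strata_proportions <- function(xtab) {
  stopifnot(inherits(xtab, "trial_crosstab"))
  if (any(xtab$arm_n == 0)) {
    stop("an arm has no analyzable records", call. = FALSE)
  }
  p_hs <- xtab$n["incentives", "smoker"] / xtab$arm_n[["incentives"]]
  p_iq <- xtab$n["control", "quitter"] / xtab$arm_n[["control"]]
  p_pq <- 1 - p_hs - p_iq
  structure(list(p_hs = p_hs, p_iq = p_iq, p_pq = p_pq, p_defier = 0,
                 valid = p_pq > 0),
            class = "strata_proportions")
}

#' @export
print.strata_proportions <- function(x, ...) {
  cat(sprintf("Stratum proportions: hardened smokers %.3f, independent quitters %.3f, potential quitters %.3f%s\n",
              x$p_hs, x$p_iq, x$p_pq,
              if (x$valid) "" else "  [INVALID: non-positive complier proportion]"))
  invisible(x)
}

#' Observed cell means entering the stratum inversion
#'
#' Extracts from the cross-tab the four observed means the inversion uses —
#' control-arm continuing smokers (`w0`), incentives-arm quitters (`w1`), and
#' the two per-arm overall means (`mu0`, `mu1`) — together with the two
#' directly identified stratum means: hardened smokers (`w_hs`, from
#' incentives-arm smokers) and independent quitters (`w_iq`, from control-arm
#' quitters).
#'
#' @param xtab a `"trial_crosstab"`; the four referenced cells must be
#'   nonempty.
#' @return A list of class `"observed_cell_means"` with elements `w0`, `w1`,
#'   `mu0`, `mu1`, `w_hs`, `w_iq`.
#' @export
observed_means <- function(xtab) {
  stopifnot(inherits(xtab, "trial_crosstab"))
  need <- rbind(c("control", "smoker"), c("control", "quitter"),
                c("incentives", "smoker"), c("incentives", "quitter"))
  empty <- xtab$n[need] == 0
  if (any(empty)) {
    stop("empty cell(s): ",
         paste(apply(need[empty, , drop = FALSE], 1L, paste,
                     collapse = " / "), collapse = "; "),
         call. = FALSE)
  }
  structure(list(w0 = xtab$mean["control", "smoker"],
                 w1 = xtab$mean["incentives", "quitter"],
                 mu0 = xtab$arm_mean[["control"]],
                 mu1 = xtab$arm_mean[["incentives"]],
                 w_hs = xtab$mean["incentives", "smoker"],
                 w_iq = xtab$mean["control", "quitter"]),
            class = "observed_cell_means")
}

#' Solve for the potential-quitter means
#'
#' The incentives-arm quitter mean is a mixture of independent quitters and
#' compliers, and the control-arm smoker mean a mixture of hardened smokers
#' and compliers.  Inverting the two weighted-mean identities yields the
#' complier mean under each arm:
#' \deqn{W_{PQQ} = \frac{W_1 (P_{IQ}+P_{PQ}) - P_{IQ} W_{IQ}}{P_{PQ}}, \qquad
#'       W_{PQS} = \frac{W_0 (P_{HS}+P_{PQ}) - P_{HS} W_{HS}}{P_{PQ}}.}
#'
#' @param props a [strata_proportions()] result.
#' @param cells an [observed_means()] result.
#' @return A list of class `"strata_means"` with `w_hs`, `w_iq`, `w_pqq`
#'   (complier mean when offered incentives), `w_pqs` (complier mean without
#'   the offer), at full precision, plus `valid`.  When `props` is invalid
#'   (`p_pq <= 0`), the potential-quitter means are `NA` sentinels — never an
#'   error, so bootstrap replicates can record the failure.
#' @export
solve_potential_quitter_means <- function(props, cells) {
  stopifnot(inherits(props, "strata_proportions"),
            inherits(cells, "observed_cell_means"))
  if (!props$valid) {
    return(structure(list(w_hs = cells$w_hs, w_iq = cells$w_iq,
                          w_pqq = NA_real_, w_pqs = NA_real_, valid = FALSE),
                     class = "strata_means"))
  }
  w_pqq <- (cells$w1 * (props$p_iq + props$p_pq) -
              props$p_iq * cells$w_iq) / props$p_pq
  w_pqs <- (cells$w0 * (props$p_hs + props$p_pq) -
              props$p_hs * cells$w_hs) / props$p_pq
  structure(list(w_hs = cells$w_hs, w_iq = cells$w_iq, w_pqq = w_pqq,
                 w_pqs = w_pqs, valid = TRUE),
            class = "strata_means")
}

#' @export
print.strata_means <- function(x, ...) {
  cat("Estimated stratum mean birth weights (g):\n")
  cat(sprintf("  hardened smokers                 %8.1f\n", x$w_hs))
  cat(sprintf("  potential quitters, no offer     %8.1f\n", x$w_pqs))
  cat(sprintf("  potential quitters, offered      %8.1f\n", x$w_pqq))
  cat(sprintf("  independent quitters             %8.1f\n", x$w_iq))
  invisible(x)
}

new_cace_estimate <- function(point, method, proportions,
                              interval = NULL) {
  structure(list(point = point, method = method, proportions = proportions,
                 interval = interval, valid = is.finite(point)),
            class = "cace_estimate")
}

#' Complier effect from the stratum-mean inversion
#'
#' The causal effect of the incentive offer among potential quitters is the
#' difference between their two solved means: `w_pqq - w_pqs`.
#'
#' @param strata a [solve_potential_quitter_means()] result.
#' @param proportions optionally, the [strata_proportions()] used, carried
#'   along in the estimate.
#' @return A `"cace_estimate"` with `point` (grams) and
#'   `method = "intuitive"`; invalid strata propagate to an invalid (`NA`)
#'   estimate.
#' @export
cace_intuitive <- function(strata, proportions = NULL) {
  stopifnot(inherits(strata, "strata_means"))
  point <- if (strata$valid) strata$w_pqq - strata$w_pqs else NA_real_
  new_cace_estimate(point, "intuitive", proportions)
}

#' Complier effect as an instrumental-variable Wald ratio
#'
#' Treating randomization as an instrument that affects birth weight only
#' through quitting, the complier average causal effect is the
#' intention-to-treat outcome difference divided by the compliance gap:
#' \deqn{\mu_{c1} - \mu_{c0} = (\mu_1 - \mu_0) / \pi_c.}
#' On any complete-case cohort this is algebraically identical to
#' [cace_intuitive()] computed from the same cross-tab.
#'
#' @param xtab a `"trial_crosstab"`.
#' @return A `"cace_estimate"` with `method = "wald_ratio"`; a non-positive
#'   compliance gap yields an invalid (`NA`) estimate, not an error.
#' @export
cace_wald <- function(xtab) {
  props <- strata_proportions(xtab)
  point <- if (props$valid) {
    (xtab$arm_mean[["incentives"]] - xtab$arm_mean[["control"]]) / props$p_pq
  } else {
    NA_real_
  }
  new_cace_estimate(point, "wald_ratio", props)
}

#' @export
print.cace_estimate <- function(x, ...) {
  lab <- c(intuitive = "stratum-mean inversion",
           wald_ratio = "IV Wald ratio")[[x$method]]
  if (!x$valid) {
    cat(sprintf("CACE (%s): INVALID (non-positive compliance gap)\n", lab))
    return(invisible(x))
  }
  cat(sprintf("CACE (%s): %.1f g", lab, x$point))
  if (!is.null(x$interval)) {
    cat(sprintf("  [%.0f%% BCa CI %.0f, %.0f]", 100 * x$interval$level,
                x$interval$lower, x$interval$upper))
  }
  cat("\n")
  invisible(x)
}

#' Run both estimators on one cohort and compare
#'
#' Computes the stratum-inversion and Wald-ratio estimates from the same
#' complete-case cross-tab and reports their absolute difference.  Because
#' both are derived from the same weighted-mean identities, they agree to
#' numerical precision on any individual-level cohort; the comparison makes
#' that identity visible.
#'
#' @param cohort a [trial_cohort()].
#' @return A list of class `"equivalence_report"`: both `"cace_estimate"`s,
#'   `abs_difference`, `identical_to_1e6` (difference below 1e-6 g), and the
#'   shared proportions.  Invalid estimates propagate (`abs_difference` `NA`).
#' @export
equivalence_report <- function(cohort) {
  xtab <- cross_tab(cohort)
  props <- strata_proportions(xtab)
  intuit <- if (props$valid) {
    cace_intuitive(solve_potential_quitter_means(props, observed_means(xtab)),
                   props)
  } else {
    new_cace_estimate(NA_real_, "intuitive", props)
  }
  wald <- cace_wald(xtab)
  d <- abs(intuit$point - wald$point)
  structure(list(intuitive = intuit, wald = wald, abs_difference = d,
                 identical_to_1e6 = isTRUE(d < 1e-6), proportions = props),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  print(x$intuitive)
  print(x$wald)
  if (is.na(x$abs_difference)) {
    cat("Both estimates invalid: non-positive compliance gap.\n")
  } else {
    cat(sprintf("Absolute difference: %.2e g (%s)\n", x$abs_difference,
                if (x$identical_to_1e6) "identical to < 1e-6 g"
                else "NOT within 1e-6 g"))
  }
  invisible(x)
}

# Fast estimator chain on raw vectors, shared by the bootstrap, jackknife and
# simulation harnesses.  Complete-case; returns the five estimates plus the
# compliance gap, or NA sentinels when the gap is <= tol or a needed cell is
# empty.
chain_estimates <- function(inc, quit, w, tol = 1e-6) {
  keep <- !is.na(w)
  inc <- inc[keep]; quit <- quit[keep]; w <- w[keep]
  n_cs <- sum(!inc & !quit); n_cq <- sum(!inc & quit)
  n_is <- sum(inc & !quit);  n_iq <- sum(inc & quit)
  nc <- n_cs + n_cq; ni <- n_is + n_iq
  if (nc == 0L || ni == 0L || n_cs == 0L || n_cq == 0L ||
      n_is == 0L || n_iq == 0L) {
    return(c(w_hs = NA_real_, w_iq = NA_real_, w_pqq = NA_real_,
             w_pqs = NA_real_, cace = NA_real_, p_pq = NA_real_))
  }
  p_hs <- n_is / ni
  p_iq <- n_cq / nc
  p_pq <- 1 - p_hs - p_iq
  w_hs <- sum(w[inc & !quit]) / n_is
  w_iq <- sum(w[!inc & quit]) / n_cq
  if (p_pq <= tol) {
    return(c(w_hs = w_hs, w_iq = w_iq, w_pqq = NA_real_, w_pqs = NA_real_,
             cace = NA_real_, p_pq = p_pq))
  }
  w1 <- sum(w[inc & quit]) / n_iq
  w0 <- sum(w[!inc & !quit]) / n_cs
  w_pqq <- (w1 * (p_iq + p_pq) - p_iq * w_iq) / p_pq
  w_pqs <- (w0 * (p_hs + p_pq) - p_hs * w_hs) / p_pq
  c(w_hs = w_hs, w_iq = w_iq, w_pqq = w_pqq, w_pqs = w_pqs,
    cace = w_pqq - w_pqs, p_pq = p_pq)
}
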