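#' Run the full analysis pipeline on a cohort
#'
#' Ties the stages together the way the trial reanalysis proceeds: (1) the
#' birth weight cross-tab, (2) the quit-rate contrast with its Fisher exact
#' test and the between-arm and quitter-vs-smoker t tests, (3) the stratum
#' proportions and the solved stratum means with the complier-effect chain
#' shown step by step by both routes, (4) the bootstrap BCa interval table,
#' and (5) a run log recording seed, scheme, valid-replicate count and the
#' untestable identifying assumptions (no defiers, exclusion restriction,
#' outcomes missing completely at random).
#'
#' @param cohort a [trial_cohort()] (latent stratum labels, if present, are
#'   stripped before estimation).
#' @param n_replicates bootstrap replicates (>= 100 for interval estimation).
#' @param seed integer seed driving all resampling.
#' @param level nominal interval coverage in (0, 1).
#' @param scheme resampling scheme, see [bootstrap_estimates()].
#' @return A list of class `"cace_analysis"` with elements `crosstab`,
#'   `rates` (contrast + tests), `strata` (proportions, means, both
#'   estimates, equivalence difference), `intervals`, `log`.
#' @examples
#' cohort <- generate_cohort(reference_trial_config(seed = 11))
#' fit <- analyze(cohort, n_replicates = 200, seed = 11)
#' fit
#' @export
analyze <- function(cohort, n_replicates = 10000, seed, level = 0.95,
                    scheme = c("within_arm", "whole_cohort")) {
  scheme <- match.arg(scheme)
  stopifnot(n_replicates >= 100, level > 0, level < 1)
  cohort <- strip_strata(cohort)
  xtab <- cross_tab(cohort)
  if (any(xtab$n == 0)) {
    stop("strata stage requires all four arm x quit cells to be nonempty; ",
         "empty: ",
         paste(apply(which(xtab$n == 0, arr.ind = TRUE), 1L, function(i) {
           paste(rownames(xtab$n)[i[1L]], colnames(xtab$n)[i[2L]])
         }), collapse = ", "),
         call. = FALSE)
  }
  rates <- quit_rate_contrast(xtab)
  fisher <- fisher_exact_2x2(xtab$n["incentives", "quitter"],
                             xtab$n["incentives", "smoker"],
                             xtab$n["control", "quitter"],
                             xtab$n["control", "smoker"])
  t_arms <- two_sample_t_from_summary(
    xtab$arm_mean[["incentives"]], xtab$arm_sd[["incentives"]],
    xtab$arm_n[["incentives"]],
    xtab$arm_mean[["control"]], xtab$arm_sd[["control"]],
    xtab$arm_n[["control"]])
  nq <- sum(xtab$n[, "quitter"]); ns <- sum(xtab$n[, "smoker"])
  mq <- sum(xtab$n[, "quitter"] * xtab$mean[, "quitter"]) / nq
  ms <- sum(xtab$n[, "smoker"] * xtab$mean[, "smoker"]) / ns
  cc <- cohort[!is.na(cohort$birth_weight), , drop = FALSE]
  t_quit <- two_sample_t_from_summary(
    mq, stats::sd(cc$birth_weight[cc$quit == 1L]), nq,
    ms, stats::sd(cc$birth_weight[cc$quit == 0L]), ns)
  props <- strata_proportions(xtab)
  means <- solve_potential_quitter_means(props, observed_means(xtab))
  equiv <- equivalence_report(cohort)
  intervals <- subgroup_intervals(cohort, n_replicates, seed, level, scheme)
  boot <- attr(intervals, "draws")
  structure(list(
    crosstab = xtab,
    rates = list(contrast = rates, fisher = fisher, t_arms = t_arms,
                 t_quit_vs_smoke = t_quit,
                 quit_smoke_diff = mq - ms),
    strata = list(proportions = props, means = means,
                  intuitive = equiv$intuitive, wald = equiv$wald,
                  abs_difference = equiv$abs_difference,
                  expected_itt = props$p_pq * equiv$intuitive$point),
    intervals = intervals,
    log = list(seed = seed, scheme = scheme, level = level,
               n_replicates = n_replicates, n_valid = boot$n_valid,
               provenance = attr(cohort, "provenance"),
               assumptions = c(
                 "no defiers: nobody quits only when not offered incentives",
                 "exclusion restriction: randomization affects birth weight only through quitting",
                 "missing outcomes are missing completely at random (complete-case analysis)"))),
    class = "cace_analysis")
}

#' @export
print.cace_analysis <- function(x, ...) {
  cat("== 1. Birth weight by arm and quit status ==\n")
  print(x$crosstab)
  cat("\n== 2. Quit rates and hypothesis tests ==\n")
  print(x$rates$contrast)
  print(x$rates$fisher)
  cat("Between-arm birth weight: ")
  print(x$rates$t_arms)
  cat(sprintf("Quitters vs smokers (pooled arms): difference %.0f g, ",
              x$rates$quit_smoke_diff))
  print(x$rates$t_quit_vs_smoke)
  cat("\n== 3. Stratum proportions, means and complier effect ==\n")
  print(x$strata$proportions)
  print(x$strata$means)
  print(x$strata$intuitive)
  print(x$strata$wald)
  cat(sprintf("Route difference %.2e g; expected diluted (ITT) effect %.1f g\n",
              x$strata$abs_difference, x$strata$expected_itt))
  cat("\n== 4. Bootstrap BCa intervals ==\n")
  print(x$intervals)
  cat("\n== 5. Run log ==\n")
  cat(sprintf("  seed %d, %s scheme, %d replicates (%d valid), level %.2f\n",
              x$log$seed, x$log$scheme, x$log$n_replicates, x$log$n_valid,
              x$log$level))
  cat("  assumptions:\n")
  for (a in x$log$assumptions) cat("   -", a, "\n")
  invisible(x)
}

#' Write an analysis to disk
#'
#' Emits a plain-text report (the printed analysis, with full-precision
#' values alongside the rounded ones) plus machine-readable CSVs: the
#' cross-tab cells, the interval table, and a flat key-value file of every
#' estimate.
#'
#' @param x a `"cace_analysis"` from [analyze()].
#' @param dir output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "cace_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  sink(con)
  on.exit({ sink(); close(con) })
  print(x)
  cat("\nFull-precision key values:\n")
  kv <- analysis_keyvalues(x)
  for (nm in names(kv)) {
    cat(sprintf("  %-24s %.10g  (reported %s)\n", nm, kv[[nm]],
                format_reported(nm, kv[[nm]])))
  }
  sink(); close(con); on.exit()
  utils::write.csv(as.data.frame(x$crosstab),
                   file.path(dir, "crosstab.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(x$intervals)),
                   file.path(dir, "intervals.csv"), row.names = FALSE)
  utils::write.csv(data.frame(key = names(kv), value = unlist(kv)),
                   file.path(dir, "estimates.csv"), row.names = FALSE)
  invisible(dir)
}

analysis_keyvalues <- function(x) {
  list(quit_rate_incentives = x$rates$contrast$p1,
       quit_rate_control = x$rates$contrast$p0,
       quit_rate_diff = x$rates$contrast$diff,
       fisher_p = x$rates$fisher$p_value,
       t_arms_p = x$rates$t_arms$p_value,
       p_hs = x$strata$proportions$p_hs,
       p_iq = x$strata$proportions$p_iq,
       p_pq = x$strata$proportions$p_pq,
       w_hs = x$strata$means$w_hs,
       w_iq = x$strata$means$w_iq,
       w_pqs = x$strata$means$w_pqs,
       w_pqq = x$strata$means$w_pqq,
       cace_intuitive = x$strata$intuitive$point,
       cace_wald = x$strata$wald$point,
       expected_itt = x$strata$expected_itt)
}

# reporting convention: grams to the nearest integer, proportions to 3
# decimals, percentages to 1 decimal, half away from zero
format_reported <- function(name, value) {
  if (grepl("^(quit_rate|p_)", name)) {
    sprintf("%.3f (%.1f%%)", round_half_up(value, 3),
            round_half_up(100 * value, 1))
  } else if (grepl("_p$", name)) {
    sprintf("%.3g", value)
  } else {
    sprintf("%d g", as.integer(round_half_up(value)))
  }
}
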