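#' Construct a trial cohort
#'
#' Builds the individual-level data container used by every estimator: one
#' record per mother with her randomized arm, a biochemically validated quit
#' indicator, and infant birth weight in grams (missing allowed).  An optional
#' latent stratum label may be carried by synthetic cohorts for validation;
#' estimators never read it.
#'
#' @param arm character or factor with levels `"control"` and `"incentives"`.
#' @param quit binary quit indicator (0/1 or logical): cotinine-validated
#'   cessation at the primary outcome.
#' @param birth_weight numeric, grams; `NA` for missing.  Present values must
#'   be strictly positive and finite.
#' @param id optional record identifiers; defaults to row numbers.  Duplicate
#'   ids raise a warning but records are kept.
#' @param stratum optional latent labels in `{"HS","IQ","PQ"}` (hardened
#'   smoker / independent quitter / potential quitter), synthetic data only.
#' @param provenance free-text source tag.
#' @return A `data.frame` of class `"trial_cohort"` with columns `id`, `arm`,
#'   `quit`, `birth_weight` and optionally `stratum`.
#' @seealso [read_trial_csv()], [cross_tab()], [generate_cohort()]
#' @export
trial_cohort <- function(arm, quit, birth_weight, id = NULL, stratum = NULL,
                         provenance = "constructed") {
  arm <- as.character(arm)
  bad <- !arm %in% c("control", "incentives")
  if (any(bad)) {
    stop("unknown arm label(s) ", paste(unique(arm[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (is.logical(quit)) quit <- as.integer(quit)
  if (!all(quit %in% c(0L, 1L))) {
    stop("quit must be a 0/1 indicator", call. = FALSE)
  }
  birth_weight <- as.numeric(birth_weight)
  pres <- !is.na(birth_weight)
  if (any(pres & (birth_weight <= 0 | !is.finite(birth_weight)))) {
    stop("birth_weight must be strictly positive and finite when present; ",
         "offending row(s): ",
         paste(utils::head(which(pres & (birth_weight <= 0 |
                                           !is.finite(birth_weight))), 5L),
               collapse = ", "),
         call. = FALSE)
  }
  n <- length(arm)
  stopifnot(length(quit) == n, length(birth_weight) == n)
  if (is.null(id)) id <- as.character(seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    warning("duplicate record ids found; records kept", call. = FALSE)
  }
  out <- data.frame(id = id, arm = factor(arm, c("control", "incentives")),
                    quit = as.integer(quit), birth_weight = birth_weight,
                    stringsAsFactors = FALSE)
  if (!is.null(stratum)) {
    stratum <- as.character(stratum)
    stopifnot(all(is.na(stratum) | stratum %in% c("HS", "IQ", "PQ")))
    out$stratum <- stratum
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("trial_cohort", "data.frame")
  out
}

#' Read a trial cohort from delimited text
#'
#' Reads a CSV (UTF-8, header row) with one row per mother.  Column names are
#' configurable; missing birth weight may be encoded as an empty field or
#' `NA`, and is kept as absent — never as zero.
#'
#' @param path path to a CSV file.
#' @param columns named list mapping the canonical fields `id`, `arm`, `quit`,
#'   `birth_weight` (and optionally `stratum`) to the file's column names.
#' @param arm_labels named character vector translating the file's arm codes
#'   to the `control`/`incentives` enumeration, e.g.
#'   `c(control = "0", incentives = "1")`.  Defaults to the identity mapping.
#' @return A [trial_cohort()] with row order preserved.
#' @export
read_trial_csv <- function(path,
                           columns = list(id = "id", arm = "group",
                                          quit = "quit",
                                          birth_weight = "birthweight_g"),
                           arm_labels = c(control = "control",
                                          incentives = "incentives")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("arm", "quit", "birth_weight")
  for (f in need) {
    if (is.null(columns[[f]]) || !columns[[f]] %in% names(raw)) {
      stop("required column for '", f, "' not found in ", path, call. = FALSE)
    }
  }
  arm_raw <- as.character(raw[[columns$arm]])
  arm <- names(arm_labels)[match(arm_raw, arm_labels)]
  if (anyNA(arm)) {
    bad <- which(is.na(arm))
    stop("unknown arm label '", arm_raw[bad[1L]], "' at data row ", bad[1L],
         call. = FALSE)
  }
  id <- if (!is.null(columns$id) && columns$id %in% names(raw)) {
    raw[[columns$id]]
  } else {
    NULL
  }
  stratum <- if (!is.null(columns$stratum) &&
                 columns$stratum %in% names(raw)) {
    raw[[columns$stratum]]
  } else {
    NULL
  }
  trial_cohort(arm = arm, quit = raw[[columns$quit]],
               birth_weight = raw[[columns$birth_weight]], id = id,
               stratum = stratum, provenance = path)
}

#' Write a trial cohort as CSV
#'
#' Inverse of [read_trial_csv()] with the default column dialect.  The latent
#' stratum column of synthetic cohorts is included only on request.
#'
#' @param cohort a [trial_cohort()].
#' @param path output file path.
#' @param include_stratum keep the latent stratum column if present?
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(cohort, path, include_stratum = FALSE) {
  out <- data.frame(id = cohort$id, group = as.character(cohort$arm),
                    quit = cohort$quit, birthweight_g = cohort$birth_weight)
  if (include_stratum && !is.null(cohort$stratum)) out$stratum <- cohort$stratum
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Strip latent stratum labels from a cohort
#'
#' Estimators are defined on observed data only; this removes the synthetic
#' generator's latent labels so a cohort can be fed to the estimation chain
#' exactly as real trial data would be.
#'
#' @param cohort a [trial_cohort()].
#' @return The cohort without a `stratum` column.
#' @export
strip_strata <- function(cohort) {
  cohort$stratum <- NULL
  cohort
}

sample_sd <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_

#' Cross-tabulate birth weight by arm and quit status
#'
#' Computes the standard descriptive table for a two-arm cessation trial:
#' per-cell (arm x quit status) counts, mean and sample standard deviation of
#' birth weight, arm totals, the overall total, and the number of missing
#' outcomes per arm.  The analysis is complete-case: records with missing
#' birth weight are excluded from every cell and total and counted in
#' `n_missing`.
#'
#' @param cohort a [trial_cohort()] with at least one record.
#' @return An object of class `"trial_crosstab"`: a list with 2x2 matrices
#'   `n`, `mean`, `sd` (rows `control`/`incentives`, columns
#'   `smoker`/`quitter`), vectors `arm_n`, `arm_mean`, `arm_sd`, `n_missing`,
#'   and scalars `total_n`, `total_mean`, `total_sd`.
#' @examples
#' xt <- cross_tab(generate_cohort(reference_trial_config(seed = 1)))
#' xt
#' @export
cross_tab <- function(cohort) {
  stopifnot(inherits(cohort, "trial_cohort"), nrow(cohort) >= 1L)
  arms <- c("control", "incentives")
  stat <- c("smoker", "quitter")
  n <- mean_ <- sd_ <- matrix(NA_real_, 2L, 2L, dimnames = list(arms, stat))
  arm_n <- arm_mean <- arm_sd <- n_missing <-
    stats::setNames(numeric(2L), arms)
  cc <- !is.na(cohort$birth_weight)
  for (a in arms) {
    ina <- cohort$arm == a
    n_missing[a] <- sum(ina & !cc)
    for (q in 0:1) {
      w <- cohort$birth_weight[ina & cc & cohort$quit == q]
      cellname <- stat[q + 1L]
      n[a, cellname] <- length(w)
      mean_[a, cellname] <- if (length(w)) mean(w) else NA_real_
      sd_[a, cellname] <- sample_sd(w)
    }
    wa <- cohort$birth_weight[ina & cc]
    arm_n[a] <- length(wa)
    arm_mean[a] <- if (length(wa)) mean(wa) else NA_real_
    arm_sd[a] <- sample_sd(wa)
  }
  wall <- cohort$birth_weight[cc]
  structure(list(n = n, mean = mean_, sd = sd_, arm_n = arm_n,
                 arm_mean = arm_mean, arm_sd = arm_sd,
                 n_missing = n_missing, total_n = length(wall),
                 total_mean = if (length(wall)) mean(wall) else NA_real_,
                 total_sd = sample_sd(wall)),
            class = "trial_crosstab")
}

#' Build a cross-tab from published summary statistics
#'
#' Reconstructs the `"trial_crosstab"` container from printed per-cell counts,
#' means and standard deviations — the form in which trial reports publish
#' their birth weight breakdown — so the estimation chain can be run on a
#' published table without individual-level data.  Arm and overall totals are
#' derived as count-weighted means unless printed values are supplied (printed
#' values carry the source's own rounding).
#'
#' @param n,mean,sd 2x2 matrices with rows `control`, `incentives` and columns
#'   `smoker`, `quitter`.
#' @param arm_mean,arm_sd optional printed per-arm summaries (named vectors);
#'   derived from the cells when omitted (`arm_sd` then pooled exactly).
#' @param n_missing missing outcomes per arm, default zero.
#' @return A `"trial_crosstab"` as from [cross_tab()].
#' @export
crosstab_from_summary <- function(n, mean, sd, arm_mean = NULL, arm_sd = NULL,
                                  n_missing = c(control = 0, incentives = 0)) {
  arms <- c("control", "incentives")
  stat <- c("smoker", "quitter")
  n <- matrix(as.numeric(n), 2L, 2L, dimnames = list(arms, stat))
  mean <- matrix(as.numeric(mean), 2L, 2L, dimnames = list(arms, stat))
  sd <- matrix(as.numeric(sd), 2L, 2L, dimnames = list(arms, stat))
  arm_n <- rowSums(n)
  if (is.null(arm_mean)) arm_mean <- rowSums(n * mean) / arm_n
  arm_mean <- stats::setNames(as.numeric(arm_mean), arms)
  if (is.null(arm_sd)) {
    # exact pooling of within- and between-cell variation
    ss <- rowSums((n - 1) * sd^2 + n * (mean - arm_mean)^2, na.rm = TRUE)
    arm_sd <- sqrt(ss / (arm_n - 1))
  }
  arm_sd <- stats::setNames(as.numeric(arm_sd), arms)
  total_n <- sum(arm_n)
  total_mean <- sum(arm_n * arm_mean) / total_n
  ss_tot <- sum((arm_n - 1) * arm_sd^2 + arm_n * (arm_mean - total_mean)^2)
  structure(list(n = n, mean = mean, sd = sd, arm_n = arm_n,
                 arm_mean = arm_mean, arm_sd = arm_sd,
                 n_missing = stats::setNames(as.numeric(n_missing), arms),
                 total_n = total_n, total_mean = total_mean,
                 total_sd = sqrt(ss_tot / (total_n - 1))),
            class = "trial_crosstab")
}

#' Published summary table of the motivating incentive trial
#'
#' The birth weight breakdown, by randomized group and validated cessation
#' status, printed in the report of a single-centre trial that offered
#' pregnant smokers financial voucher incentives for biochemically verified
#' quitting: 582 analyzable mother/baby pairs (25 birth weights missing from
#' routine records).  Printed per-arm means and SDs are retained alongside the
#' cells.
#'
#' @return A `"trial_crosstab"` holding the published summary statistics.
#' @examples
#' xt <- incentive_trial_table()
#' cace_wald(xt)
#' @export
incentive_trial_table <- function() {
  crosstab_from_summary(
    n    = rbind(control = c(smoker = 262, quitter = 25),
                 incentives = c(smoker = 227, quitter = 68)),
    mean = rbind(control = c(3075, 3586), incentives = c(3053, 3432)),
    sd   = rbind(control = c(569, 566), incentives = c(588, 527)),
    arm_mean = c(control = 3120, incentives = 3141),
    arm_sd = c(control = 586, incentives = 595),
    n_missing = c(control = 16, incentives = 9)
  )
}

#' @export
print.trial_crosstab <- function(x, ...) {
  cat("Birth weight (g) by randomized group and quit status",
      "(complete case)\n\n")
  fmt <- function(a, s) {
    if (x$n[a, s] == 0) return("  -")
    sprintf("N=%d %s (%s)", x$n[a, s], round_half_up(x$mean[a, s]),
            ifelse(is.na(x$sd[a, s]), "-", round_half_up(x$sd[a, s])))
  }
  for (a in rownames(x$n)) {
    cat(sprintf("  %-10s smoker: %-22s quitter: %-22s all: N=%d %s (%s)\n",
                a, fmt(a, "smoker"), fmt(a, "quitter"), x$arm_n[[a]],
                round_half_up(x$arm_mean[[a]]),
                round_half_up(x$arm_sd[[a]])))
  }
  cat(sprintf("  %-10s N=%d mean %s (SD %s); missing: %d control, %d incentives\n",
              "overall", x$total_n, round_half_up(x$total_mean),
              round_half_up(x$total_sd), x$n_missing[["control"]],
              x$n_missing[["incentives"]]))
  invisible(x)
}

#' @export
as.data.frame.trial_crosstab <- function(x, ...) {
  cells <- expand.grid(arm = rownames(x$n), status = colnames(x$n),
                       stringsAsFactors = FALSE)
  cells$n <- x$n[cbind(cells$arm, cells$status)]
  cells$mean <- x$mean[cbind(cells$arm, cells$status)]
  cells$sd <- x$sd[cbind(cells$arm, cells$status)]
  cells
}

#' Quit-rate contrast between arms
#'
#' The intention-to-treat compliance contrast: validated quit proportions per
#' arm on complete-case denominators, and their difference — the compliance
#' gap that identifies the complier stratum under monotonicity.
#'
#' @param xtab a `"trial_crosstab"`.
#' @return A list of class `"rate_contrast"`: `p1` (incentives), `p0`
#'   (control), `diff = p1 - p0`, and the underlying counts.
#' @export
quit_rate_contrast <- function(xtab) {
  stopifnot(inherits(xtab, "trial_crosstab"))
  if (any(xtab$arm_n == 0)) {
    stop("an arm has no analyzable records", call. = FALSE)
  }
  p0 <- xtab$n["control", "quitter"] / xtab$arm_n[["control"]]
  p1 <- xtab$n["incentives", "quitter"] / xtab$arm_n[["incentives"]]
  structure(list(p1 = p1, p0 = p0, diff = p1 - p0,
                 x1 = xtab$n["incentives", "quitter"],
                 n1 = xtab$arm_n[["incentives"]],
                 x0 = xtab$n["control", "quitter"],
                 n0 = xtab$arm_n[["control"]]),
            class = "rate_contrast")
}

#' @export
print.rate_contrast <- function(x, ...) {
  cat(sprintf("Quit rates: incentives %d/%d = %.1f%%, control %d/%d = %.1f%%, difference %.1f%%\n",
              x$x1, x$n1, 100 * x$p1, x$x0, x$n0, 100 * x$p0, 100 * x$diff))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of association between arm and quit status, with the
#' p value defined as the sum of hypergeometric probabilities of tables (at
#' the observed margins) no more probable than the observed one.
#'
#' @param a,b,c,d nonnegative cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return A list of class `"trial_test"` with `statistic` (odds ratio
#'   estimate), `p_value`, `method = "fisher_exact"`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero table", call. = FALSE)
  ft <- stats::fisher.test(matrix(counts, 2L, 2L, byrow = TRUE))
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 method = "fisher_exact", df = NA_real_),
            class = "trial_test")
}

#' Two-sample t test from summary statistics
#'
#' Compares two group means given only (mean, SD, n) — the form available
#' from a published table.  Welch's unequal-variance statistic with
#' Welch–Satterthwaite degrees of freedom is the default; the pooled-variance
#' test is available via `var_equal = TRUE`.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @param var_equal use the pooled-variance statistic?
#' @return A `"trial_test"` with `statistic`, `df`, `p_value` and `method`.
#'   Degenerate zero-variance inputs return p = 1 when the means are equal
#'   and p = 0 otherwise (with a warning).
#' @export
two_sample_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                      var_equal = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    warning("both groups have zero variance; p value by convention",
            call. = FALSE)
    eq <- isTRUE(all.equal(mean1, mean2))
    return(structure(list(statistic = if (eq) 0 else Inf,
                          p_value = if (eq) 1 else 0,
                          method = if (var_equal) "pooled_t" else "welch_t",
                          df = NA_real_),
                     class = "trial_test"))
  }
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    method <- "pooled_t"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "welch_t"
  }
  t <- (mean1 - mean2) / se
  structure(list(statistic = t, p_value = 2 * stats::pt(-abs(t), df),
                 method = method, df = df),
            class = "trial_test")
}

#' @export
print.trial_test <- function(x, ...) {
  if (x$method == "fisher_exact") {
    cat(sprintf("Fisher exact test: OR = %.3f, p = %.3g\n", x$statistic,
                x$p_value))
  } else {
    cat(sprintf("%s: t = %.3f, df = %.1f, p = %.3g\n",
                if (x$method == "welch_t") "Welch t test" else "Pooled t test",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

# round half away from zero, the reporting convention for grams/percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
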