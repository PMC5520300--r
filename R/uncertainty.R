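#' Bootstrap the full estimator chain
#'
#' Resamples trial records with replacement and recomputes, for each
#' replicate, the complete estimation chain: the two directly observed
#' stratum means (hardened smokers `w_hs`, independent quitters `w_iq`), the
#' two solved potential-quitter means (`w_pqq`, `w_pqs`) and the complier
#' effect `cace`.  Replicates whose compliance gap is not positive (below
#' `1e-6`), or in which a needed cell comes up empty, are counted invalid and
#' excluded from the stored draws — the ratio estimator is undefined there.
#'
#' @param cohort a [trial_cohort()] on which the chain is estimable.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed; identical `(cohort, seed, scheme, n_replicates)`
#'   give bit-identical draws.
#' @param scheme `"within_arm"` (default) resamples within each arm,
#'   preserving arm sizes; `"whole_cohort"` resamples the pooled records, so
#'   arm sizes vary across replicates.
#' @return A list of class `"bootstrap_draws"`: `draws` (matrix, one row per
#'   valid replicate, columns `w_hs, w_iq, w_pqq, w_pqs, cace`),
#'   `n_replicates`, `n_valid`, `seed`, `scheme`, and `point` (the full-data
#'   estimates).
#' @export
bootstrap_estimates <- function(cohort, n_replicates, seed,
                                scheme = c("within_arm", "whole_cohort")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cohort, "trial_cohort"), n_replicates >= 1)
  cc <- cohort[!is.na(cohort$birth_weight), , drop = FALSE]
  inc <- cc$arm == "incentives"
  quit <- cc$quit == 1L
  w <- cc$birth_weight
  n <- length(w)
  point <- chain_estimates(inc, quit, w)
  if (!is.finite(point[["cace"]])) {
    stop("estimator chain is not estimable on the full cohort", call. = FALSE)
  }
  i_ctl <- which(!inc)
  i_inc <- which(inc)
  draws <- matrix(NA_real_, n_replicates, 5L,
                  dimnames = list(NULL, c("w_hs", "w_iq", "w_pqq", "w_pqs",
                                          "cace")))
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    idx <- if (scheme == "within_arm") {
      c(i_ctl[sample.int(length(i_ctl), replace = TRUE)],
        i_inc[sample.int(length(i_inc), replace = TRUE)])
    } else {
      sample.int(n, replace = TRUE)
    }
    est <- chain_estimates(inc[idx], quit[idx], w[idx])
    if (is.finite(est[["cace"]])) draws[b, ] <- est[1:5]
  }
  valid <- is.finite(draws[, "cace"])
  if (!any(valid)) {
    stop("no valid bootstrap replicates; use a larger cohort or the ",
         "within_arm scheme", call. = FALSE)
  }
  structure(list(draws = draws[valid, , drop = FALSE],
                 n_replicates = n_replicates, n_valid = sum(valid),
                 seed = seed, scheme = scheme, point = point[1:5]),
            class = "bootstrap_draws")
}

#' @export
print.bootstrap_draws <- function(x, ...) {
  cat(sprintf("Bootstrap draws: %d requested, %d valid (%s scheme, seed %d)\n",
              x$n_replicates, x$n_valid, x$scheme, x$seed))
  print(round(apply(x$draws, 2L, stats::quantile,
                    probs = c(0.025, 0.5, 0.975)), 1))
  invisible(x)
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' Computes a BCa interval from bootstrap draws of a statistic.  The bias
#' correction `z0` is the normal quantile of the fraction of draws below the
#' point estimate; the acceleration `a` comes from the jackknife skewness
#' \deqn{a = \sum_i (\bar\theta - \theta_{(i)})^3 \big/
#'        6 \left[\sum_i (\bar\theta - \theta_{(i)})^2\right]^{3/2},}
#' and the nominal quantiles are remapped to
#' \deqn{\alpha' = \Phi\!\left(z_0 + \frac{z_0 + z_\alpha}
#'        {1 - a (z_0 + z_\alpha)}\right)}
#' before reading off empirical quantiles of the draws.  Adjusted quantile
#' levels are clipped to `[1/(B+1), B/(B+1)]`; a fraction-below of exactly 0
#' or 1 is clamped to that bound with a warning.  Identical draws yield a
#' zero-width interval.
#'
#' @param draws numeric vector of bootstrap replicate values (valid draws
#'   only).
#' @param point the full-data point estimate.
#' @param jackknife_values leave-one-out estimates of the same statistic.
#' @param level nominal two-sided coverage in (0, 1).
#' @return A list of class `"bca_interval"`: `lower`, `upper`, `level`, `z0`,
#'   `a`, `n_valid`.
#' @references Efron, B. (1987) Better bootstrap confidence intervals.
#'   JASA 82, 171-185.
#' @export
bca_interval <- function(draws, point, jackknife_values, level = 0.95) {
  stopifnot(level > 0, level < 1, length(draws) >= 1)
  B <- length(draws)
  if (max(draws) == min(draws)) {
    return(structure(list(lower = draws[1L], upper = draws[1L],
                          level = level, z0 = 0, a = 0, n_valid = B),
                     class = "bca_interval"))
  }
  clip <- c(1 / (B + 1), B / (B + 1))
  frac <- mean(draws < point)
  if (frac == 0 || frac == 1) {
    warning("all bootstrap draws on one side of the point estimate; ",
            "bias correction clamped", call. = FALSE)
    frac <- if (frac == 0) clip[1L] else clip[2L]
  }
  z0 <- stats::qnorm(frac)
  jk <- jackknife_values[is.finite(jackknife_values)]
  d <- mean(jk) - jk
  denom <- sum(d^2)
  a <- if (denom > 0) sum(d^3) / (6 * denom^1.5) else 0
  zq <- stats::qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  adj <- pmin(pmax(adj, clip[1L]), clip[2L])
  ends <- unname(stats::quantile(draws, adj, names = FALSE, type = 7))
  structure(list(lower = ends[1L], upper = ends[2L], level = level, z0 = z0,
                 a = a, n_valid = B),
            class = "bca_interval")
}

#' @export
print.bca_interval <- function(x, ...) {
  cat(sprintf("%.0f%% BCa interval: [%.1f, %.1f]  (z0 = %.3f, a = %.4f, B = %d)\n",
              100 * x$level, x$lower, x$upper, x$z0, x$a, x$n_valid))
  invisible(x)
}

# Leave-one-record-out estimates of the chain over analyzable records,
# computed in O(n) total by adjusting cell counts and sums rather than
# re-scanning the cohort for each deletion.
jackknife_chain <- function(inc, quit, w, tol = 1e-6) {
  keep <- !is.na(w)
  inc <- inc[keep]; quit <- quit[keep]; w <- w[keep]
  n <- length(w)
  cell <- 1L + inc * 2L + quit  # 1 ctl-smoker, 2 ctl-quitter, 3 inc-smoker, 4 inc-quitter
  n_cell <- tabulate(cell, 4L)
  s_cell <- c(sum(w[cell == 1L]), sum(w[cell == 2L]),
              sum(w[cell == 3L]), sum(w[cell == 4L]))
  # per-record adjusted cell counts/sums: own cell loses (1, w_i)
  nmat <- matrix(n_cell, n, 4L, byrow = TRUE)
  smat <- matrix(s_cell, n, 4L, byrow = TRUE)
  pick <- cbind(seq_len(n), cell)
  nmat[pick] <- nmat[pick] - 1L
  smat[pick] <- smat[pick] - w
  nc <- nmat[, 1L] + nmat[, 2L]
  ni <- nmat[, 3L] + nmat[, 4L]
  p_hs <- nmat[, 3L] / ni
  p_iq <- nmat[, 2L] / nc
  p_pq <- 1 - p_hs - p_iq
  w_hs <- smat[, 3L] / nmat[, 3L]
  w_iq <- smat[, 2L] / nmat[, 2L]
  w1 <- smat[, 4L] / nmat[, 4L]
  w0 <- smat[, 1L] / nmat[, 1L]
  w_pqq <- (w1 * (p_iq + p_pq) - p_iq * w_iq) / p_pq
  w_pqs <- (w0 * (p_hs + p_pq) - p_hs * w_hs) / p_pq
  bad <- !(p_pq > tol) | nmat[, 1L] == 0L | nmat[, 2L] == 0L |
    nmat[, 3L] == 0L | nmat[, 4L] == 0L
  w_pqq[bad] <- NA_real_
  w_pqs[bad] <- NA_real_
  cbind(w_hs = w_hs, w_iq = w_iq, w_pqq = w_pqq, w_pqs = w_pqs,
        cace = w_pqq - w_pqs)
}

#' BCa intervals for all stratum means and the complier effect
#'
#' One bootstrap and one jackknife pass give point estimates and BCa
#' intervals for the four stratum mean birth weights and the complier
#' effect.  Rows are ordered by the expected birth weight gradient across
#' strata: hardened smokers, potential quitters without the offer, potential
#' quitters with the offer, independent quitters, then the complier effect.
#'
#' @inheritParams bootstrap_estimates
#' @param level nominal coverage of each interval.
#' @return A `data.frame` of class `"subgroup_intervals"` with columns
#'   `quantity`, `point`, `lower`, `upper`, `level`, `n_valid`, `z0`, `a`;
#'   attribute `draws` holds the underlying `"bootstrap_draws"`.
#' @examples
#' cohort <- generate_cohort(reference_trial_config(seed = 7))
#' subgroup_intervals(cohort, n_replicates = 200, seed = 7)
#' @export
subgroup_intervals <- function(cohort, n_replicates = 10000, seed,
                               level = 0.95,
                               scheme = c("within_arm", "whole_cohort")) {
  scheme <- match.arg(scheme)
  boot <- bootstrap_estimates(cohort, n_replicates, seed, scheme)
  cc <- cohort[!is.na(cohort$birth_weight), , drop = FALSE]
  jack <- jackknife_chain(cc$arm == "incentives", cc$quit == 1L,
                          cc$birth_weight)
  order_q <- c("w_hs", "w_pqs", "w_pqq", "w_iq", "cace")
  rows <- lapply(order_q, function(q) {
    ci <- bca_interval(boot$draws[, q], boot$point[[q]], jack[, q], level)
    data.frame(quantity = q, point = boot$point[[q]], lower = ci$lower,
               upper = ci$upper, level = level, n_valid = ci$n_valid,
               z0 = ci$z0, a = ci$a)
  })
  out <- do.call(rbind, rows)
  attr(out, "draws") <- boot
  class(out) <- c("subgroup_intervals", "data.frame")
  out
}

#' @export
print.subgroup_intervals <- function(x, ...) {
  labels <- c(w_hs = "hardened smokers",
              w_pqs = "potential quitters, no offer",
              w_pqq = "potential quitters, offered",
              w_iq = "independent quitters",
              cace = "complier effect (CACE)")
  boot <- attr(x, "draws")
  cat(sprintf("Bootstrap BCa intervals (%d/%d valid replicates, %s scheme, seed %d)\n",
              boot$n_valid, boot$n_replicates, boot$scheme, boot$seed))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-30s %8.1f  [%8.1f, %8.1f]  %.0f%%\n",
                labels[[x$quantity[i]]], x$point[i], x$lower[i], x$upper[i],
                100 * x$level[i]))
  }
  invisible(x)
}
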