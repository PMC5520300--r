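# Shared fixtures, all built in code.

# Published summary table of the motivating trial, as cell counts.
table1_counts <- list(
  n = rbind(control = c(smoker = 262, quitter = 25),
            incentives = c(smoker = 227, quitter = 68)),
  mean = rbind(control = c(smoker = 3075, quitter = 3586),
               incentives = c(smoker = 3053, quitter = 3432)),
  sd = rbind(control = c(smoker = 569, quitter = 566),
             incentives = c(smoker = 588, quitter = 527))
)

# Build n records with an exact sample mean and (n-1)-denominator SD.
cell_records <- function(n, mean, sd) {
  if (n == 1L) return(mean)
  z <- scale(seq_len(n))[, 1L]  # mean 0, sample sd 1
  mean + sd * z
}

# Individual-level cohort whose cross-tab reproduces the published cells
# exactly (arm/overall totals then follow by weighted reconstruction).
table1_cohort <- function() {
  args <- list()
  for (a in c("control", "incentives")) {
    for (s in c("smoker", "quitter")) {
      w <- cell_records(table1_counts$n[a, s], table1_counts$mean[a, s],
                        table1_counts$sd[a, s])
      args[[paste(a, s)]] <- data.frame(arm = a,
                                        quit = as.integer(s == "quitter"),
                                        w = w)
    }
  }
  d <- do.call(rbind, args)
  trial_cohort(arm = d$arm, quit = d$quit, birth_weight = d$w,
               provenance = "reconstructed from published cells")
}

# Small random cohort with all four arm x quit cells guaranteed nonempty.
rand_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  base <- data.frame(
    arm = c("control", "control", "incentives", "incentives"),
    quit = c(0L, 1L, 0L, 1L))
  arm <- sample(c("control", "incentives"), n - 4L, replace = TRUE)
  extra <- data.frame(
    arm = arm,
    quit = rbinom(n - 4L, 1L, ifelse(arm == "incentives", 0.45, 0.15)))
  d <- rbind(base, extra)
  trial_cohort(arm = d$arm, quit = d$quit,
               birth_weight = stats::rnorm(n, 3200, 500),
               provenance = "random test cohort")
}

# Six-record toy cohort for exhaustive bootstrap enumeration.
toy6_cohort <- function() {
  trial_cohort(
    arm = c("control", "control", "control", "incentives", "incentives",
            "incentives"),
    quit = c(0L, 0L, 1L, 0L, 1L, 1L),
    birth_weight = c(3000, 3100, 3500, 2900, 3050, 3400))
}
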