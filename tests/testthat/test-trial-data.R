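test_that("read_trial_csv parses rows, preserves order, keeps missing absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,quit,birthweight_g",
               "a,control,0,3000",
               "b,incentives,1,",
               "c,control,0,3100"), path)
  cohort <- read_trial_csv(path)
  expect_s3_class(cohort, "trial_cohort")
  expect_equal(nrow(cohort), 3L)
  expect_equal(cohort$id, c("a", "b", "c"))
  expect_equal(as.character(cohort$arm),
               c("control", "incentives", "control"))
  expect_identical(cohort$birth_weight, c(3000, NA, 3100))
})

test_that("read_trial_csv rejects bad arms and nonpositive weights, warns on dup ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,quit,birthweight_g",
               "a,control,0,3000",
               "b,placebo,1,3200"), path)
  expect_error(read_trial_csv(path), "placebo.*row 2")

  writeLines(c("id,group,quit,birthweight_g",
               "a,control,0,-5"), path)
  expect_error(read_trial_csv(path), "positive")

  writeLines(c("id,group,quit,birthweight_g",
               "a,control,0,3000",
               "a,incentives,1,3200"), path)
  expect_warning(cohort <- read_trial_csv(path), "duplicate")
  expect_equal(nrow(cohort), 2L)
})

test_that("write_trial_csv / read_trial_csv round-trip a synthetic cohort", {
  cohort <- generate_cohort(reference_trial_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(cohort, path, include_stratum = TRUE)
  back <- read_trial_csv(path, columns = list(id = "id", arm = "group",
                                              quit = "quit",
                                              birth_weight = "birthweight_g",
                                              stratum = "stratum"))
  expect_equal(nrow(back), 607L)
  expect_equal(back$birth_weight, cohort$birth_weight)
  expect_equal(back$stratum, cohort$stratum)
  n_missing <- sum(is.na(back$birth_weight))
  expect_equal(nrow(back) - n_missing,
               sum(cross_tab(back)$arm_n))
})

test_that("cross_tab reproduces published cell and total moments", {
  xt <- cross_tab(table1_cohort())
  expect_equal(xt$n, table1_counts$n)
  expect_equal(unname(xt$mean), unname(table1_counts$mean), tolerance = 1e-9)
  expect_equal(unname(xt$sd), unname(table1_counts$sd), tolerance = 1e-9)
  expect_equal(xt$total_n, 582)
  expect_equal(round(xt$total_mean), 3130)
  expect_equal(xt$total_sd, 590, tolerance = 0.005)
})

test_that("cross_tab weighted-mean reconstruction holds on random cohorts", {
  for (seed in 1:20) {
    cohort <- rand_cohort(n = 30 + seed, seed = seed)
    xt <- cross_tab(cohort)
    for (a in c("control", "incentives")) {
      expect_equal(sum(xt$n[a, ] * xt$mean[a, ]) / xt$arm_n[[a]],
                   xt$arm_mean[[a]], tolerance = 1e-9)
    }
    expect_equal(sum(xt$arm_n * xt$arm_mean) / xt$total_n, xt$total_mean,
                 tolerance = 1e-9)
    expect_equal(sum(xt$n), xt$total_n)
  }
})

test_that("cross_tab handles degenerate cells", {
  cohort <- trial_cohort(arm = "control", quit = 1L, birth_weight = 3100)
  xt <- cross_tab(cohort)
  expect_equal(xt$n["control", "quitter"], 1)
  expect_true(is.na(xt$sd["control", "quitter"]))
  expect_equal(xt$n["incentives", "smoker"], 0)
  expect_true(is.na(xt$mean["incentives", "smoker"]))
})

test_that("quit_rate_contrast matches published rates and edge cases", {
  xt <- cross_tab(table1_cohort())
  rc <- quit_rate_contrast(xt)
  expect_equal(rc$p1, 68 / 295, tolerance = 1e-12)
  expect_equal(rc$p0, 25 / 287, tolerance = 1e-12)
  expect_equal(rc$diff, rc$p1 - rc$p0)
  expect_equal(round(100 * c(rc$p1, rc$p0, rc$diff), 1), c(23.1, 8.7, 14.3))

  sym <- trial_cohort(arm = rep(c("control", "incentives"), each = 10),
                      quit = rep(c(0L, 1L), 10),
                      birth_weight = rnorm(20, 3000, 100))
  expect_equal(quit_rate_contrast(cross_tab(sym))$diff, 0)

  ext <- trial_cohort(arm = rep(c("control", "incentives"), each = 10),
                      quit = rep(c(0L, 1L), each = 10),
                      birth_weight = rnorm(20, 3000, 100))
  expect_equal(quit_rate_contrast(cross_tab(ext))$diff, 1)
})

test_that("fisher_exact_2x2 matches a hypergeometric enumeration oracle", {
  fisher_oracle <- function(a, b, c, d) {
    # sum of probabilities of all tables at the observed margins that are
    # no more probable than the observed table
    r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
    xs <- max(0, c1 - r2):min(r1, c1)
    pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
    sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
  }
  set.seed(99)
  tabs <- rbind(c(5, 5, 5, 5), c(0, 10, 10, 0), c(1, 0, 0, 1),
                c(3, 7, 9, 2), c(12, 8, 4, 16),
                matrix(sample(0:10, 4 * 40, replace = TRUE), ncol = 4))
  tabs <- tabs[rowSums(tabs) > 0, , drop = FALSE]
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4])$p_value,
                 fisher_oracle(t[1], t[2], t[3], t[4]), tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("two_sample_t_from_summary matches t.test and is symmetric", {
  set.seed(7)
  x <- rnorm(25, 3100, 400)
  y <- rnorm(31, 3300, 500)
  ours <- two_sample_t_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 31)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  pooled <- two_sample_t_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 31,
                                      var_equal = TRUE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$p_value, refp$p.value, tolerance = 1e-12)

  swap <- two_sample_t_from_summary(mean(y), sd(y), 31, mean(x), sd(x), 25)
  expect_equal(swap$statistic, -ours$statistic)
  expect_equal(swap$p_value, ours$p_value)

  same <- two_sample_t_from_summary(3000, 100, 10, 3000, 100, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(deg <- two_sample_t_from_summary(3000, 0, 5, 3000, 0, 5))
  expect_equal(deg$p_value, 1)
})

test_that("published arm summaries give the reported t tests", {
  arms <- two_sample_t_from_summary(3141, 595, 295, 3120, 586, 287)
  expect_equal(arms$p_value, 0.67, tolerance = 0.005)
  qs <- two_sample_t_from_summary(3473, 539, 93, 3065, 577, 489)
  expect_lt(qs$p_value, 1e-4)
})
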