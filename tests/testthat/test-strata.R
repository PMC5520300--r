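# Frozen chain values computed from the published cell counts/means with
# exact fractions P_HS = 227/295, P_IQ = 25/287:
#   W_PQQ = (3432 (P_IQ+P_PQ) - P_IQ 3586) / P_PQ = 3338.453340
#   W_PQS = (3075 (P_HS+P_PQ) - P_HS 3053) / P_PQ = 3193.052714
#   CACE  = 145.4006260

test_that("stratum proportions from the published counts", {
  props <- strata_proportions(cross_tab(table1_cohort()))
  expect_true(props$valid)
  expect_equal(props$p_hs, 227 / 295, tolerance = 1e-12)
  expect_equal(props$p_iq, 25 / 287, tolerance = 1e-12)
  expect_equal(props$p_hs + props$p_iq + props$p_pq, 1, tolerance = 1e-12)
  expect_equal(round(c(props$p_hs, props$p_iq, props$p_pq), 3),
               c(0.769, 0.087, 0.143))
  expect_equal(props$p_defier, 0)
})

test_that("identical quit rates give a flagged-invalid zero complier proportion", {
  cohort <- trial_cohort(arm = rep(c("control", "incentives"), each = 10),
                         quit = rep(c(0L, 0L, 0L, 0L, 1L), 4),
                         birth_weight = rnorm(20, 3200, 300))
  props <- strata_proportions(cross_tab(cohort))
  expect_equal(props$p_pq, 0, tolerance = 1e-12)
  expect_false(props$valid)
  means <- solve_potential_quitter_means(props,
                                         observed_means(cross_tab(cohort)))
  expect_false(means$valid)
  expect_true(is.na(means$w_pqq))
  est <- cace_intuitive(means)
  expect_false(est$valid)
})

test_that("all-complier limit: control all smoke, incentives all quit", {
  cohort <- trial_cohort(arm = rep(c("control", "incentives"), each = 6),
                         quit = rep(c(0L, 1L), each = 6),
                         birth_weight = rnorm(12, 3200, 300))
  props <- strata_proportions(cross_tab(cohort))
  expect_equal(props$p_pq, 1)
})

test_that("observed means read the right cells", {
  xt <- cross_tab(table1_cohort())
  cm <- observed_means(xt)
  expect_equal(cm$w_hs, 3053, tolerance = 1e-9)
  expect_equal(cm$w_iq, 3586, tolerance = 1e-9)
  expect_equal(cm$w0, 3075, tolerance = 1e-9)
  expect_equal(cm$w1, 3432, tolerance = 1e-9)
  expect_equal(round(cm$mu0), 3120)
  expect_equal(round(cm$mu1), 3140)  # weighted cell means; source printed 3141

  const <- trial_cohort(arm = rep(c("control", "incentives"), each = 4),
                        quit = rep(c(0L, 1L), 4),
                        birth_weight = rep(3000, 8))
  cmc <- observed_means(cross_tab(const))
  expect_true(all(unlist(cmc) == 3000))

  one_arm <- trial_cohort(arm = rep("control", 4), quit = c(0L, 0L, 1L, 1L),
                          birth_weight = rnorm(4, 3000, 100))
  expect_error(observed_means(cross_tab(one_arm)), "empty cell")
})

test_that("observed means match a direct per-cell averaging oracle", {
  cohort <- rand_cohort(n = 60, seed = 3)
  cm <- observed_means(cross_tab(cohort))
  avg <- function(a, q) {
    mean(cohort$birth_weight[cohort$arm == a & cohort$quit == q])
  }
  expect_equal(cm$w_hs, avg("incentives", 0), tolerance = 1e-12)
  expect_equal(cm$w_iq, avg("control", 1), tolerance = 1e-12)
  expect_equal(cm$w1, avg("incentives", 1), tolerance = 1e-12)
  expect_equal(cm$w0, avg("control", 0), tolerance = 1e-12)
})

test_that("the published chain solves to the reported stratum means and effect", {
  xt <- cross_tab(table1_cohort())
  props <- strata_proportions(xt)
  means <- solve_potential_quitter_means(props, observed_means(xt))
  expect_equal(means$w_pqq, 3338.453340, tolerance = 1e-8)
  expect_equal(means$w_pqs, 3193.052714, tolerance = 1e-8)
  est <- cace_intuitive(means, props)
  expect_equal(est$point, 145.4006260, tolerance = 1e-8)
  expect_equal(est$method, "intuitive")
})

test_that("no-mixing limits collapse the inversion to the observed cell", {
  cells <- structure(list(w0 = 3100, w1 = 3400, mu0 = 3150, mu1 = 3200,
                          w_hs = 3050, w_iq = 3550),
                     class = "observed_cell_means")
  no_iq <- structure(list(p_hs = 0.8, p_iq = 0, p_pq = 0.2, p_defier = 0,
                          valid = TRUE), class = "strata_proportions")
  m <- solve_potential_quitter_means(no_iq, cells)
  expect_equal(m$w_pqq, cells$w1)
  no_hs <- structure(list(p_hs = 0, p_iq = 0.8, p_pq = 0.2, p_defier = 0,
                          valid = TRUE), class = "strata_proportions")
  m2 <- solve_potential_quitter_means(no_hs, cells)
  expect_equal(m2$w_pqs, cells$w0)
})

test_that("mixture-consistency identities hold by construction", {
  for (seed in 1:10) {
    xt <- cross_tab(rand_cohort(n = 50, seed = seed))
    props <- strata_proportions(xt)
    if (!props$valid) next
    cells <- observed_means(xt)
    m <- solve_potential_quitter_means(props, cells)
    expect_equal(props$p_iq * m$w_iq + props$p_pq * m$w_pqq,
                 (props$p_iq + props$p_pq) * cells$w1, tolerance = 1e-9)
    expect_equal(props$p_hs * m$w_hs + props$p_pq * m$w_pqs,
                 (props$p_hs + props$p_pq) * cells$w0, tolerance = 1e-9)
  }
})

test_that("inversion and Wald ratio agree on any individual-level cohort", {
  n_checked <- 0L
  for (seed in 1:200) {
    cohort <- rand_cohort(n = 40, seed = seed)
    rep <- equivalence_report(cohort)
    if (!rep$proportions$valid) next
    n_checked <- n_checked + 1L
    expect_equal(rep$intuitive$point, rep$wald$point,
                 tolerance = 1e-9)
    expect_true(rep$identical_to_1e6)
  }
  expect_gt(n_checked, 100L)
})

test_that("equivalence_report propagates invalid estimates", {
  cohort <- trial_cohort(arm = rep(c("control", "incentives"), each = 10),
                         quit = rep(c(0L, 0L, 0L, 0L, 1L), 4),
                         birth_weight = rnorm(20, 3200, 300))
  rep <- equivalence_report(cohort)
  expect_false(rep$intuitive$valid)
  expect_false(rep$wald$valid)
  expect_true(is.na(rep$abs_difference))
})

test_that("null intention-to-treat difference gives a zero Wald estimate", {
  cohort <- rand_cohort(n = 60, seed = 11)
  xt <- cross_tab(cohort)
  xt$arm_mean[] <- c(3200, 3200)
  est <- cace_wald(xt)
  expect_equal(est$point, 0)
})

test_that("large-n synthetic cohorts recover the latent stratum means", {
  cfg <- cohort_config(n_per_arm = c(2e6, 2e6),
                       stratum_probs = c(0.77, 0.087, 0.143),
                       stratum_means = c(3053, 3586, 3193),
                       complier_effect = 100,
                       stratum_sds = c(588, 566, 570),
                       missing_rate = 0, seed = 42)
  cohort <- generate_cohort(cfg)
  xt <- cross_tab(strip_strata(cohort))
  m <- solve_potential_quitter_means(strata_proportions(xt),
                                     observed_means(xt))
  truth_pqs <- mean(cohort$birth_weight[cohort$stratum == "PQ" &
                                          cohort$arm == "control"])
  truth_pqq <- mean(cohort$birth_weight[cohort$stratum == "PQ" &
                                          cohort$arm == "incentives"])
  expect_equal(m$w_pqs, truth_pqs, tolerance = 0.01)
  expect_equal(m$w_pqq, truth_pqq, tolerance = 0.01)
  est <- cace_intuitive(m)
  expect_lt(abs(est$point - 100), 10)
  # stratum ordering: hardened smokers lowest, independent quitters highest
  expect_lt(m$w_hs, m$w_pqs)
  expect_lt(m$w_pqq, m$w_iq)
})
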