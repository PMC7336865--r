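test_that("pooled t-test matches the closed form and stats::t.test", {
  # identical groups: t = 0, p = 1
  ht0 <- pooled_t_test_stats(5, 2, 30, 5, 2, 40)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)

  # study-like duration-of-smoking summaries, against an independent
  # recomputation of the pooled formula
  m1 <- 47.73; s1 <- 10.5; n1 <- 40
  m2 <- 42.13; s2 <- 13.61; n2 <- 283
  ht <- pooled_t_test_stats(m1, s1, n1, m2, s2, n2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t_hand <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(unname(ht$statistic), t_hand, tolerance = 1e-10)
  expect_equal(unname(ht$parameter), 321)
  expect_equal(ht$p.value, 2 * pt(-abs(t_hand), 321), tolerance = 1e-12)

  # doubling both sample sizes with the same summaries decreases p
  ht2 <- pooled_t_test_stats(m1, s1, 2 * n1, m2, s2, 2 * n2)
  expect_lt(ht2$p.value, ht$p.value)

  # raw-vector overload equals summary version and stats::t.test
  withr::local_seed(3)
  x <- rnorm(25, 50, 8); y <- rnorm(40, 46, 9)
  hraw <- pooled_t_test(x, y)
  hsum <- pooled_t_test_stats(mean(x), sd(x), length(x),
                              mean(y), sd(y), length(y))
  expect_equal(unname(hraw$statistic), unname(hsum$statistic), tolerance = 1e-12)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(hraw$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(hraw$p.value, ref$p.value, tolerance = 1e-12)
  # Welch flag reproduces Welch
  expect_equal(pooled_t_test(x, y, welch = TRUE)$p.value,
               t.test(x, y)$p.value, tolerance = 1e-12)
  expect_error(pooled_t_test(1, 1:5), "two observations")
  expect_error(pooled_t_test_stats(1, 0, 10, 2, 1, 10), "positive")
})

test_that("chi-squared test matches hand-computed sums over (O-E)^2/E", {
  # proportional rows: X^2 = 0, p = 1
  ht0 <- chi_squared_test(rbind(c(10, 20), c(30, 60)))
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)

  # study-like advice-from-others table
  tab <- rbind(c(24, 15), c(170, 96))
  ht <- chi_squared_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_hand <- sum((tab - E)^2 / E)
  expect_equal(unname(ht$statistic), x2_hand, tolerance = 1e-10)
  expect_equal(unname(ht$parameter), 1)
  expect_equal(ht$p.value, pchisq(x2_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # permuting rows/columns leaves X^2 unchanged
  expect_equal(unname(chi_squared_test(tab[2:1, ])$statistic),
               unname(ht$statistic), tolerance = 1e-12)
  expect_equal(unname(chi_squared_test(tab[, 2:1])$statistic),
               unname(ht$statistic), tolerance = 1e-12)

  expect_error(chi_squared_test(rbind(c(0, 0), c(1, 2))), "non-empty")
  expect_error(chi_squared_test(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("baseline stage distributions report counts and percentages", {
  subs <- c(
    lapply(1:28, function(i) list(id = paste0("h", i), group = "HCP",
                                  times = 0, stages = 1)),
    lapply(1:9, function(i) list(id = paste0("hc", i), group = "HCP",
                                 times = 0, stages = 2)),
    lapply(1:3, function(i) list(id = paste0("hp", i), group = "HCP",
                                 times = 0, stages = 3)))
  ds <- make_panel(subs)
  d <- baseline_stage_distribution(ds, "HCP")
  expect_equal(d$count, c(28L, 9L, 3L, 0L))
  expect_equal(d$pct, c(70.0, 22.5, 7.5, 0.0))
  expect_equal(sum(d$count), 40L)
  expect_error(baseline_stage_distribution(ds, "nope"), "no baseline")
})

test_that("transition crosstab counts pairs and conserves subjects", {
  ds <- make_panel(list(
    list(id = "a", times = c(0, 4), stages = c(1, 1)),
    list(id = "b", times = c(0, 4), stages = c(3, 4)),
    list(id = "c", times = c(0, 4), stages = c(2, 2)),
    list(id = "d", times = 0, stages = 1)))
  ct <- transition_crosstab(ds, "control", 0, 4)
  expect_equal(sum(ct), 3L)  # subject d lacks the second visit
  expect_equal(ct["preparation", "action"], 1L)
  expect_equal(ct["precontemplation", "precontemplation"], 1L)
  expect_error(transition_crosstab(ds, "control", 0, 2), "no subject")

  # simulated cohort: row sums equal the baseline counts of completers
  cfg <- default_study_config(seed = 6)
  sim <- simulate_cohort(cfg, exact_baseline = TRUE)
  ct2 <- transition_crosstab(sim, "control", 0, 4)
  base <- baseline_stage_distribution(sim, "control")
  expect_equal(unname(rowSums(ct2)), base$count)
})

test_that("group_summary assembles tests per covariate and stage mixes", {
  cfg <- default_study_config(seed = 12)
  ds <- simulate_cohort(cfg, exact_baseline = TRUE)
  gs <- group_summary(ds)
  expect_setequal(gs$covariates$covariate,
                  c("age", "smoking_duration", "advice", "hcp"))
  expect_equal(unname(gs$n[c("HCP", "control")]), c(40L, 283L))
  # percentages over transient stages sum to 100 (within rounding)
  for (g in names(gs$baseline)) {
    expect_equal(sum(gs$baseline[[g]]$pct), 100, tolerance = 0.1)
  }
  # continuous rows use the pooled t, binary rows the chi-squared test
  expect_equal(gs$covariates$test[gs$covariates$covariate == "age"], "pooled t")
  expect_equal(gs$covariates$test[gs$covariates$covariate == "advice"],
               "chi-squared")
  # t statistic equals a direct recomputation from the subject table
  tab <- subject_table(ds)
  ht <- pooled_t_test(tab$age[tab$group == "HCP"],
                      tab$age[tab$group == "control"])
  expect_equal(abs(gs$covariates$statistic[gs$covariates$covariate == "age"]),
               abs(unname(ht$statistic)), tolerance = 1e-12)
})
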