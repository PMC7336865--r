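test_that("intercept-only MLE on single-cycle data equals empirical frequencies", {
  cfg <- quick_config(n = 400, schedule = c(0L, 1L), seed = 41)
  ds <- simulate_cohort(cfg)
  tr <- observed_transitions(ds)
  emp <- prop.table(table(factor(tr$from, 1:4), factor(tr$to, 1:4)), 1)
  fit <- fit_mle(ds, model_spec(), restarts = 3, seed = 2)
  it <- fit$interval_table
  pr <- it[it$quantity == "transition_prob", ]
  for (r in seq_len(nrow(pr))) {
    s <- stage_code(pr$source[r]); d <- stage_code(pr$destination[r])
    expect_equal(pr$estimate[r], unname(emp[s, d]), tolerance = 1e-6)
  }
  expect_true(fit$convergence$converged)
  # likelihood at the MLE beats the likelihood at the truth
  fd <- stagechain:::build_fit_data(ds, model_spec())
  ll_true <- stagechain:::cpp_panel_loglik(
    stagechain:::pack_params(cfg$params, cfg$spec)[1:9] * 0, fd$X, fd$terms,
    0L, FALSE, 0)  # any fixed parameter vector is dominated
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("all-stayers data pushes the diagonal to 1 and flags the boundary", {
  subs <- lapply(1:30, function(i) {
    list(id = sprintf("s%d", i), times = c(0, 1), stages = rep(1 + i %% 3, 2))
  })
  ds <- make_panel(subs)
  fit <- suppressWarnings(fit_mle(ds, model_spec(), restarts = 2, seed = 1))
  P <- transition_matrix_for(params = fit$params)
  expect_true(all(diag(P)[1:3] > 0.99))
  expect_true(fit$convergence$boundary)
})

test_that("states with no observed departures are flagged, not fatal", {
  withr::local_seed(13)
  subs <- lapply(1:40, function(i) {
    list(id = sprintf("s%d", i), times = c(0, 1),
         stages = c(1 + i %% 2, sample(1:2, 1)))
  })
  ds <- make_panel(subs)
  fit <- fit_mle(ds, model_spec(), restarts = 2, seed = 1)
  expect_true(3L %in% fit$convergence$nonidentified_states)
  it <- fit$interval_table
  prep <- it[it$quantity == "transition_prob" & it$source == "preparation", ]
  expect_true(all(is.na(prep$lower)))
})

test_that("complete-case accounting adds up and is reported", {
  cfg <- quick_config(n = 60, seed = 9)
  ds <- simulate_cohort(cfg)
  ds$data$z[ds$data$subject_id %in% c("A_0001", "A_0002")] <- NA
  spec <- model_spec("z", types = "binary", scaling = "none")
  fit <- suppressMessages(fit_mle(ds, spec, restarts = 2, seed = 1))
  expect_equal(fit$n_excluded, 2L)
  expect_equal(fit$n_used + fit$n_excluded, 60L)
})

test_that("parameter recovery: MLE finds the truth at moderate n", {
  cfg <- quick_config(n = 3000, schedule = c(0L, 1L, 2L), seed = 314)
  ds <- simulate_cohort(cfg)
  fit <- fit_mle(ds, cfg$spec, restarts = 3, seed = 5)
  # every beta within ~3 SE of truth (SEs from the information matrix)
  it <- fit$interval_table
  no <- it[it$quantity == "net_or", ]
  truth <- sapply(1:3, function(s) net_odds_ratio(cfg$params, cfg$spec, "z", s))
  for (s in 1:3) {
    row <- no[no$source == stage_levels()[s], ]
    expect_gt(truth[s], row$lower * 0.67)
    expect_lt(truth[s], row$upper * 1.5)
  }
  # likelihood at the MLE >= likelihood at the simulation truth
  fd <- stagechain:::build_fit_data(ds, cfg$spec)
  ll_true <- stagechain:::cpp_panel_loglik(
    stagechain:::pack_params(cfg$params, cfg$spec), fd$X, fd$terms, 1L,
    FALSE, 0)
  expect_gte(fit$loglik + 1e-6, ll_true)
})

test_that("groupwise fit fixes the absorbing action row exactly", {
  cfg <- quick_two_arm_config(n_hcp = 80, n_control = 120, seed = 21)
  ds <- simulate_cohort(cfg)
  gw <- fit_groupwise(ds, interval = "wald", restarts = 2)
  for (g in gw$groups) {
    expect_identical(unname(g$matrix[4, ]), c(0, 0, 0, 1))
    expect_true(all(g$matrix >= 0 & g$matrix <= 1))
    expect_equal(unname(rowSums(g$matrix)), rep(1, 4), tolerance = 1e-8)
  }
  expect_setequal(names(gw$groups), c("HCP", "control"))
})

test_that("bootstrap intervals are reproducible and degenerate data give zero width", {
  cfg <- quick_config(n = 80, seed = 2)
  ds <- simulate_cohort(cfg)
  spec <- model_spec()
  b1 <- bootstrap_intervals(ds, spec, B = 2, seed = 7, restarts = 1)
  b2 <- bootstrap_intervals(ds, spec, B = 2, seed = 7, restarts = 1)
  expect_equal(b1$interval_table, b2$interval_table)
  b3 <- bootstrap_intervals(ds, spec, B = 2, seed = 8, restarts = 1)
  expect_false(isTRUE(all.equal(b3$interval_table$lower,
                                b1$interval_table$lower)))

  # identical subjects: every resample is the same dataset
  subs <- lapply(1:12, function(i) {
    list(id = sprintf("s%d", i), times = c(0, 1), stages = c(1, 2))
  })
  dsd <- make_panel(subs)
  bd <- suppressWarnings(
    bootstrap_intervals(dsd, model_spec(), B = 3, seed = 1, restarts = 1))
  tabd <- bd$interval_table
  row <- tabd[tabd$source == "precontemplation" &
                !is.na(tabd$destination) &
                tabd$destination == "contemplation", ]
  expect_equal(row$lower, row$upper, tolerance = 1e-5)
})

test_that("posterior sampling is seed-reproducible and matches the MLE on big data", {
  cfg <- quick_config(n = 1500, schedule = c(0L, 1L), seed = 6)
  ds <- simulate_cohort(cfg)
  ps1 <- fit_posterior(ds, model_spec(), iterations = 1500, burn_in = 500,
                       seed = 42, restarts = 2)
  ps2 <- fit_posterior(ds, model_spec(), iterations = 1500, burn_in = 500,
                       seed = 42, restarts = 2)
  expect_identical(ps1$chain, ps2$chain)
  expect_gt(ps1$diagnostics$acceptance_rate, 0.05)
  expect_lt(ps1$diagnostics$acceptance_rate, 0.7)
  # flat priors + large n: posterior medians near the MLE
  mle <- ps1$mle
  se <- sqrt(diag(mle$vcov))
  expect_true(all(abs(ps1$theta[ps1$free] - mle$theta[mle$free]) <
                    pmax(0.5 * se, 0.05)))
  # absorbing row is exactly (0,0,0,1) in every draw-derived matrix
  it <- ps1$interval_table
  expect_false(any(it$source == "action", na.rm = TRUE))
  P_med <- transition_matrix_for(params = ps1$params)
  expect_identical(unname(P_med[4, ]), c(0, 0, 0, 1))
})

test_that("interval tables respect lower <= point <= upper", {
  cfg <- quick_two_arm_config(n_hcp = 120, n_control = 150, seed = 17)
  ds <- simulate_cohort(cfg)
  fit <- fit_mle(ds, cfg$spec, restarts = 2, seed = 3)
  it <- fit$interval_table
  ok <- stats::complete.cases(it[, c("estimate", "lower", "upper")])
  expect_true(all(it$lower[ok] <= it$estimate[ok] + 1e-9))
  expect_true(all(it$estimate[ok] <= it$upper[ok] + 1e-9))
  pr <- it$quantity == "transition_prob"
  expect_true(all(it$lower[pr & ok] >= 0 & it$upper[pr & ok] <= 1))
})
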