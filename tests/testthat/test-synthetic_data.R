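test_that("the default study config states the emulated design", {
  cfg <- default_study_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$arms$HCP$n, 40L)
  expect_equal(cfg$arms$control$n, 283L)
  expect_equal(cfg$arms$HCP$schedule, c(0L, 1L, 4L))
  expect_equal(cfg$arms$control$schedule, c(0L, 4L))
  expect_equal(cfg$arms$HCP$baseline_probs, c(0.700, 0.225, 0.075))
  expect_equal(cfg$arms$control$baseline_probs,
               c(0.583, 0.360, 0.057) / sum(c(0.583, 0.360, 0.057)))
  expect_equal(cfg$arms$HCP$covariates$age$mean, 71.00)
  expect_equal(cfg$arms$control$covariates$age$sd, 12.22)
  expect_equal(cfg$arms$HCP$covariates$advice$prob, 0.615)
  # placeholder truth is a valid parameter set on a valid spec
  expect_silent(check_transition_matrix(
    transition_matrix_for(rep(0, 4), cfg$params, cfg$spec)))
})

test_that("simulation_config validates schedules and baseline probabilities", {
  cfg <- default_study_config()
  bad <- cfg$arms
  bad$HCP$schedule <- c(1L, 4L)
  expect_error(simulation_config(bad, cfg$params, cfg$spec), "starting at 0")
  bad <- cfg$arms
  bad$control$baseline_probs <- c(0.5, 0.5)
  expect_error(simulation_config(bad, cfg$params, cfg$spec), "3 non-negative")
})

test_that("simulation is reproducible by seed and stable under arm growth", {
  cfg <- quick_two_arm_config(n_hcp = 25, n_control = 30, seed = 5)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1$data, d2$data)
  cfg2 <- cfg
  cfg2$seed <- 6L
  d3 <- simulate_cohort(cfg2)
  expect_false(identical(d1$data$stage, d3$data$stage))
  # enlarging the first arm leaves existing subjects' trajectories unchanged
  cfg3 <- cfg
  cfg3$arms$HCP$n <- 40L
  d4 <- simulate_cohort(cfg3)
  kept <- d4$data[d4$data$subject_id %in% d1$data$subject_id, ]
  rownames(kept) <- NULL
  expect_identical(kept, d1$data)
})

test_that("n = 0 arms give an empty dataset", {
  cfg <- quick_config(n = 0)
  ds <- simulate_cohort(cfg)
  expect_equal(nrow(ds$data), 0L)
})

test_that("every simulated dataset validates cleanly and action absorbs", {
  cfg <- default_study_config(seed = 8)
  ds <- simulate_cohort(cfg)
  expect_equal(nrow(validate_panel(ds)), 0L)
  d <- ds$data
  for (sid in unique(d$subject_id[d$stage == 4L])) {
    rows <- d[d$subject_id == sid, ]
    after <- rows$stage[seq(min(which(rows$stage == 4L)), nrow(rows))]
    expect_true(all(after == 4L))
  }
})

test_that("uniform transient rows give ~25% one-cycle frequencies at n = 20000", {
  spec <- model_spec()
  params <- model_params(matrix(0, 3, 4))
  cfg <- simulation_config(
    arms = list(A = list(n = 20000L, schedule = c(0L, 1L),
                         baseline_probs = c(1, 1, 1) / 3,
                         covariates = list())),
    params = params, spec = spec, seed = 33)
  ds <- simulate_cohort(cfg)
  tr <- observed_transitions(ds)
  emp <- prop.table(table(factor(tr$from, 1:3), factor(tr$to, 1:4)), 1)
  expect_true(all(abs(emp - 0.25) < 0.01))
  # baseline frequencies converge to the configured distribution
  base <- baseline_stage_distribution(ds, "A")
  expect_true(all(abs(base$count[1:3] / 20000 - 1 / 3) < 0.01))
})

test_that("covariate generators hit their configured moments", {
  cfg <- default_study_config(seed = 10)
  cfg$arms$HCP$n <- 10000L
  cfg$arms$control$n <- 0L
  ds <- simulate_cohort(cfg)
  tab <- subject_table(ds)
  # age: mean within 3 SE, sd close (truncation at 30-100 is ~4 sigma out)
  expect_lt(abs(mean(tab$age) - 71.00), 3 * 7.22 / sqrt(10000))
  expect_lt(abs(sd(tab$age) - 7.22), 0.2)
  # duration: conditional-on-age draw preserves the marginal moments
  expect_lt(abs(mean(tab$smoking_duration) - 47.73), 3 * 10.5 / sqrt(10000) + 0.15)
  # the duration <= age - 10 cap clips the far upper tail (~2.6 sigma),
  # shaving a few percent off the realised SD
  expect_lt(abs(sd(tab$smoking_duration) - 10.5), 0.5)
  # the age cap holds and the correlation is strong
  expect_true(all(tab$smoking_duration <= tab$age - 10 + 1e-9))
  expect_gt(cor(tab$age, tab$smoking_duration), 0.8)
  # binary covariate
  p_hat <- mean(tab$advice)
  expect_lt(abs(p_hat - 0.615), 3 * sqrt(0.615 * 0.385 / 10000))
})

test_that("exact baseline allocation reproduces stated counts", {
  cfg <- default_study_config(seed = 2)
  ds <- simulate_cohort(cfg, exact_baseline = TRUE)
  expect_equal(baseline_stage_distribution(ds, "HCP")$count, c(28L, 9L, 3L, 0L))
  expect_equal(baseline_stage_distribution(ds, "control")$count,
               c(165L, 102L, 16L, 0L))
})

test_that("simulate_replicates aggregates bias and coverage", {
  cfg <- quick_config(n = 40, seed = 3)
  truth <- stagechain:::fit_quantities(
    stagechain:::pack_params(cfg$params, cfg$spec), cfg$spec)
  # trivial analysis returning the truth with wide intervals
  analysis <- function(ds) {
    list(interval_table = stagechain:::quantity_frame(
      truth, truth * 0.5, truth * 2 + 0.5, "oracle", cfg$spec))
  }
  rep <- simulate_replicates(cfg, reps = 3, analysis = analysis)
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep), length(truth))
  expect_equal(rep$bias, rep(0, nrow(rep)), tolerance = 1e-12)
  expect_equal(rep$coverage, rep(1, nrow(rep)))
  expect_equal(attr(rep, "n_fail"), 0L)
  # failures are recorded, not fatal
  boom <- function(ds) stop("nope")
  rep2 <- simulate_replicates(cfg, reps = 2, analysis = boom)
  expect_equal(attr(rep2, "n_fail"), 2L)
})
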