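# Synthetic two-arm cohort generator: known Markov-regression parameters in,
# panel datasets out, so every downstream stage has a ground-truth test bed.

#' Build a simulation configuration
#'
#' Describes a two-arm (or k-arm) panel study: per-arm sample size,
#' observation schedule in cycles, baseline distribution over the three
#' transient stages, and covariate generators; plus the true transition
#' model (`params` + `spec`) driving the stage trajectories.
#'
#' @param arms named list; each arm is a list with `n` (>= 0), `schedule`
#'   (strictly increasing integer cycles starting at 0), `baseline_probs`
#'   (length-3 probabilities over precontemplation/contemplation/
#'   preparation; renormalised if they do not sum to exactly 1) and
#'   `covariates`, a named list of generators: `list(mean=, sd=, bounds=)`
#'   for continuous, `list(prob=)` for binary covariates.
#' @param params true [model_params()].
#' @param spec true [model_spec()]; its `centers`/`scales` anchors define
#'   the scale on which `params` acts (required for any covariate whose
#'   scaling is not `"none"`).
#' @param dependence optional list(parent=, child=, rho=, lower=,
#'   upper_offset=): the child covariate is drawn conditionally on the
#'   parent (bivariate normal with correlation `rho`, marginal mean/sd
#'   preserved) and truncated to `[lower, parent + upper_offset]`.
#' @param seed master seed; per-arm and per-subject random streams are
#'   derived from it so that enlarging one arm never perturbs the draws of
#'   existing subjects or other arms.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(arms, params, spec, dependence = NULL,
                              seed = 1) {
  stopifnot(is.list(arms), length(arms) >= 1, !is.null(names(arms)))
  for (nm in names(arms)) {
    arm <- arms[[nm]]
    stopifnot(is.numeric(arm$n), arm$n >= 0, arm$n == round(arm$n))
    sch <- arm$schedule
    if (length(sch) < 1 || sch[1] != 0 || any(diff(sch) <= 0) ||
        any(sch != round(sch))) {
      stop("arm '", nm, "': schedule must be strictly increasing integer ",
           "cycles starting at 0", call. = FALSE)
    }
    bp <- arm$baseline_probs
    if (length(bp) != 3 || any(bp < 0) || sum(bp) <= 0) {
      stop("arm '", nm, "': baseline_probs must be 3 non-negative values",
           call. = FALSE)
    }
    arms[[nm]]$baseline_probs <- bp / sum(bp)
  }
  stopifnot(inherits(params, "model_params"), inherits(spec, "model_spec"))
  structure(list(arms = arms, params = params, spec = spec,
                 dependence = dependence, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$arms)) {
    arm <- x$arms[[nm]]
    cat(sprintf("  %s: n=%d, schedule [%s], baseline (%s)\n", nm, arm$n,
                paste(arm$schedule, collapse = ", "),
                paste(sprintf("%.3f", arm$baseline_probs), collapse = ", ")))
  }
  cat("  covariates:", paste(x$spec$covariates, collapse = ", "), "\n")
  invisible(x)
}

# largest-remainder allocation of n among categories with given probabilities
quota_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Default study configuration
#'
#' The stated world the generator emulates: a two-arm quasi-experimental
#' community smoking-cessation advice study with 40 male smokers advised by
#' healthcare professionals (HCP; observed at baseline, 2 weeks and 2
#' months, i.e. cycles 0, 1, 4) and 283 controls (baseline and 2 months,
#' cycles 0 and 4).  Baseline transient-stage mixes are 70%/22.5%/7.5%
#' (HCP) and 58.3%/36.0%/5.7% (control).  Covariates: age (normal,
#' 71.00 +/- 7.22 vs 66.15 +/- 12.22 years, truncated to 30-100 years),
#' smoking duration (47.73 +/- 10.5 vs 42.13 +/- 13.61 years, drawn
#' conditionally on age with correlation 0.9 and capped at age - 10), and
#' prior cessation advice from others (Bernoulli 0.615 vs 0.639).  The true
#' transition parameters are a documented placeholder: control-arm
#' intercepts matching plausible biweekly transition probabilities for an
#' unadvised population, and net forward odds ratios of realistic magnitude
#' for the HCP indicator, age, duration and advice, split antisymmetrically
#' between forward and backward coefficients.
#'
#' Continuous covariates act on the standardised scale anchored at the
#' pooled (mixture) population mean and SD, which are stored in the spec so
#' simulation and refitting use the same units.
#'
#' @param seed master seed stored in the config.
#' @return a [simulation_config()].
#' @export
default_study_config <- function(seed = 1) {
  arms <- list(
    HCP = list(
      n = 40L, schedule = c(0L, 1L, 4L),
      baseline_probs = c(0.700, 0.225, 0.075),
      covariates = list(
        age = list(mean = 71.00, sd = 7.22, bounds = c(30, 100)),
        smoking_duration = list(mean = 47.73, sd = 10.5),
        advice = list(prob = 0.615))),
    control = list(
      n = 283L, schedule = c(0L, 4L),
      baseline_probs = c(0.583, 0.360, 0.057),
      covariates = list(
        age = list(mean = 66.15, sd = 12.22, bounds = c(30, 100)),
        smoking_duration = list(mean = 42.13, sd = 13.61),
        advice = list(prob = 0.639))))
  # pooled-mixture anchors for the standardised scale
  w <- c(40, 283) / 323
  mix <- function(cv) {
    m <- c(arms$HCP$covariates[[cv]]$mean, arms$control$covariates[[cv]]$mean)
    s <- c(arms$HCP$covariates[[cv]]$sd, arms$control$covariates[[cv]]$sd)
    mu <- sum(w * m)
    c(center = mu, scale = sqrt(sum(w * (s^2 + m^2)) - mu^2))
  }
  age_a <- mix("age")
  dur_a <- mix("smoking_duration")
  spec <- model_spec(
    covariates = c("hcp", "age", "smoking_duration", "advice"),
    types = c("binary", "continuous", "continuous", "binary"),
    scaling = "standardize", constraint = "free",
    centers = c(hcp = 0, age = unname(age_a["center"]),
                smoking_duration = unname(dur_a["center"]), advice = 0),
    scales = c(hcp = 1, age = unname(age_a["scale"]),
               smoking_duration = unname(dur_a["scale"]), advice = 1))
  # placeholder truth: control-arm one-cycle probabilities ...
  ctl <- rbind(c(0.5359, 0.3564, 0.0722, 0.0355),
               c(0.8523, 0.0935, 0.0393, 0.0149),
               c(0.5733, 0.3231, 0.1366, 0.0570))
  alpha <- matrix(0, 3, 4)
  for (s in 1:3) for (d in setdiff(1:4, s)) alpha[s, d] <- log(ctl[s, d] / ctl[s, s])
  # ... and per-stage net forward ORs of realistic magnitude per covariate
  net_or <- rbind(hcp = c(1.21, 4.29, 2.40),
                  age = c(0.50, 0.58, 1.28),
                  smoking_duration = c(1.21, 1.19, 0.74),
                  advice = c(1.33, 1.06, 1.36))
  bf <- bb <- matrix(0, 3, nrow(net_or),
                     dimnames = list(NULL, rownames(net_or)))
  for (j in seq_len(nrow(net_or))) {
    l <- log(net_or[j, ])
    bf[1, j] <- l[1]                 # no backward path from precontemplation
    bf[2:3, j] <- l[2:3] / 2
    bb[2:3, j] <- -l[2:3] / 2
  }
  params <- model_params(alpha, bf, bb, covariates = spec$covariates)
  simulation_config(
    arms = arms, params = params, spec = spec,
    dependence = list(parent = "age", child = "smoking_duration", rho = 0.9,
                      lower = 1, upper_offset = -10),
    seed = seed)
}

draw_truncnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Simulate a cohort from a configuration
#'
#' For each subject: draw covariates, draw the baseline stage from the
#' arm's baseline distribution (or allocate exactly by largest-remainder
#' quota with `exact_baseline = TRUE`), build the subject's one-cycle
#' matrix via [transition_matrix_for()], evolve the chain cycle by cycle to
#' the last scheduled visit (action absorbs), and record the stage at each
#' scheduled cycle.  Deterministic given the config seed; per-subject
#' streams are derived so earlier subjects' draws are stable under `n`
#' changes.  An `hcp` indicator column (1 for the arm named "HCP",
#' case-insensitive) is added for use as the intervention covariate.
#'
#' @param config a [simulation_config()].
#' @param exact_baseline allocate baseline stages by exact quota instead of
#'   sampling (used to build fixture cohorts with stated baseline counts).
#' @return a `panel_dataset`.
#' @export
simulate_cohort <- function(config, exact_baseline = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$spec
  dep <- config$dependence
  cov_names <- unique(unlist(lapply(config$arms, function(a) names(a$covariates))))
  arm_masters <- withr::with_seed(config$seed,
    sample.int(2147483646L, length(config$arms), replace = TRUE))
  rows <- list()
  for (ai in seq_along(config$arms)) {
    arm_name <- names(config$arms)[ai]
    arm <- config$arms[[ai]]
    if (arm$n == 0L) next
    subject_seeds <- withr::with_seed(arm_masters[ai],
      sample.int(2147483646L, arm$n, replace = TRUE))
    base_assign <- NULL
    if (exact_baseline) {
      base_assign <- rep(1:3, quota_counts(arm$n, arm$baseline_probs))
    }
    is_hcp <- as.integer(tolower(arm_name) == "hcp")
    horizon <- max(arm$schedule)
    for (i in seq_len(arm$n)) {
      res <- withr::with_seed(subject_seeds[i], {
        covs <- list()
        for (cv in names(arm$covariates)) {
          g <- arm$covariates[[cv]]
          if (!is.null(g$prob)) {
            covs[[cv]] <- stats::rbinom(1, 1, g$prob)
          } else if (!is.null(dep) && identical(dep$child, cv)) {
            pg <- arm$covariates[[dep$parent]]
            parent_val <- covs[[dep$parent]]
            if (is.null(pg) || is.null(parent_val)) {
              stop("dependence parent '", dep$parent,
                   "' must be generated before child '", cv, "'",
                   call. = FALSE)
            }
            mu <- g$mean + dep$rho * (g$sd / pg$sd) * (parent_val - pg$mean)
            sdc <- g$sd * sqrt(1 - dep$rho^2)
            covs[[cv]] <- draw_truncnorm(mu, sdc, dep$lower,
                                         parent_val + dep$upper_offset)
          } else {
            b <- if (is.null(g$bounds)) c(-Inf, Inf) else g$bounds
            covs[[cv]] <- draw_truncnorm(g$mean, g$sd, b[1], b[2])
          }
        }
        covs$hcp <- is_hcp
        x <- scaled_profile(covs, spec)
        P <- transition_matrix_for(x, config$params, spec)
        state <- if (exact_baseline) base_assign[i] else
          sample.int(3L, 1L, prob = arm$baseline_probs)
        traj <- integer(horizon + 1L)
        traj[1L] <- state
        if (horizon > 0L) for (t in seq_len(horizon)) {
          state <- if (state == 4L) 4L else
            sample.int(4L, 1L, prob = P[state, ])
          traj[t + 1L] <- state
        }
        list(covs = covs, stages = traj[arm$schedule + 1L])
      })
      row <- data.frame(subject_id = sprintf("%s_%04d", arm_name, i),
                        group = arm_name, time = arm$schedule,
                        stage = res$stages, stringsAsFactors = FALSE)
      for (cv in c(cov_names, "hcp")) row[[cv]] <- res$covs[[cv]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  schema_names <- c(cov_names, "hcp")
  schema_types <- vapply(schema_names, function(cv) {
    if (cv %in% spec$covariates) unname(spec$types[[cv]])
    else if (cv == "hcp") "binary"
    else {
      g <- NULL
      for (a in config$arms) if (cv %in% names(a$covariates)) g <- a$covariates[[cv]]
      if (!is.null(g$prob)) "binary" else "continuous"
    }
  }, character(1))
  data <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0),
               time = integer(0), stage = integer(0))
  if (!length(rows)) for (cv in schema_names) data[[cv]] <- numeric(0)
  panel_dataset(data, schema = stats::setNames(schema_types, schema_names))
}

# scale a named covariate list onto the model scale using the spec anchors
scaled_profile <- function(covs, spec) {
  if (!length(spec$covariates)) return(numeric(0))
  vapply(spec$covariates, function(cv) {
    val <- covs[[cv]]
    if (is.null(val)) stop("simulation produced no value for covariate ", cv,
                           call. = FALSE)
    if (spec$scaling[[cv]] == "none") return(as.numeric(val))
    if (is.null(spec$centers) || !cv %in% names(spec$centers)) {
      stop("spec has no scaling anchors for covariate ", cv,
           "; provide centers/scales or use scaling = 'none'", call. = FALSE)
    }
    (as.numeric(val) - spec$centers[[cv]]) / spec$scales[[cv]]
  }, numeric(1))
}

#' Parameter-recovery harness
#'
#' Runs `analysis` (a function `dataset -> stage_fit`-like object with an
#' `interval_table`) on `reps` independently simulated cohorts and
#' aggregates, per reported quantity (reference-profile transition
#' probabilities and net forward odds ratios), the bias and RMSE of the
#' point estimates and the empirical coverage of the nominal-95% intervals
#' against the configured truth.  Replicate failures are recorded, not
#' fatal.
#'
#' @param config a [simulation_config()]; truth is taken from its
#'   `params`/`spec`.
#' @param reps number of replicates (>= 2).
#' @param analysis function taking a `panel_dataset`.
#' @param seed seed for the replicate seed stream (defaults to the config
#'   seed).
#' @param exact_baseline passed to [simulate_cohort()].
#' @return object of class `recovery_report`: data.frame with one row per
#'   quantity (`true`, `mean_est`, `bias`, `rmse`, `coverage`, `n_ok`),
#'   with attribute `n_fail`.
#' @export
simulate_replicates <- function(config, reps, analysis,
                                seed = config$seed, exact_baseline = FALSE) {
  stopifnot(inherits(config, "simulation_config"), reps >= 2)
  truth <- fit_quantities(pack_params(config$params, config$spec), config$spec)
  rep_seeds <- withr::with_seed(seed,
    sample.int(2147483646L, reps, replace = TRUE))
  est <- lo <- hi <- matrix(NA_real_, reps, length(truth),
                            dimnames = list(NULL, names(truth)))
  n_fail <- 0L
  failures <- character(0)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- rep_seeds[r]
      fit <- analysis(simulate_cohort(cfg, exact_baseline = exact_baseline))
      interval_table_quantities(fit$interval_table)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      failures <- c(failures, conditionMessage(res))
      next
    }
    common <- intersect(names(truth), names(res$est))
    est[r, common] <- res$est[common]
    lo[r, common] <- res$lower[common]
    hi[r, common] <- res$upper[common]
  }
  out <- data.frame(
    quantity = names(truth), true = unname(truth),
    mean_est = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(truth),
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2, na.rm = TRUE)),
    sd_est = apply(est, 2, stats::sd, na.rm = TRUE),
    coverage = sapply(seq_along(truth), function(j) {
      ok <- !is.na(lo[, j]) & !is.na(hi[, j])
      if (!any(ok)) return(NA_real_)
      mean(lo[ok, j] <= truth[j] & truth[j] <= hi[ok, j])
    }),
    n_ok = colSums(!is.na(est)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("recovery_report", "data.frame"),
            n_fail = n_fail, failures = failures)
}

# rebuild named quantity vectors (est/lower/upper) from an interval_table
interval_table_quantities <- function(tab) {
  nm <- ifelse(tab$quantity == "transition_prob",
               sprintf("prob[%s->%s]", tab$source, tab$destination),
               sprintf("netor[%s:%s]", tab$covariate, tab$source))
  list(est = stats::setNames(tab$estimate, nm),
       lower = stats::setNames(tab$lower, nm),
       upper = stats::setNames(tab$upper, nm))
}
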