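# Shared fixture builders: everything is generated in code at test time.

# random valid one-cycle matrix (absorbing action row) from the current RNG
rand_tmatrix <- function() {
  M <- matrix(stats::rexp(16), 4)
  M <- M / rowSums(M)
  M[4, ] <- c(0, 0, 0, 1)
  transition_matrix(M)
}

# long-format panel from a compact description:
#   subjects = list(list(id=, group=, times=, stages=, <covariates>...))
make_panel <- function(subjects, schema = NULL) {
  rows <- lapply(subjects, function(s) {
    out <- data.frame(subject_id = s$id,
                      group = if (is.null(s$group)) "control" else s$group,
                      time = s$times, stage = s$stages,
                      stringsAsFactors = FALSE)
    extra <- setdiff(names(s), c("id", "group", "times", "stages"))
    for (cv in extra) out[[cv]] <- s[[cv]]
    out
  })
  panel_dataset(do.call(rbind, rows), schema = schema)
}

# small single-arm config with one binary covariate on the raw (unscaled)
# scale, observed every cycle: strong identification for quick fit tests
quick_config <- function(n = 300, schedule = c(0L, 1L), seed = 1,
                         baseline = c(1, 1, 1) / 3) {
  spec <- model_spec("z", types = "binary", scaling = "none",
                     constraint = "free")
  alpha <- matrix(c(0, -0.5, -1.0, -1.5,
                    0.5, 0, -0.8, -1.2,
                    0.8, 0.3, 0, -0.5), 3, 4, byrow = TRUE)
  params <- model_params(alpha,
                         beta_forward = matrix(c(0.6, 0.4, 0.9), 3, 1),
                         beta_backward = matrix(c(0, -0.3, -0.5), 3, 1),
                         covariates = "z")
  simulation_config(
    arms = list(A = list(n = as.integer(n), schedule = as.integer(schedule),
                         baseline_probs = baseline,
                         covariates = list(z = list(prob = 0.5)))),
    params = params, spec = spec, seed = seed)
}

# two-arm version of quick_config with an hcp indicator effect, mirroring a
# treated/control design with different observation schedules
quick_two_arm_config <- function(n_hcp = 300, n_control = 300, seed = 1,
                                 schedule_hcp = c(0L, 1L, 4L),
                                 schedule_control = c(0L, 4L)) {
  spec <- model_spec("hcp", types = "binary", scaling = "none",
                     constraint = "free")
  alpha <- matrix(c(0, -0.4, -1.4, -2.0,
                    1.0, 0, -0.9, -1.5,
                    0.6, 0.4, 0, -0.8), 3, 4, byrow = TRUE)
  params <- model_params(alpha,
                         beta_forward = matrix(c(0.2, 0.7, 0.45), 3, 1),
                         beta_backward = matrix(c(0, -0.7, -0.45), 3, 1),
                         covariates = "hcp")
  arm <- function(n, schedule, bp) {
    list(n = as.integer(n), schedule = as.integer(schedule),
         baseline_probs = bp, covariates = list())
  }
  simulation_config(
    arms = list(HCP = arm(n_hcp, schedule_hcp, c(0.700, 0.225, 0.075)),
                control = arm(n_control, schedule_control,
                              c(0.583, 0.360, 0.057))),
    params = params, spec = spec, seed = seed)
}
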