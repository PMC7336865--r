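# End-to-end orchestration: describe -> groupwise fit -> covariate fit ->
# per-covariate (univariate) net-OR table, driven by a JSON config.  A thin
# command-line wrapper lives in inst/cli/stagechain.

#' Read and validate a pipeline configuration
#'
#' The config is a JSON object with exactly one of:
#' \describe{
#'   \item{input}{path to a long-format panel CSV (see
#'     [read_panel_csv()]), with optional `schema` (object name -> type)
#'     and `time_unit`.}
#'   \item{simulation}{`{"default_study": true, "seed": N}` with optional
#'     per-arm overrides `n_hcp` / `n_control` and `exact_baseline`.}
#' }
#' plus optional blocks `model` (`covariates`, `types`, `scaling`,
#' `constraint`), `estimation` (`method` = wald/bootstrap/posterior, `B`,
#' `iterations`, `burn_in`, `seed`, `restarts`, `use_intermediate_visit`),
#' and `output_dir`.
#'
#' @param path JSON file path, or a list already parsed.
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim) {
    stop("pipeline config must contain exactly one of 'input' and 'simulation'",
         call. = FALSE)
  }
  if (is.null(cfg$output_dir)) cfg$output_dir <- "stagechain-output"
  est <- cfg$estimation
  cfg$estimation <- list(
    method = if (is.null(est$method)) "wald" else est$method,
    B = if (is.null(est$B)) 200L else as.integer(est$B),
    iterations = if (is.null(est$iterations)) 6000L else as.integer(est$iterations),
    burn_in = if (is.null(est$burn_in)) 1000L else as.integer(est$burn_in),
    seed = if (is.null(est$seed)) 1L else as.integer(est$seed),
    restarts = if (is.null(est$restarts)) 5L else as.integer(est$restarts),
    use_intermediate_visit =
      if (is.null(est$use_intermediate_visit)) TRUE
      else isTRUE(est$use_intermediate_visit))
  if (!cfg$estimation$method %in% c("wald", "bootstrap", "posterior")) {
    stop("estimation method must be wald, bootstrap or posterior", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_dataset <- function(cfg) {
  if (!is.null(cfg$input)) {
    schema <- NULL
    if (!is.null(cfg$schema)) schema <- unlist(cfg$schema)
    read_panel_csv(cfg$input, schema = schema,
                   time_unit = if (is.null(cfg$time_unit)) "cycles"
                               else cfg$time_unit)
  } else {
    sim <- cfg$simulation
    sc <- default_study_config(seed = if (is.null(sim$seed)) 1L
                                      else as.integer(sim$seed))
    if (!is.null(sim$n_hcp)) sc$arms$HCP$n <- as.integer(sim$n_hcp)
    if (!is.null(sim$n_control)) sc$arms$control$n <- as.integer(sim$n_control)
    simulate_cohort(sc, exact_baseline = isTRUE(sim$exact_baseline))
  }
}

pipeline_spec <- function(cfg, dataset) {
  m <- cfg$model
  if (is.null(m) || is.null(m$covariates)) {
    return(model_spec(
      covariates = c("hcp", dataset$schema$name[dataset$schema$name != "hcp"]),
      types = c("binary", dataset$schema$type[dataset$schema$name != "hcp"])))
  }
  model_spec(covariates = unlist(m$covariates),
             types = if (is.null(m$types)) "continuous" else unlist(m$types),
             scaling = if (is.null(m$scaling)) "standardize" else unlist(m$scaling),
             constraint = if (is.null(m$constraint)) "free" else m$constraint)
}

ensure_outdir <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$output_dir
}

pipeline_log <- function(cfg, ...) {
  msg <- paste0(...)
  message("[stagechain] ", msg)
  cat(msg, "\n", file = file.path(cfg$output_dir, "run.log"), append = TRUE)
}

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
}

#' Run the descriptive stage of the pipeline
#'
#' Writes the two-group covariate comparison, the per-group baseline stage
#' distributions and the baseline-to-endpoint stage-change cross-tabs as
#' CSV plus a human-readable text report.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return the [group_summary()], invisibly.
#' @export
run_describe <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out <- ensure_outdir(cfg)
  ds <- pipeline_dataset(cfg)
  if (!nrow(ds$data)) stop("dataset is empty", call. = FALSE)
  gs <- group_summary(ds)
  pipeline_log(cfg, "describe: ", paste(sprintf("%s n=%d", names(gs$n), gs$n),
                                        collapse = ", "))
  utils::write.csv(gs$covariates, file.path(out, "covariate_comparison.csv"),
                   row.names = FALSE)
  base <- do.call(rbind, lapply(names(gs$baseline), function(g) {
    cbind(group = g, gs$baseline[[g]])
  }))
  utils::write.csv(base, file.path(out, "baseline_distribution.csv"),
                   row.names = FALSE)
  txt <- file.path(out, "describe.txt")
  sink(txt)
  on.exit(sink(), add = TRUE)
  print(gs)
  for (g in names(gs$baseline)) {
    times <- sort(unique(ds$data$time[ds$data$group == g]))
    if (length(times) >= 2) {
      cat("\nStage changes, group ", g, " (cycle ", times[1], " -> ",
          max(times), ")\n", sep = "")
      print(transition_crosstab(ds, g, times[1], max(times)))
    }
  }
  invisible(gs)
}

#' Run the model-fitting stage of the pipeline
#'
#' Fits the groupwise (per-arm intercept-only) matrices and the
#' covariate-adjusted model, writing the matrices with intervals, the
#' net-forward-OR table and a full-precision JSON result.  Every output row
#' is labelled with its interval method and covariate scaling; numbers in
#' the text tables are printed at 2 decimals, full precision is kept in
#' the JSON.  Identical config and seeds give byte-identical JSON.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return list with the groupwise and covariate fits, invisibly.
#' @export
run_fit <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out <- ensure_outdir(cfg)
  est <- cfg$estimation
  ds <- pipeline_dataset(cfg)
  spec <- pipeline_spec(cfg, ds)
  gw <- fit_groupwise(ds,
                      interval = if (est$method == "wald") "wald" else "posterior",
                      iterations = est$iterations, burn_in = est$burn_in,
                      seed = est$seed,
                      use_intermediate_visit = est$use_intermediate_visit)
  fit <- fit_mle(ds, spec, use_intermediate_visit = est$use_intermediate_visit,
                 restarts = est$restarts, seed = est$seed)
  itab <- fit$interval_table
  if (est$method == "bootstrap") {
    bt <- bootstrap_intervals(ds, spec, B = est$B, seed = est$seed,
                              use_intermediate_visit = est$use_intermediate_visit,
                              restarts = est$restarts)
    itab <- bt$interval_table
  } else if (est$method == "posterior") {
    ps <- fit_posterior(ds, spec, iterations = est$iterations,
                        burn_in = est$burn_in, seed = est$seed,
                        use_intermediate_visit = est$use_intermediate_visit,
                        restarts = est$restarts)
    itab <- ps$interval_table
  }
  pipeline_log(cfg, sprintf("fit: loglik %.4f, n_used %d, n_excluded %d",
                            fit$loglik, fit$n_used, fit$n_excluded))
  netor <- itab[itab$quantity == "net_or", , drop = FALSE]
  netor$scaling <- unname(fit$spec$scaling[netor$covariate])
  utils::write.csv(netor, file.path(out, "netor_table.csv"), row.names = FALSE)
  sink(file.path(out, "fit.txt"))
  on.exit(sink(), add = TRUE)
  print(gw)
  cat("\nNet forward odds ratios (", unique(netor$method), " intervals; ",
      "continuous covariates per scaled unit; unadjusted 95% intervals, ",
      "alpha = 0.05, no multiplicity correction)\n", sep = "")
  nn <- netor
  nn$estimate <- sprintf("%.2f", nn$estimate)
  nn$lower <- sprintf("%.2f", nn$lower)
  nn$upper <- sprintf("%.2f", nn$upper)
  print(nn[, c("covariate", "source", "estimate", "lower", "upper",
               "method", "scaling")], row.names = FALSE)
  json <- list(
    package_version = as.character(utils::packageVersion("stagechain")),
    seed = est$seed, method = est$method,
    n_used = fit$n_used, n_excluded = fit$n_excluded,
    loglik = fit$loglik,
    scaling = as.list(fit$spec$scaling),
    centers = as.list(fit$spec$centers), scales = as.list(fit$spec$scales),
    groupwise = lapply(gw$groups, function(g) {
      list(group = g$group, matrix = g$matrix, lower = g$lower,
           upper = g$upper, interval = g$interval)
    }),
    intervals = itab)
  write_json_result(json, file.path(out, "fit.json"))
  invisible(list(groupwise = gw, fit = fit, interval_table = itab))
}

#' Run the per-covariate (univariate) analysis
#'
#' Fits the transition model once per single covariate and collects one
#' net-forward-OR row per covariate per departing stage.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return the combined net-OR data.frame, invisibly.
#' @export
run_univariate <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out <- ensure_outdir(cfg)
  est <- cfg$estimation
  ds <- pipeline_dataset(cfg)
  spec <- pipeline_spec(cfg, ds)
  if (!length(spec$covariates)) {
    stop("univariate analysis needs at least one covariate", call. = FALSE)
  }
  rows <- list()
  for (cv in spec$covariates) {
    sub_spec <- model_spec(covariates = cv, types = spec$types[[cv]],
                           scaling = spec$scaling[[cv]],
                           constraint = spec$constraint)
    fit <- fit_mle(ds, sub_spec,
                   use_intermediate_visit = est$use_intermediate_visit,
                   restarts = est$restarts, seed = est$seed)
    tab <- fit$interval_table
    tab <- tab[tab$quantity == "net_or", , drop = FALSE]
    tab$scaling <- unname(fit$spec$scaling[tab$covariate])
    rows[[cv]] <- tab
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  pipeline_log(cfg, sprintf("univariate: %d covariates x 3 departing stages",
                            length(spec$covariates)))
  utils::write.csv(res, file.path(out, "univariate_netor.csv"),
                   row.names = FALSE)
  invisible(res)
}
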