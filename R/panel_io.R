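#' Construct a stage panel dataset
#'
#' A panel dataset holds long-format observations of subjects moving through
#' the four stages of change, observed at a handful of discrete times
#' measured in integer model cycles (1 cycle = `cycle_length_weeks` weeks,
#' 2 by default, so a two-month follow-up sits at cycle 4).  Baseline
#' covariates are carried on every row of a subject and must be constant
#' within subject.
#'
#' @param data data.frame with columns `subject_id`, `group`, `time`
#'   (non-negative integer cycles), `stage` (code 1-4 or label), plus one
#'   column per schema covariate.
#' @param schema covariate schema: a character vector of covariate names
#'   with a `types` attribute, or a data.frame with columns `name`, `type`
#'   (`"continuous"` or `"binary"`), or a named character vector of types.
#'   `NULL` means no covariates.
#' @param cycle_length_weeks length of one model cycle in weeks.
#' @return An object of class `panel_dataset`: list with elements `data`
#'   (long data.frame, stage stored as integer code, sorted by subject then
#'   time), `schema` (data.frame name/type) and `cycle_length_weeks`.
#' @seealso [read_panel_csv()], [validate_panel()], [simulate_cohort()]
#' @export
panel_dataset <- function(data, schema = NULL, cycle_length_weeks = 2) {
  stopifnot(is.data.frame(data))
  schema <- as_covariate_schema(schema)
  required <- c("subject_id", "group", "time", "stage")
  missing_cols <- setdiff(c(required, schema$name), names(data))
  if (length(missing_cols)) {
    stop("panel data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, c(required, schema$name), drop = FALSE]
  data$subject_id <- as.character(data$subject_id)
  data$group <- as.character(data$group)
  if (nrow(data)) {
    if (!is.numeric(data$time) || any(!is.finite(data$time))) {
      stop("observation times must be finite numbers", call. = FALSE)
    }
    off <- which(abs(data$time - round(data$time)) > 1e-8 | data$time < 0)
    if (length(off)) {
      stop("observation times must be non-negative integer cycles; offending row(s): ",
           paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
    }
    data$time <- as.integer(round(data$time))
    data$stage <- stage_code(data$stage)
    data <- data[order(data$subject_id, data$time), , drop = FALSE]
    rownames(data) <- NULL
  } else {
    data$time <- integer(0)
    data$stage <- integer(0)
  }
  structure(
    list(data = data, schema = schema,
         cycle_length_weeks = as.numeric(cycle_length_weeks)),
    class = "panel_dataset"
  )
}

as_covariate_schema <- function(schema) {
  if (is.null(schema)) {
    return(data.frame(name = character(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(schema)) {
    stopifnot(all(c("name", "type") %in% names(schema)))
    out <- data.frame(name = as.character(schema$name),
                      type = as.character(schema$type),
                      stringsAsFactors = FALSE)
  } else if (is.character(schema) && !is.null(names(schema)) &&
             all(nzchar(names(schema)))) {
    out <- data.frame(name = names(schema), type = unname(schema),
                      stringsAsFactors = FALSE)
  } else if (is.character(schema)) {
    types <- attr(schema, "types")
    if (is.null(types)) types <- rep("continuous", length(schema))
    out <- data.frame(name = as.character(schema), type = as.character(types),
                      stringsAsFactors = FALSE)
  } else {
    stop("cannot interpret covariate schema", call. = FALSE)
  }
  bad <- setdiff(out$type, c("continuous", "binary"))
  if (length(bad)) {
    stop("covariate types must be 'continuous' or 'binary', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(out$name)) stop("duplicate covariate names", call. = FALSE)
  out
}

#' @export
print.panel_dataset <- function(x, ...) {
  tab <- subject_table(x)
  cat("Stage panel dataset\n")
  cat("  subjects:", nrow(tab), " observations:", nrow(x$data), "\n")
  if (nrow(tab)) {
    cnt <- table(tab$group)
    cat("  groups:  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  }
  cat("  cycle length:", x$cycle_length_weeks, "weeks\n")
  if (nrow(x$schema)) {
    cat("  covariates:",
        paste(sprintf("%s (%s)", x$schema$name, x$schema$type), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-subject baseline table
#'
#' One row per subject with group and covariates (taken from the subject's
#' first observation row; covariates are baseline quantities).
#'
#' @param dataset a `panel_dataset`.
#' @return data.frame with `subject_id`, `group` and covariate columns.
#' @export
subject_table <- function(dataset) {
  stopifnot(inherits(dataset, "panel_dataset"))
  d <- dataset$data
  first <- !duplicated(d$subject_id)
  out <- d[first, c("subject_id", "group", dataset$schema$name), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consecutive observed transitions
#'
#' All consecutive observation pairs per subject, as used by the panel
#' likelihood: a subject observed at cycles 0, 1 and 4 contributes the pairs
#' (0 to 1, gap 1) and (1 to 4, gap 3).
#'
#' @param dataset a `panel_dataset`.
#' @param use_intermediate_visit if `FALSE`, each subject is collapsed to
#'   baseline and last observation only before forming pairs.
#' @return data.frame with `subject_id`, `from`, `to` (stage codes) and
#'   `gap` (integer cycles).
#' @export
observed_transitions <- function(dataset, use_intermediate_visit = TRUE) {
  stopifnot(inherits(dataset, "panel_dataset"))
  d <- dataset$data
  if (!nrow(d)) {
    return(data.frame(subject_id = character(0), from = integer(0),
                      to = integer(0), gap = integer(0)))
  }
  if (!use_intermediate_visit) {
    keep <- !duplicated(d$subject_id) | !duplicated(d$subject_id, fromLast = TRUE)
    d <- d[keep, , drop = FALSE]
  }
  same <- d$subject_id[-1] == d$subject_id[-nrow(d)]
  idx <- which(c(same, FALSE))
  data.frame(subject_id = d$subject_id[idx],
             from = d$stage[idx],
             to = d$stage[idx + 1L],
             gap = d$time[idx + 1L] - d$time[idx],
             stringsAsFactors = FALSE)
}

#' Validate a panel dataset
#'
#' Enumerates violations of the panel data model: duplicated or decreasing
#' observation times, missing baseline (first time not 0), observations
#' after action in a non-action stage (the absorbing assumption), covariates
#' varying within subject, and missing covariate values (reported but not
#' fatal; model fits drop those subjects as complete-case exclusions).
#'
#' @param dataset a `panel_dataset`.
#' @return data.frame with columns `subject_id`, `rule`, `message`; zero
#'   rows iff the dataset satisfies every invariant.
#' @export
validate_panel <- function(dataset) {
  stopifnot(inherits(dataset, "panel_dataset"))
  v <- list()
  add <- function(subject, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(subject_id = subject, rule = rule,
                                       message = message, stringsAsFactors = FALSE)
  }
  d <- dataset$data
  for (sid in unique(d$subject_id)) {
    rows <- d[d$subject_id == sid, , drop = FALSE]
    if (anyDuplicated(rows$time)) {
      add(sid, "duplicate_time",
          sprintf("duplicated observation time(s): %s",
                  paste(unique(rows$time[duplicated(rows$time)]), collapse = ", ")))
    }
    if (rows$time[1] != 0L) {
      add(sid, "no_baseline",
          sprintf("first observation at cycle %d, expected baseline at 0", rows$time[1]))
    }
    if (nrow(rows) > 1L) {
      st <- rows$stage[order(rows$time)]
      hit <- which(st == 4L)
      if (length(hit) && any(st[seq(min(hit), length(st))] != 4L)) {
        add(sid, "absorbing_violation",
            "observed in a non-action stage after an action observation; action is absorbing")
      }
    }
    if (length(unique(rows$group)) > 1L) {
      add(sid, "group_varies", "group changes within subject")
    }
    for (cv in dataset$schema$name) {
      vals <- rows[[cv]]
      if (anyNA(vals)) {
        add(sid, "missing_covariate", sprintf("missing value for covariate '%s'", cv))
      } else if (length(unique(vals)) > 1L) {
        add(sid, "covariate_varies",
            sprintf("covariate '%s' varies within subject", cv))
      }
    }
  }
  bin <- dataset$schema$name[dataset$schema$type == "binary"]
  for (cv in bin) {
    vals <- d[[cv]]
    bad <- vals[!is.na(vals) & !vals %in% c(0, 1)]
    if (length(bad)) {
      add("", "binary_not_01",
          sprintf("binary covariate '%s' has value(s) outside {0,1}: %s",
                  cv, paste(unique(bad), collapse = ", ")))
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(subject_id = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Read a long-format stage panel CSV
#'
#' Expects a comma-separated UTF-8 file with header and columns
#' `subject_id`, `group`, `time`, `stage`, plus one column per schema
#' covariate.  Stages may be given as codes 1-4 or labels
#' (case-insensitive).  Hard structural errors (unknown stage, duplicated
#' or decreasing times, non-integer cycle after unit conversion, a
#' non-action stage after action) abort the read; missing covariate values
#' do not (they are excluded from model fits as complete cases).
#'
#' @param path file path.
#' @param schema covariate schema, see [panel_dataset()].
#' @param time_unit `"cycles"` (default) or `"weeks"`; week times are
#'   divided by `cycle_length_weeks` and must land on integers.
#' @param cycle_length_weeks length of one model cycle in weeks.
#' @return a validated `panel_dataset`.
#' @export
read_panel_csv <- function(path, schema = NULL,
                           time_unit = c("cycles", "weeks"),
                           cycle_length_weeks = 2) {
  time_unit <- match.arg(time_unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("subject_id", "group", "time", "stage")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (time_unit == "weeks" && nrow(raw)) {
    cyc <- raw$time / cycle_length_weeks
    off <- which(abs(cyc - round(cyc)) > 1e-8)
    if (length(off)) {
      stop(sprintf(
        "time %s weeks (row %d) is not a whole number of %g-week cycles",
        raw$time[off[1]], off[1], cycle_length_weeks), call. = FALSE)
    }
    raw$time <- round(cyc)
  }
  dup <- duplicated(raw[, c("subject_id", "time")])
  if (any(dup)) {
    stop("duplicate (subject_id, time) row(s): row ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  ds <- panel_dataset(raw, schema = schema,
                      cycle_length_weeks = cycle_length_weeks)
  rep <- validate_panel(ds)
  fatal <- rep[rep$rule %in% c("absorbing_violation", "no_baseline",
                               "group_varies", "covariate_varies",
                               "binary_not_01"), , drop = FALSE]
  if (nrow(fatal)) {
    stop("invalid panel data in ", path, ":\n",
         paste(sprintf("  subject %s: %s", fatal$subject_id, fatal$message),
               collapse = "\n"), call. = FALSE)
  }
  ds
}

#' Write a stage panel dataset to CSV
#'
#' Writes the long format read by [read_panel_csv()] (times in cycles,
#' stages as integer codes); `read_panel_csv(write_panel_csv(d))` reproduces
#' `d` field for field.
#'
#' @param dataset a `panel_dataset`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "panel_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a panel dataset to a set of subjects
#'
#' @param dataset a `panel_dataset`.
#' @param subject_ids character vector of subject ids to keep; duplicates
#'   are allowed (each occurrence becomes a distinct resampled subject,
#'   which is what the subject-level bootstrap needs).
#' @return a `panel_dataset`.
#' @export
subset_panel <- function(dataset, subject_ids) {
  stopifnot(inherits(dataset, "panel_dataset"))
  d <- dataset$data
  pieces <- lapply(seq_along(subject_ids), function(i) {
    rows <- d[d$subject_id == subject_ids[i], , drop = FALSE]
    if (!nrow(rows)) stop("unknown subject_id: ", subject_ids[i], call. = FALSE)
    if (anyDuplicated(subject_ids)) {
      rows$subject_id <- sprintf("%s#%d", subject_ids[i], i)
    }
    rows
  })
  panel_dataset(do.call(rbind, pieces), schema = dataset$schema,
                cycle_length_weeks = dataset$cycle_length_weeks)
}
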