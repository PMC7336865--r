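# Two-sample descriptive comparisons (Table-1-style) and stage
# distributions / transition cross-tabulations.

#' Pooled-variance two-sample t-test
#'
#' Classic Student's t-test with pooled variance, computable either from
#' raw vectors (`pooled_t_test`) or from summary statistics
#' (`pooled_t_test_stats`); the two agree exactly on matching summaries.
#' Welch's unpooled version is available behind `welch = TRUE`.
#'
#' @param x,y numeric vectors of observations (each of length >= 2 with
#'   positive spread).
#' @param welch use the Welch (unpooled) statistic instead.
#' @return an object of class `htest` with `statistic` (t), `parameter`
#'   (df) and `p.value` (two-sided).
#' @export
pooled_t_test <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two observations per group", call. = FALSE)
  }
  pooled_t_test_stats(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y), welch = welch)
}

#' @rdname pooled_t_test
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summaries.
#' @export
pooled_t_test_stats <- function(mean1, sd1, n1, mean2, sd2, n2,
                                welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                 method = if (welch) "Welch two-sample t-test"
                          else "Pooled-variance two-sample t-test",
                 data.name = "group summaries"),
            class = "htest")
}

#' Pearson chi-squared test on a count table
#'
#' Pearson X^2 with df = (r-1)(c-1) and, by default, no continuity
#' correction (matching the generic chi-squared test of group comparisons;
#' Yates' correction for 2x2 tables is available behind `correct = TRUE`).
#'
#' @param table matrix of non-negative counts with at least two non-empty
#'   rows and columns.
#' @param correct apply the continuity correction (2x2 only).
#' @return an object of class `htest`.
#' @export
chi_squared_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (sum(rowSums(table) > 0) < 2 || sum(colSums(table) > 0) < 2) {
    stop("need at least two non-empty rows and columns", call. = FALSE)
  }
  suppressWarnings(stats::chisq.test(table, correct = correct))
}

#' Baseline stage distribution of a group
#'
#' Counts and percentages of the stages occupied at cycle 0.
#'
#' @param dataset a `panel_dataset`.
#' @param group group label present in the dataset.
#' @return data.frame with `stage`, `count`, `pct` (percent of the group,
#'   rounded to 1 decimal).  Counts sum to the group size.
#' @export
baseline_stage_distribution <- function(dataset, group) {
  stopifnot(inherits(dataset, "panel_dataset"))
  d <- dataset$data
  rows <- d[d$group == group & d$time == 0L, , drop = FALSE]
  if (!nrow(rows)) stop("no baseline observations for group: ", group,
                        call. = FALSE)
  cnt <- tabulate(rows$stage, nbins = 4L)
  data.frame(stage = stage_levels(), count = cnt,
             pct = round(100 * cnt / nrow(rows), 1),
             stringsAsFactors = FALSE)
}

#' Stage-change cross-tabulation between two visits
#'
#' 4x4 table of (stage at `from_time`, stage at `to_time`) over the
#' subjects of a group observed at both times; row sums count the subjects
#' occupying each stage at `from_time`.
#'
#' @param dataset a `panel_dataset`.
#' @param group group label.
#' @param from_time,to_time observation cycles, `from_time < to_time`.
#' @return 4x4 integer matrix with stage dimnames.
#' @export
transition_crosstab <- function(dataset, group, from_time = 0, to_time = 4) {
  stopifnot(inherits(dataset, "panel_dataset"), from_time < to_time)
  d <- dataset$data[dataset$data$group == group, , drop = FALSE]
  a <- d[d$time == from_time, c("subject_id", "stage")]
  b <- d[d$time == to_time, c("subject_id", "stage")]
  both <- merge(a, b, by = "subject_id", suffixes = c("_from", "_to"))
  if (!nrow(both)) {
    stop(sprintf("no subject of group %s observed at both cycles %s and %s",
                 group, from_time, to_time), call. = FALSE)
  }
  out <- matrix(0L, 4, 4, dimnames = list(stage_levels(), stage_levels()))
  for (r in seq_len(nrow(both))) {
    out[both$stage_from[r], both$stage_to[r]] <-
      out[both$stage_from[r], both$stage_to[r]] + 1L
  }
  out
}

#' Two-group descriptive comparison
#'
#' Per covariate: mean +/- SD and a pooled t-test for continuous
#' covariates, level counts/percentages and a Pearson chi-squared test for
#' binary ones; plus the baseline stage distribution of each group.
#'
#' @param dataset a `panel_dataset` with exactly two groups.
#' @return object of class `group_summary`: `covariates` (data.frame of
#'   per-covariate summaries and tests), `baseline` (named list of
#'   [baseline_stage_distribution()] tables) and `n` (group sizes).
#' @export
group_summary <- function(dataset) {
  stopifnot(inherits(dataset, "panel_dataset"))
  tab <- subject_table(dataset)
  groups <- sort(unique(tab$group))
  if (length(groups) != 2) {
    stop("group_summary needs exactly two groups, found ",
         length(groups), call. = FALSE)
  }
  g1 <- tab[tab$group == groups[1], , drop = FALSE]
  g2 <- tab[tab$group == groups[2], , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(dataset$schema))) {
    cv <- dataset$schema$name[i]
    type <- dataset$schema$type[i]
    x1 <- g1[[cv]][!is.na(g1[[cv]])]
    x2 <- g2[[cv]][!is.na(g2[[cv]])]
    if (type == "continuous") {
      ht <- tryCatch(pooled_t_test(x1, x2), error = function(e) NULL)
      rows[[cv]] <- data.frame(
        covariate = cv, type = type,
        summary1 = sprintf("%.2f ± %.2f (n=%d)", mean(x1), stats::sd(x1),
                           length(x1)),
        summary2 = sprintf("%.2f ± %.2f (n=%d)", mean(x2), stats::sd(x2),
                           length(x2)),
        statistic = if (is.null(ht)) NA_real_ else unname(ht$statistic),
        df = if (is.null(ht)) NA_real_ else unname(ht$parameter),
        p_value = if (is.null(ht)) NA_real_ else ht$p.value,
        test = "pooled t", stringsAsFactors = FALSE)
    } else {
      counts <- rbind(c(sum(x1 == 1), sum(x1 == 0)),
                      c(sum(x2 == 1), sum(x2 == 0)))
      ht <- tryCatch(chi_squared_test(counts), error = function(e) NULL)
      rows[[cv]] <- data.frame(
        covariate = cv, type = type,
        summary1 = sprintf("%d/%d (%.1f%%)", sum(x1 == 1), length(x1),
                           100 * mean(x1 == 1)),
        summary2 = sprintf("%d/%d (%.1f%%)", sum(x2 == 1), length(x2),
                           100 * mean(x2 == 1)),
        statistic = if (is.null(ht)) NA_real_ else unname(ht$statistic),
        df = if (is.null(ht)) NA_real_ else unname(ht$parameter),
        p_value = if (is.null(ht)) NA_real_ else ht$p.value,
        test = "chi-squared", stringsAsFactors = FALSE)
    }
  }
  cov_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(0))
  rownames(cov_tab) <- NULL
  baseline <- lapply(stats::setNames(groups, groups), function(g) {
    baseline_stage_distribution(dataset, g)
  })
  structure(list(covariates = cov_tab, baseline = baseline,
                 groups = groups,
                 n = stats::setNames(c(nrow(g1), nrow(g2)), groups)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group comparison: %s (n=%d) vs %s (n=%d)\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2]))
  if (nrow(x$covariates)) {
    tab <- x$covariates
    tab$statistic <- round(tab$statistic, 3)
    tab$p_value <- signif(tab$p_value, 3)
    print(tab, row.names = FALSE)
  }
  for (g in names(x$baseline)) {
    cat("\nBaseline stages,", g, "\n")
    print(x$baseline[[g]], row.names = FALSE)
  }
  invisible(x)
}
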