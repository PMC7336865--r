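#' Four-state transition matrices
#'
#' A one-cycle transition matrix is a 4x4 row-stochastic matrix over the
#' ordered stages, with the action row fixed at (0, 0, 0, 1): action is
#' absorbing.  `transition_matrix()` validates and classes a matrix;
#' `check_transition_matrix()` throws on violation.
#'
#' @param entries 4x4 numeric matrix, rows = source stage, columns =
#'   destination stage in stage-code order.
#' @param tol tolerance for the row-sum check.
#' @return `transition_matrix()` returns the validated matrix with class
#'   `transition_matrix`.
#' @export
transition_matrix <- function(entries, tol = 1e-12) {
  check_transition_matrix(entries, tol = tol)
  structure(entries, class = c("transition_matrix", "matrix"),
            dimnames = list(stage_levels(), stage_levels()))
}

#' @rdname transition_matrix
#' @param P matrix to check.
#' @export
check_transition_matrix <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || !all(dim(P) == c(4L, 4L)) || !is.numeric(P)) {
    stop("a transition matrix must be a numeric 4x4 matrix", call. = FALSE)
  }
  if (any(!is.finite(P)) || any(P < -tol) || any(P > 1 + tol)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > max(tol, 1e-12))) {
    stop(sprintf("rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1))),
         call. = FALSE)
  }
  if (!identical(as.numeric(P[4, ]), c(0, 0, 0, 1))) {
    stop("action row must be exactly (0, 0, 0, 1): action is absorbing",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Matrix power of a transition matrix
#'
#' `P^k` bridges a gap of `k` cycles between two observations
#' (Chapman-Kolmogorov); `P^0` is the identity.  Computed by repeated
#' squaring.
#'
#' @param P 4x4 transition matrix.
#' @param k non-negative integer power.
#' @return 4x4 matrix `P` raised to the `k`-th power.
#' @export
matrix_power <- function(P, k) {
  check_transition_matrix(P, tol = 1e-9)
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 0) {
    stop("k must be a single non-negative integer", call. = FALSE)
  }
  k <- as.integer(k)
  out <- diag(4)
  base <- unclass(P)
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2L
  }
  dimnames(out) <- list(stage_levels(), stage_levels())
  out
}

#' Brute-force k-step transition probability
#'
#' Independent oracle for [matrix_power()]: sums, over all `4^(k-1)`
#' intermediate stage paths, the product of one-step probabilities from
#' `source` to `dest` in `k` steps.  Guarded at `k <= 8` against
#' combinatorial blow-up.
#'
#' @param P 4x4 transition matrix.
#' @param source,dest stage code or label.
#' @param k positive integer number of steps, at most 8.
#' @return the probability of being in `dest` after `k` steps from `source`.
#' @export
path_enumeration_prob <- function(P, source, dest, k) {
  check_transition_matrix(P, tol = 1e-9)
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 1 || k > 8) {
    stop("k must be a single integer in 1..8", call. = FALSE)
  }
  s <- stage_code(source)
  d <- stage_code(dest)
  k <- as.integer(k)
  if (k == 1L) return(unname(P[s, d]))
  mids <- as.matrix(expand.grid(rep(list(1:4), k - 1L)))
  total <- 0
  for (r in seq_len(nrow(mids))) {
    path <- c(s, mids[r, ], d)
    prob <- 1
    for (i in seq_len(k)) prob <- prob * P[path[i], path[i + 1L]]
    total <- total + prob
  }
  unname(total)
}

#' Panel log-likelihood of a stage dataset
#'
#' Conditional on each subject's baseline stage, the log-likelihood is the
#' sum over consecutive observation pairs of `log [P_subject^gap]{from,to}`,
#' where `P_subject` is the subject's one-cycle matrix and `gap` the integer
#' cycle gap (multi-cycle gaps are bridged by matrix powers).  Baseline
#' stage distributions contribute no term.  If an observed transition has
#' probability zero the function returns `-Inf` (with attribute
#' `zero_transitions` counting the offending pairs) rather than flooring:
#' in the logistic parameterisation all entries are positive, so `-Inf` can
#' only arise from user-supplied degenerate matrices.
#'
#' @param dataset a `panel_dataset`.
#' @param matrix_provider function taking one row of [subject_table()] (a
#'   one-row data.frame with group and covariates) and returning that
#'   subject's one-cycle `transition_matrix`; or a single matrix used for
#'   every subject.
#' @param use_intermediate_visit if `FALSE`, only baseline and last
#'   observation of each subject enter the likelihood.
#' @return log-likelihood value (scalar; possibly `-Inf`).
#' @export
panel_log_likelihood <- function(dataset, matrix_provider,
                                 use_intermediate_visit = TRUE) {
  stopifnot(inherits(dataset, "panel_dataset"))
  if (is.matrix(matrix_provider)) {
    M <- matrix_provider
    matrix_provider <- function(subject) M
  }
  stopifnot(is.function(matrix_provider))
  trans <- observed_transitions(dataset, use_intermediate_visit)
  if (!nrow(trans)) return(0)
  subjects <- subject_table(dataset)
  total <- 0
  n_zero <- 0L
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    tr <- trans[trans$subject_id == sid, , drop = FALSE]
    if (!nrow(tr)) next
    P <- matrix_provider(subjects[i, , drop = FALSE])
    check_transition_matrix(P, tol = 1e-9)
    powers <- list()
    for (j in seq_len(nrow(tr))) {
      k <- tr$gap[j]
      key <- as.character(k)
      if (is.null(powers[[key]])) powers[[key]] <- matrix_power(P, k)
      p <- powers[[key]][tr$from[j], tr$to[j]]
      if (p <= 0) {
        n_zero <- n_zero + 1L
        total <- -Inf
      } else if (is.finite(total)) {
        total <- total + log(p)
      }
    }
  }
  if (n_zero > 0L) attr(total, "zero_transitions") <- n_zero
  total
}
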