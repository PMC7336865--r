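# Model fitting: maximum likelihood with Wald intervals, subject-level
# bootstrap, and random-walk Metropolis posterior sampling.  All three share
# the packed-data representation and the C++ likelihood/gradient.

# ---- packed fit data ----------------------------------------------------

# Resolve covariates (deriving `hcp` from the group column if absent),
# apply complete-case exclusion, resolve scaling anchors, and pack the
# design matrix and transition terms for the C++ core.
build_fit_data <- function(dataset, spec, use_intermediate_visit = TRUE) {
  stopifnot(inherits(dataset, "panel_dataset"), inherits(spec, "model_spec"))
  subjects <- subject_table(dataset)
  p <- length(spec$covariates)
  if (p > 0L) {
    for (cv in spec$covariates) {
      if (!cv %in% names(subjects)) {
        if (identical(cv, "hcp")) {
          subjects$hcp <- as.integer(tolower(subjects$group) == "hcp")
        } else {
          stop("covariate not present in dataset: ", cv, call. = FALSE)
        }
      }
    }
    cc <- stats::complete.cases(subjects[, spec$covariates, drop = FALSE])
  } else {
    cc <- rep(TRUE, nrow(subjects))
  }
  used <- subjects[cc, , drop = FALSE]
  n_excluded <- sum(!cc)
  if (n_excluded > 0L) {
    message(n_excluded, " subject(s) excluded from the fit (missing covariates)")
  }
  centers <- scales <- stats::setNames(numeric(p), spec$covariates)
  if (p > 0L) {
    for (cv in spec$covariates) {
      sc <- spec$scaling[[cv]]
      if (!is.null(spec$centers) && cv %in% names(spec$centers)) {
        centers[cv] <- spec$centers[[cv]]
        scales[cv] <- spec$scales[[cv]]
      } else if (sc == "standardize") {
        centers[cv] <- mean(used[[cv]])
        scales[cv] <- stats::sd(used[[cv]])
        if (!is.finite(scales[cv]) || scales[cv] <= 0) scales[cv] <- 1
      } else if (sc == "per_decade") {
        centers[cv] <- mean(used[[cv]])
        scales[cv] <- 10
      } else {
        centers[cv] <- 0
        scales[cv] <- 1
      }
    }
    X <- sapply(spec$covariates, function(cv) {
      (used[[cv]] - centers[[cv]]) / scales[[cv]]
    })
    X <- matrix(as.numeric(X), nrow = nrow(used), ncol = p,
                dimnames = list(NULL, spec$covariates))
  } else {
    X <- matrix(0, nrow(used), 0)
  }
  spec$centers <- centers
  spec$scales <- scales
  trans <- observed_transitions(dataset, use_intermediate_visit)
  trans <- trans[trans$subject_id %in% used$subject_id, , drop = FALSE]
  terms <- cbind(match(trans$subject_id, used$subject_id),
                 trans$from, trans$to, trans$gap)
  storage.mode(terms) <- "integer"
  from_counts <- tabulate(trans$from, nbins = 4L)
  nonidentified <- which(from_counts[1:3] == 0L)
  free <- free_param_mask(spec, nonidentified)
  list(spec = spec, X = X, terms = terms, used_ids = used$subject_id,
       n_used = nrow(used), n_excluded = n_excluded,
       n_transitions = nrow(trans), from_counts = from_counts,
       nonidentified = nonidentified, free = free)
}

# logical mask over theta marking free (estimated) entries; parameters of
# stages with no observed departures are fixed at 0 and flagged
free_param_mask <- function(spec, nonidentified) {
  p <- length(spec$covariates)
  free <- rep(TRUE, n_theta(spec))
  if (!length(nonidentified)) return(free)
  ai <- alpha_index()
  free[1:9][ai[, 1] %in% nonidentified] <- FALSE
  if (p > 0L) {
    for (s in nonidentified) free[9L + (s - 1L) * p + seq_len(p)] <- FALSE
    if (spec$constraint == "free") {
      for (s in intersect(nonidentified, 2:3)) {
        free[9L + 3L * p + (s - 2L) * p + seq_len(p)] <- FALSE
      }
    }
  }
  free
}

expand_theta <- function(par, free) {
  theta <- numeric(length(free))
  theta[free] <- par
  theta
}

# ---- reported quantities ------------------------------------------------

# Named vector of the reportable transforms of theta: the 12 transient
# entries of the one-cycle matrix at the reference covariate profile
# (all scaled covariates at 0), plus one net forward OR per covariate per
# departing stage.
fit_quantities <- function(theta, spec) {
  params <- unpack_params(theta, spec)
  P <- transition_matrix_for(rep(0, length(spec$covariates)), params, spec)
  lv <- stage_levels()
  out <- numeric(0)
  for (s in 1:3) for (d in 1:4) {
    out[sprintf("prob[%s->%s]", lv[s], lv[d])] <- P[s, d]
  }
  for (cv in spec$covariates) for (s in 1:3) {
    out[sprintf("netor[%s:%s]", cv, lv[s])] <-
      net_odds_ratio(params, spec, cv, s)
  }
  out
}

quantity_frame <- function(est, lower, upper, method, spec) {
  nm <- names(est)
  lv <- stage_levels()
  kind <- ifelse(startsWith(nm, "prob"), "transition_prob", "net_or")
  src <- dst <- cov <- rep(NA_character_, length(nm))
  pm <- regmatches(nm, regexec("^prob\\[(.+)->(.+)\\]$", nm))
  om <- regmatches(nm, regexec("^netor\\[(.+):(.+)\\]$", nm))
  for (i in seq_along(nm)) {
    if (kind[i] == "transition_prob") {
      src[i] <- pm[[i]][2]; dst[i] <- pm[[i]][3]
    } else {
      cov[i] <- om[[i]][2]; src[i] <- om[[i]][3]
    }
  }
  out <- data.frame(quantity = kind, source = src, destination = dst,
                    covariate = cov, estimate = unname(est),
                    lower = unname(lower), upper = unname(upper),
                    method = method, stringsAsFactors = FALSE)
  # probabilities and their bounds live in [0, 1]
  pr <- out$quantity == "transition_prob"
  out$lower[pr] <- pmax(out$lower[pr], 0)
  out$upper[pr] <- pmin(out$upper[pr], 1)
  rownames(out) <- NULL
  out
}

# indices (into theta) and signs of log net OR = beta^F_sj - beta^B_sj
netor_contrast <- function(spec, covariate, s) {
  p <- length(spec$covariates)
  j <- match(covariate, spec$covariates)
  idx <- 9L + (s - 1L) * p + j
  if (spec$constraint == "antisymmetric") {
    return(list(idx = idx, w = 2))
  }
  if (s == 1L) return(list(idx = idx, w = 1))
  list(idx = c(idx, 9L + 3L * p + (s - 2L) * p + j), w = c(1, -1))
}

# ---- maximum likelihood -------------------------------------------------

#' Fit the transition regression model by maximum likelihood
#'
#' Maximises the panel log-likelihood (consecutive-pair terms, multi-cycle
#' gaps bridged by matrix powers) over the intercepts and direction-level
#' covariate coefficients, using BFGS with the analytic gradient and
#' `restarts` seeded random starts drawn from N(0, 0.5^2); ties are broken
#' by highest log-likelihood, then smallest gradient norm.  Wald 95%
#' intervals come from the inverse observed information, with the delta
#' method for reference-profile transition probabilities and (on the log
#' scale) for net forward odds ratios.
#'
#' Subjects with missing covariate values are excluded (complete-case) and
#' counted in `n_excluded`.  Departing stages with no observed transitions
#' have their parameters fixed at 0 and flagged non-identified; their
#' intervals are reported as `NA`.
#'
#' @param dataset a `panel_dataset`.
#' @param spec a [model_spec()]; an empty covariate list gives the
#'   groupwise (intercept-only) model.
#' @param use_intermediate_visit include intermediate visits (e.g. the
#'   2-week reassessment of a three-visit arm) as conditionally independent
#'   Markov terms (`TRUE`, default) or collapse each subject to baseline
#'   and endpoint (`FALSE`).
#' @param restarts number of random starts.
#' @param seed integer seed for the random starts.
#' @param ridge optional ridge penalty `lambda * ||beta||^2` on covariate
#'   coefficients (default 0); reported in the result when active.
#' @param maxit BFGS iteration cap per start.
#' @param start optional full theta vector used as the only start.
#' @return an object of class `stage_fit`: parameter estimates (`params`),
#'   `loglik`, `interval_table`, `vcov` (free parameters), `convergence`
#'   diagnostics, and complete-case accounting (`n_used`, `n_excluded`).
#' @export
fit_mle <- function(dataset, spec = model_spec(), use_intermediate_visit = TRUE,
                    restarts = 5, seed = 1, ridge = 0, maxit = 500,
                    start = NULL) {
  fd <- build_fit_data(dataset, spec, use_intermediate_visit)
  if (fd$n_transitions == 0L) {
    stop("no observed transitions: nothing to fit", call. = FALSE)
  }
  spec <- fd$spec
  p <- length(spec$covariates)
  qf <- sum(fd$free)
  negll <- function(par) {
    -cpp_panel_loglik(expand_theta(par, fd$free), fd$X, fd$terms, p,
                      spec$constraint == "antisymmetric", ridge)
  }
  neggr <- function(par) {
    g <- cpp_panel_loglik_grad(expand_theta(par, fd$free), fd$X, fd$terms, p,
                               spec$constraint == "antisymmetric", ridge)
    -g$gradient[fd$free]
  }
  starts <- if (!is.null(start)) {
    list(start[fd$free])
  } else {
    withr::with_seed(seed, lapply(seq_len(restarts),
                                  function(i) stats::rnorm(qf, 0, 0.5)))
  }
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      stats::optim(s0, negll, neggr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    gn <- sqrt(sum(neggr(res$par)^2))
    if (is.null(best) || res$value < best$value - 1e-9 ||
        (abs(res$value - best$value) <= 1e-9 && gn < best$gn)) {
      best <- res
      best$gn <- gn
    }
  }
  if (is.null(best)) {
    stop("optimisation failed from every start", call. = FALSE)
  }
  theta <- expand_theta(best$par, fd$free)
  params <- unpack_params(theta, spec)
  loglik <- -best$value
  boundary <- any(abs(best$par) > 8)
  vc <- tryCatch({
    H <- stats::optimHess(best$par, negll, neggr)
    V <- solve(H)
    if (any(!is.finite(V)) || any(diag(V) < 0)) NULL else V
  }, error = function(e) NULL)
  est <- fit_quantities(theta, spec)
  se <- wald_quantity_se(best$par, fd, vc, ridge)
  z <- stats::qnorm(0.975)
  lower <- upper <- rep(NA_real_, length(est))
  names(lower) <- names(upper) <- names(est)
  pr <- startsWith(names(est), "prob")
  lower[pr] <- est[pr] - z * se[pr]
  upper[pr] <- est[pr] + z * se[pr]
  # net ORs: Wald on the log scale
  lo <- log(est[!pr])
  lower[!pr] <- exp(lo - z * se[!pr])
  upper[!pr] <- exp(lo + z * se[!pr])
  blank_nonidentified <- function(v) {
    for (s in fd$nonidentified) {
      v[grepl(sprintf("\\[%s->", stage_levels()[s]), names(v))] <- NA_real_
      v[grepl(sprintf(":%s\\]$", stage_levels()[s]), names(v))] <- NA_real_
    }
    v
  }
  lower <- blank_nonidentified(lower)
  upper <- blank_nonidentified(upper)
  structure(list(
    params = params, spec = spec, loglik = loglik,
    interval_table = quantity_frame(est, lower, upper, "wald", spec),
    vcov = vc, free = fd$free, theta = theta, ridge = ridge,
    convergence = list(
      converged = best$convergence == 0 && is.finite(loglik),
      code = best$convergence, gradient_norm = best$gn,
      restarts = length(starts), boundary = boundary,
      nonidentified_states = fd$nonidentified),
    n_used = fd$n_used, n_excluded = fd$n_excluded,
    n_transitions = fd$n_transitions, method = "mle"),
    class = "stage_fit")
}

# delta-method standard errors for fit_quantities: numeric jacobian for the
# probabilities, analytic contrast for log net ORs (returned on log scale)
wald_quantity_se <- function(par, fd, vc, ridge) {
  spec <- fd$spec
  est <- fit_quantities(expand_theta(par, fd$free), spec)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (is.null(vc)) return(se)
  pr <- which(startsWith(names(est), "prob"))
  h <- 1e-6
  J <- matrix(0, length(pr), length(par))
  for (j in seq_along(par)) {
    up <- dn <- par
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    J[, j] <- (fit_quantities(expand_theta(up, fd$free), spec)[pr] -
                 fit_quantities(expand_theta(dn, fd$free), spec)[pr]) / (2 * h)
  }
  v <- rowSums((J %*% vc) * J)
  se[pr] <- sqrt(pmax(v, 0))
  full_to_free <- cumsum(fd$free)
  for (cv in spec$covariates) for (s in 1:3) {
    nm <- sprintf("netor[%s:%s]", cv, stage_levels()[s])
    ct <- netor_contrast(spec, cv, s)
    if (!all(fd$free[ct$idx])) next
    fi <- full_to_free[ct$idx]
    se[nm] <- sqrt(max(0, drop(t(ct$w) %*% vc[fi, fi, drop = FALSE] %*% ct$w)))
  }
  se
}

#' @export
print.stage_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Stage transition fit (%s), log-likelihood %.4f\n",
              x$method, x$loglik))
  cat(sprintf("  subjects used %d (excluded %d), transition pairs %d\n",
              x$n_used, x$n_excluded, x$n_transitions))
  if (!is.null(x$convergence)) {
    cat(sprintf("  converged: %s", x$convergence$converged))
    if (isTRUE(x$convergence$boundary)) cat("  [boundary solution]")
    if (length(x$convergence$nonidentified_states)) {
      cat("  [non-identified departures from stage(s) ",
          paste(x$convergence$nonidentified_states, collapse = ","), "]",
          sep = "")
    }
    cat("\n")
  }
  if (!is.null(x$ridge) && x$ridge > 0) {
    cat(sprintf("  ridge penalty active: lambda = %g\n", x$ridge))
  }
  scl <- x$spec$scaling
  if (length(scl)) {
    cat("  covariate scaling:",
        paste(sprintf("%s=%s", names(scl), scl), collapse = ", "), "\n")
  }
  tab <- x$interval_table
  tab$estimate <- round(tab$estimate, digits)
  tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Groupwise (intercept-only) transition matrices per arm
#'
#' Fits the intercept-only model separately in each group, giving one
#' 4x4 one-cycle matrix per arm with 95% intervals; the action row is fixed
#' at (0, 0, 0, 1) by construction.  With `interval = "posterior"` (the
#' default, mirroring the credible-interval vocabulary of such tables)
#' point estimates are entrywise posterior medians and intervals posterior
#' percentiles; with `"wald"` they are MLEs with delta-method intervals.
#' Diagonal (stay) entries are the row complements and get no interval.
#'
#' @param dataset a `panel_dataset` with a group column.
#' @param interval interval method, `"posterior"` or `"wald"`.
#' @param iterations,burn_in,seed posterior sampler settings (see
#'   [fit_posterior()]).
#' @param ... passed to [fit_mle()] (e.g. `use_intermediate_visit`).
#' @return object of class `groupwise_fit`: per group a list with `matrix`
#'   (point estimates), `lower`, `upper`, and the underlying `fit`.
#' @export
fit_groupwise <- function(dataset, interval = c("posterior", "wald"),
                          iterations = 4000, burn_in = 1000, seed = 1, ...) {
  interval <- match.arg(interval)
  stopifnot(inherits(dataset, "panel_dataset"))
  tab <- subject_table(dataset)
  groups <- sort(unique(tab$group))
  out <- list()
  for (g in groups) {
    sub <- subset_panel(dataset, tab$subject_id[tab$group == g])
    sub$schema <- as_covariate_schema(NULL)  # intercept-only: drop covariates
    sub$data <- sub$data[, c("subject_id", "group", "time", "stage")]
    fit <- if (interval == "posterior") {
      fit_posterior(sub, model_spec(), iterations = iterations,
                    burn_in = burn_in, seed = seed, ...)
    } else {
      fit_mle(sub, model_spec(), seed = seed, ...)
    }
    M <- L <- U <- matrix(NA_real_, 4, 4,
                          dimnames = list(stage_levels(), stage_levels()))
    it <- fit$interval_table
    pr <- it[it$quantity == "transition_prob", , drop = FALSE]
    for (r in seq_len(nrow(pr))) {
      s <- stage_code(pr$source[r]); d <- stage_code(pr$destination[r])
      M[s, d] <- pr$estimate[r]
      if (s != d) {
        L[s, d] <- pr$lower[r]
        U[s, d] <- pr$upper[r]
      }
    }
    M[4, ] <- c(0, 0, 0, 1)
    out[[g]] <- list(group = g, matrix = M, lower = L, upper = U, fit = fit,
                     interval = interval)
  }
  structure(list(groups = out, interval = interval), class = "groupwise_fit")
}

#' @export
print.groupwise_fit <- function(x, ...) {
  cat("Groupwise one-cycle transition matrices (interval method: ",
      x$interval, ")\n", sep = "")
  for (g in x$groups) {
    cat("\nGroup ", g$group, " (n = ", g$fit$n_used, "):\n", sep = "")
    M <- g$matrix
    for (s in 1:4) {
      row <- sapply(1:4, function(d) {
        if (s == 4 || s == d || is.na(g$lower[s, d])) {
          sprintf("%6.2f%%", 100 * M[s, d])
        } else {
          sprintf("%6.2f%% (%.2f, %.2f)", 100 * M[s, d],
                  100 * g$lower[s, d], 100 * g$upper[s, d])
        }
      })
      cat(sprintf("  %-16s %s\n", stage_levels()[s], paste(row, collapse = "  ")))
    }
  }
  invisible(x)
}

# ---- bootstrap ----------------------------------------------------------

#' Nonparametric bootstrap intervals
#'
#' Subject-level resampling with replacement; each replicate is refitted by
#' [fit_mle()] started at the full-data MLE, and 2.5/97.5 percentile
#' intervals are formed for every reported quantity.  Replicates that fail
#' or do not converge are dropped with a logged count; more than 20%
#' dropped raises a warning.
#'
#' @param dataset a `panel_dataset`.
#' @param spec a [model_spec()].
#' @param B number of bootstrap replicates (at least 50 for production use;
#'   smaller values are allowed for smoke tests).
#' @param seed integer seed; results are reproducible given `seed`.
#' @param use_intermediate_visit see [fit_mle()].
#' @param ... passed to the base [fit_mle()] call.
#' @return list with `interval_table`, the base `fit`, `B_used`,
#'   `n_dropped`, and `warning` (TRUE when >20% of replicates were dropped).
#' @export
bootstrap_intervals <- function(dataset, spec = model_spec(), B = 200,
                                seed = 1, use_intermediate_visit = TRUE, ...) {
  stopifnot(B >= 2)
  base <- fit_mle(dataset, spec, use_intermediate_visit = use_intermediate_visit,
                  seed = seed, ...)
  ids <- subject_table(dataset)$subject_id
  draws <- withr::with_seed(seed, {
    replicate(B, sample(ids, length(ids), replace = TRUE), simplify = FALSE)
  })
  qs <- list()
  n_dropped <- 0L
  for (b in seq_len(B)) {
    rep_fit <- tryCatch({
      boot <- subset_panel(dataset, draws[[b]])
      fit_mle(boot, spec, use_intermediate_visit = use_intermediate_visit,
              start = base$theta, seed = seed, ...)
    }, error = function(e) NULL)
    if (is.null(rep_fit) || !isTRUE(rep_fit$convergence$converged)) {
      n_dropped <- n_dropped + 1L
      next
    }
    qs[[length(qs) + 1L]] <- fit_quantities(rep_fit$theta, rep_fit$spec)
  }
  if (!length(qs)) stop("every bootstrap replicate failed", call. = FALSE)
  if (n_dropped > 0L) {
    message(n_dropped, " of ", B, " bootstrap replicate(s) dropped")
  }
  warn <- n_dropped > 0.2 * B
  if (warn) warning("more than 20% of bootstrap replicates were dropped")
  Q <- do.call(rbind, qs)
  est <- fit_quantities(base$theta, base$spec)
  lower <- apply(Q, 2, stats::quantile, probs = 0.025, names = FALSE)
  upper <- apply(Q, 2, stats::quantile, probs = 0.975, names = FALSE)
  list(interval_table = quantity_frame(est, lower, upper, "bootstrap", base$spec),
       fit = base, B_used = B - n_dropped, n_dropped = n_dropped,
       warning = warn)
}

# ---- posterior ----------------------------------------------------------

#' Posterior sampling by random-walk Metropolis
#'
#' Samples the model parameters under flat priors (the posterior is then
#' proportional to the panel likelihood), using a Gaussian random walk
#' whose proposal covariance is the Wald covariance of the MLE scaled by
#' `2.38^2/q` (falling back to a spherical proposal when the information
#' matrix is unusable), with step-size adaptation during burn-in targeting
#' about 25% acceptance.  Credible intervals are 2.5/97.5 posterior
#' percentiles; point estimates are posterior medians.  The absorbing
#' action row is not a parameter and equals (0, 0, 0, 1) in every draw.
#'
#' @param dataset a `panel_dataset`.
#' @param spec a [model_spec()].
#' @param iterations total Metropolis iterations (> `burn_in`).
#' @param burn_in iterations discarded (and used for adaptation).
#' @param seed integer seed; chains are reproducible given `seed`.
#' @param use_intermediate_visit see [fit_mle()].
#' @param start optional full theta start; defaults to the MLE.
#' @param ... passed to the internal [fit_mle()] call.
#' @return a `stage_fit` with `method = "posterior"`, posterior-median
#'   `params`, percentile `interval_table`, the retained `chain`, and
#'   `diagnostics` (acceptance rate post burn-in, split-chain Rhat per
#'   parameter and its maximum).  Acceptance outside 0.05-0.7 adds a
#'   warning to the diagnostics.
#' @export
fit_posterior <- function(dataset, spec = model_spec(), iterations = 6000,
                          burn_in = 1000, seed = 1,
                          use_intermediate_visit = TRUE, start = NULL, ...) {
  stopifnot(iterations > burn_in, burn_in >= 0)
  base <- fit_mle(dataset, spec, use_intermediate_visit = use_intermediate_visit,
                  seed = seed, start = start, ...)
  fd <- build_fit_data(dataset, base$spec, use_intermediate_visit)
  spec <- fd$spec
  p <- length(spec$covariates)
  antisym <- spec$constraint == "antisymmetric"
  qf <- sum(fd$free)
  ll_fun <- function(par) {
    cpp_panel_loglik(expand_theta(par, fd$free), fd$X, fd$terms, p, antisym, 0)
  }
  # proposal covariance: Wald vcov, regularised so that boundary directions
  # (singular or exploding information) still get a usable random walk
  prop_chol <- NULL
  if (!is.null(base$vcov)) {
    V <- base$vcov + diag(1e-8, qf)
    vd <- diag(V)
    shrink <- sqrt(pmin(vd, 25) / vd)  # cap proposal SD at 5 per coordinate
    V <- V * tcrossprod(shrink)
    prop_chol <- tryCatch(chol(V), error = function(e) NULL)
  }
  if (is.null(prop_chol)) prop_chol <- diag(0.5, qf)
  scale0 <- 2.38 / sqrt(qf)
  keep <- iterations - burn_in
  chain <- matrix(NA_real_, keep, qf)
  withr::with_seed(seed, {
    # start at the MLE, pulled back from boundary excursions: an empty cell
    # drives its intercept towards -Inf, where the flat-prior posterior is
    # improper and a chain started there cannot explore the plausible range
    cur <- pmin(pmax(base$theta[fd$free], -6), 6)
    cur_ll <- ll_fun(cur)
    sc <- scale0
    acc_post <- 0L
    acc_block <- 0L
    for (it in seq_len(iterations)) {
      prop <- cur + sc * drop(stats::rnorm(qf) %*% prop_chol)
      prop_ll <- ll_fun(prop)
      if (is.finite(prop_ll) &&
          log(stats::runif(1)) < prop_ll - cur_ll) {
        cur <- prop
        cur_ll <- prop_ll
        acc_block <- acc_block + 1L
        if (it > burn_in) acc_post <- acc_post + 1L
      }
      if (it <= burn_in && it %% 50L == 0L) {
        rate <- acc_block / 50
        # bounded adaptation: a flat or cliff-like likelihood must not
        # collapse (or explode) the step so far that the chain freezes
        sc <- min(max(sc * exp(rate - 0.25), scale0 / 20), scale0 * 20)
        acc_block <- 0L
      }
      if (it > burn_in) chain[it - burn_in, ] <- cur
    }
    acc_rate <- acc_post / keep
    med <- apply(chain, 2, stats::median)
    theta_med <- expand_theta(med, fd$free)
    Q <- t(apply(chain, 1, function(par) {
      fit_quantities(expand_theta(par, fd$free), spec)
    }))
    est <- apply(Q, 2, stats::median)
    lower <- apply(Q, 2, stats::quantile, probs = 0.025, names = FALSE)
    upper <- apply(Q, 2, stats::quantile, probs = 0.975, names = FALSE)
    names(est) <- names(lower) <- names(upper) <- colnames(Q)
    rhat <- split_chain_rhat(chain)
    warnings <- character(0)
    if (acc_rate < 0.05 || acc_rate > 0.7) {
      warnings <- c(warnings, sprintf(
        "acceptance rate %.3f outside [0.05, 0.7] after adaptation", acc_rate))
    }
    structure(list(
      params = unpack_params(theta_med, spec), spec = spec,
      loglik = ll_fun(med),
      interval_table = quantity_frame(est, lower, upper, "posterior", spec),
      chain = chain, free = fd$free, theta = theta_med,
      mle = base,
      convergence = list(converged = TRUE, boundary = FALSE,
                         nonidentified_states = fd$nonidentified),
      diagnostics = list(acceptance_rate = acc_rate, rhat = rhat,
                         rhat_max = max(rhat), proposal_scale = sc,
                         warnings = warnings),
      n_used = fd$n_used, n_excluded = fd$n_excluded,
      n_transitions = fd$n_transitions, method = "posterior"),
      class = "stage_fit")
  })
}

# potential scale reduction factor between the two halves of a single chain
split_chain_rhat <- function(chain) {
  n <- nrow(chain)
  half <- n %/% 2L
  a <- chain[seq_len(half), , drop = FALSE]
  b <- chain[seq.int(n - half + 1L, n), , drop = FALSE]
  sapply(seq_len(ncol(chain)), function(j) {
    m <- c(mean(a[, j]), mean(b[, j]))
    W <- mean(c(stats::var(a[, j]), stats::var(b[, j])))
    B <- half * stats::var(m)
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  })
}
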