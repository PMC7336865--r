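#' Specify the transition regression model
#'
#' The one-cycle transition matrix is parameterised by polytomous
#' (multinomial) logistic regression per transient source stage, with
#' *staying* as the reference outcome.  For source stage `s` and destination
#' `d != s` the linear predictor is
#' `eta_sd = alpha_sd + x . beta_s^F` when `d > s` (forward) and
#' `eta_sd = alpha_sd + x . beta_s^B` when `d < s` (backward), and
#' `p_sd = exp(eta_sd) / (1 + sum_d' exp(eta_sd'))`, `p_ss = 1 / (1 + sum)`.
#' Covariate effects are shared across destinations within a direction (one
#' forward and one backward coefficient per covariate per departing stage),
#' while intercepts stay destination-specific; with one OR reported per
#' covariate per departing stage, destination-specific slopes would not be
#' identifiable at a few hundred subjects.
#'
#' Backward coefficients for departures from precontemplation are
#' structurally undefined (there is no lower stage) and are fixed at 0.
#'
#' @param covariates character vector of covariate names (empty = intercept
#'   only, the groupwise model).  The name `"hcp"`, if absent from the data,
#'   is derived from the group column (1 = HCP arm).
#' @param types covariate types, `"continuous"` or `"binary"`; a single
#'   value is recycled.  Defaults to continuous.
#' @param scaling scaling per continuous covariate: `"standardize"`
#'   (default; centre at the analysis-sample mean, divide by its SD, so ORs
#'   are per SD), `"per_decade"` (centre at the mean, divide by 10) or
#'   `"none"` (raw units).  A single value is recycled; binary covariates
#'   are never scaled.
#' @param constraint `"free"` (separate forward and backward coefficients)
#'   or `"antisymmetric"` (`beta^B = -beta^F`, so a covariate that pushes
#'   forward pulls back equally little).
#' @param centers,scales optional named numeric vectors fixing the scaling
#'   anchors; when `NULL` they are resolved from the analysis sample at fit
#'   time.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(covariates = character(),
                       types = "continuous",
                       scaling = "standardize",
                       constraint = c("free", "antisymmetric"),
                       centers = NULL, scales = NULL) {
  constraint <- match.arg(constraint)
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates)) stop("duplicate covariate names", call. = FALSE)
  p <- length(covariates)
  types <- rep_len(as.character(types), p)
  bad <- setdiff(types, c("continuous", "binary"))
  if (length(bad)) stop("unknown covariate type(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  scaling <- rep_len(as.character(scaling), p)
  bad <- setdiff(scaling, c("none", "standardize", "per_decade"))
  if (length(bad)) stop("unknown scaling option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  scaling[types == "binary"] <- "none"
  names(types) <- names(scaling) <- covariates
  structure(list(covariates = covariates, types = types, scaling = scaling,
                 constraint = constraint, centers = centers, scales = scales,
                 reference_outcome = "stay"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Transition regression spec (reference outcome: stay)\n")
  if (!length(x$covariates)) {
    cat("  intercept-only (groupwise) model\n")
  } else {
    for (cv in x$covariates) {
      cat(sprintf("  %s: %s, scaling=%s\n", cv, x$types[[cv]], x$scaling[[cv]]))
    }
  }
  cat("  constraint:", x$constraint, "\n")
  invisible(x)
}

#' Transition model parameters
#'
#' @param alpha 3x4 numeric matrix of intercepts `alpha_sd` (rows = source
#'   stages 1-3, columns = destination stages 1-4); the diagonal (stay) is
#'   the reference and is ignored/stored as `NA`.
#' @param beta_forward 3xP matrix of forward coefficients (row = source
#'   stage, column = covariate), or `NULL` for the intercept-only model.
#' @param beta_backward 3xP matrix of backward coefficients; row 1 must be
#'   zero (no backward destination from precontemplation).  `NULL` under
#'   the antisymmetric constraint (derived as `-beta_forward`).
#' @param covariates optional covariate names for the beta columns.
#' @return object of class `model_params`.
#' @export
model_params <- function(alpha, beta_forward = NULL, beta_backward = NULL,
                         covariates = NULL) {
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(3L, 4L))) {
    stop("alpha must be a 3x4 matrix (sources 1-3 by destinations 1-4)",
         call. = FALSE)
  }
  off <- alpha
  diag_idx <- cbind(1:3, 1:3)
  off[diag_idx] <- 0
  if (any(!is.finite(off))) stop("alpha entries must be finite", call. = FALSE)
  alpha[diag_idx] <- NA_real_
  dimnames(alpha) <- list(stage_levels()[1:3], stage_levels())
  p <- if (is.null(beta_forward)) 0L else ncol(as.matrix(beta_forward))
  fix_beta <- function(b, what) {
    if (p == 0L) return(NULL)
    b <- as.matrix(b)
    if (!all(dim(b) == c(3L, p))) {
      stop(what, " must be a 3x", p, " matrix", call. = FALSE)
    }
    if (any(!is.finite(b))) stop(what, " entries must be finite", call. = FALSE)
    rownames(b) <- stage_levels()[1:3]
    if (!is.null(covariates)) colnames(b) <- covariates
    b
  }
  beta_forward <- fix_beta(beta_forward, "beta_forward")
  if (!is.null(beta_backward)) {
    beta_backward <- fix_beta(beta_backward, "beta_backward")
    if (p > 0L && any(beta_backward[1, ] != 0)) {
      stop("beta_backward[1, ] must be zero: no backward transition exists ",
           "from precontemplation", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, beta_forward = beta_forward,
                 beta_backward = beta_backward),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Transition model parameters\n")
  cat("intercepts (alpha, stay = reference):\n")
  print(round(x$alpha, 4))
  if (!is.null(x$beta_forward)) {
    cat("forward coefficients (beta^F):\n")
    print(round(x$beta_forward, 4))
    if (!is.null(x$beta_backward)) {
      cat("backward coefficients (beta^B):\n")
      print(round(x$beta_backward, 4))
    } else {
      cat("backward coefficients: -beta^F (antisymmetric constraint)\n")
    }
  }
  invisible(x)
}

# backward coefficients with constraint applied; always a 3xP matrix (row 1 zero)
effective_beta_backward <- function(params, spec = NULL) {
  p <- if (is.null(params$beta_forward)) 0L else ncol(params$beta_forward)
  if (p == 0L) return(NULL)
  bb <- params$beta_backward
  if (is.null(bb)) {
    if (!is.null(spec) && spec$constraint == "antisymmetric") {
      bb <- -params$beta_forward
    } else {
      bb <- matrix(0, 3, p, dimnames = dimnames(params$beta_forward))
    }
  }
  bb
}

#' One-cycle transition matrix for a covariate profile
#'
#' @param x numeric covariate vector, already on the model's scaled units
#'   (see [model_spec()]); ignored for intercept-only parameters.
#' @param params a [model_params()] object.
#' @param spec optional [model_spec()] (needed to apply the antisymmetric
#'   constraint when `beta_backward` is not stored).
#' @return a [transition_matrix()].
#' @export
transition_matrix_for <- function(x = numeric(), params, spec = NULL) {
  stopifnot(inherits(params, "model_params"))
  p <- if (is.null(params$beta_forward)) 0L else ncol(params$beta_forward)
  x <- as.numeric(x)
  if (length(x) != p) {
    stop(sprintf("covariate vector has length %d, model has %d covariate(s)",
                 length(x), p), call. = FALSE)
  }
  bb <- effective_beta_backward(params, spec)
  P <- matrix(0, 4, 4)
  for (s in 1:3) {
    eta <- numeric(4)  # eta for destinations; stay (d == s) has eta = 0
    for (d in setdiff(1:4, s)) {
      eta[d] <- params$alpha[s, d]
      if (p > 0L) {
        eta[d] <- eta[d] +
          sum(x * (if (d > s) params$beta_forward[s, ] else bb[s, ]))
      }
    }
    m <- max(eta, 0)
    w <- exp(eta - m)
    w[s] <- exp(-m)
    P[s, ] <- w / sum(w)
  }
  P[4, ] <- c(0, 0, 0, 1)
  transition_matrix(P)
}

#' Net forward odds ratio
#'
#' The single per-covariate, per-departing-stage summary of the balance
#' between a covariate's push on forward movement and its pull on backward
#' movement, both measured against staying: `exp(beta_s^F - beta_s^B)`.
#' Under the antisymmetric constraint this equals `exp(2 beta_s^F)`; when
#' backward effects are null (including structurally, from
#' precontemplation) it reduces to the plain forward odds ratio.  Reported
#' per unit of the *scaled* covariate (per SD under the default
#' standardisation).
#'
#' @param params a [model_params()] object.
#' @param spec the matching [model_spec()].
#' @param covariate covariate name.
#' @param source transient source stage (code 1-3 or label).
#' @return the net forward odds ratio (scalar).
#' @export
net_odds_ratio <- function(params, spec, covariate, source) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "model_spec"))
  j <- match(covariate, spec$covariates)
  if (is.na(j)) stop("unknown covariate: ", covariate, call. = FALSE)
  s <- stage_code(source)
  if (s == 4L) stop("source must be a transient stage", call. = FALSE)
  bf <- params$beta_forward[s, j]
  bb <- effective_beta_backward(params, spec)[s, j]
  unname(exp(bf - bb))
}

# ---- parameter vector packing (internal) -------------------------------
# theta layout: 9 alphas (source-major, destinations ascending, skipping the
# diagonal), then beta_forward source-major (3*p), then, for the free
# constraint, beta_backward for sources 2 and 3 (2*p).

alpha_index <- function() {
  out <- NULL
  for (s in 1:3) for (d in setdiff(1:4, s)) out <- rbind(out, c(s, d))
  out
}

n_theta <- function(spec) {
  p <- length(spec$covariates)
  9L + 3L * p + if (spec$constraint == "free") 2L * p else 0L
}

pack_params <- function(params, spec) {
  p <- length(spec$covariates)
  ai <- alpha_index()
  theta <- params$alpha[ai]
  if (p > 0L) {
    theta <- c(theta, as.vector(t(params$beta_forward)))
    if (spec$constraint == "free") {
      bb <- effective_beta_backward(params, spec)
      theta <- c(theta, as.vector(t(bb[2:3, , drop = FALSE])))
    }
  }
  unname(theta)
}

unpack_params <- function(theta, spec) {
  p <- length(spec$covariates)
  if (length(theta) != n_theta(spec)) {
    stop("theta has length ", length(theta), ", expected ", n_theta(spec),
         call. = FALSE)
  }
  alpha <- matrix(0, 3, 4)
  alpha[alpha_index()] <- theta[1:9]
  bf <- bb <- NULL
  if (p > 0L) {
    bf <- matrix(theta[9L + seq_len(3L * p)], nrow = 3, byrow = TRUE)
    colnames(bf) <- spec$covariates
    if (spec$constraint == "free") {
      bb <- matrix(0, 3, p)
      bb[2:3, ] <- matrix(theta[9L + 3L * p + seq_len(2L * p)],
                          nrow = 2, byrow = TRUE)
      colnames(bb) <- spec$covariates
    }
  }
  model_params(alpha, bf, bb, covariates = spec$covariates)
}
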