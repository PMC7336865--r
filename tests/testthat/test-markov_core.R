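test_that("transition matrix validation enforces the absorbing action row", {
  P <- matrix(0.25, 4, 4)
  expect_error(transition_matrix(P), "absorbing")
  P[4, ] <- c(0, 0, 0, 1)
  expect_silent(transition_matrix(P))
  P2 <- P
  P2[1, 1] <- 0.5
  expect_error(transition_matrix(P2), "sum to 1")
})

test_that("matrix_power handles k = 0 and the identity", {
  I4 <- diag(4)
  I4[4, ] <- c(0, 0, 0, 1)
  expect_equal(unname(matrix_power(I4, 7)), diag(4))
  withr::local_seed(11)
  P <- rand_tmatrix()
  expect_equal(unname(matrix_power(P, 0)), diag(4))
  expect_error(matrix_power(P, -1), "non-negative")
})

test_that("matrix_power agrees with the path-enumeration oracle", {
  P <- transition_matrix(rbind(c(0.5, 0.3, 0.1, 0.1),
                               c(0.2, 0.5, 0.2, 0.1),
                               c(0.1, 0.2, 0.5, 0.2),
                               c(0, 0, 0, 1)))
  P4 <- matrix_power(P, 4)
  for (s in 1:4) for (d in 1:4) {
    expect_equal(P4[s, d], path_enumeration_prob(P, s, d, 4),
                 tolerance = 1e-10)
  }
  # both directions on a random matrix, k = 3, all 16 pairs
  withr::local_seed(7)
  Q <- rand_tmatrix()
  Q3 <- matrix_power(Q, 3)
  for (s in 1:4) for (d in 1:4) {
    expect_equal(Q3[s, d], path_enumeration_prob(Q, s, d, 3),
                 tolerance = 1e-12)
  }
  expect_equal(path_enumeration_prob(Q, 2, 3, 1), unname(Q[2, 3]))
  expect_equal(path_enumeration_prob(Q, 4, 4, 5), 1)
  expect_equal(path_enumeration_prob(Q, 4, 1, 5), 0)
  expect_error(path_enumeration_prob(Q, 1, 2, 9), "1..8")
})

test_that("Chapman-Kolmogorov and structure preservation hold under powers", {
  withr::local_seed(2024)
  for (i in 1:25) {
    P <- rand_tmatrix()
    a <- sample(0:4, 1)
    b <- sample(0:4, 1)
    expect_equal(matrix_power(P, a + b),
                 matrix_power(P, a) %*% matrix_power(P, b),
                 tolerance = 1e-10)
    Pk <- matrix_power(P, max(a + b, 1))
    expect_equal(unname(rowSums(Pk)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(Pk[4, ]), c(0, 0, 0, 1))
    expect_true(all(Pk >= 0 & Pk <= 1))
  }
})

test_that("panel_log_likelihood sums log transition entries over gaps", {
  P <- transition_matrix(rbind(c(0.5, 0.3, 0.1, 0.1),
                               c(0.2, 0.42, 0.28, 0.1),
                               c(0.1, 0.2, 0.5, 0.2),
                               c(0, 0, 0, 1)))
  one <- make_panel(list(list(id = "a", times = c(0, 1), stages = c(2, 3))))
  expect_equal(panel_log_likelihood(one, P), log(0.28))

  base_only <- make_panel(list(list(id = "a", times = 0, stages = 2)))
  expect_equal(panel_log_likelihood(base_only, P), 0)

  # multi-cycle gap bridged by the matrix power = path-enumeration sum
  gap <- make_panel(list(list(id = "a", times = c(0, 4), stages = c(3, 4))))
  expect_equal(panel_log_likelihood(gap, P),
               log(path_enumeration_prob(P, 3, 4, 4)), tolerance = 1e-12)
})

test_that("panel likelihood is additive over subjects and order-invariant", {
  withr::local_seed(5)
  P <- rand_tmatrix()
  subs <- lapply(1:6, function(j) {
    list(id = sprintf("s%d", j), times = c(0, 1, 3),
         stages = c(sample(1:3, 1), sample(1:4, 2, replace = TRUE)))
  })
  for (s in seq_along(subs)) {  # repair absorbing violations
    st <- subs[[s]]$stages
    if (st[2] == 4) st[3] <- 4
    subs[[s]]$stages <- st
  }
  ds <- make_panel(subs)
  ll <- panel_log_likelihood(ds, P)
  ll_rev <- panel_log_likelihood(make_panel(rev(subs)), P)
  expect_equal(ll, ll_rev, tolerance = 1e-12)
  ll_split <- panel_log_likelihood(make_panel(subs[1:3]), P) +
    panel_log_likelihood(make_panel(subs[4:6]), P)
  expect_equal(ll, ll_split, tolerance = 1e-12)
})

test_that("a zero-probability observed transition yields -Inf, flagged", {
  P <- rbind(c(0.5, 0, 0.3, 0.2),
             c(0.2, 0.5, 0.2, 0.1),
             c(0.1, 0.2, 0.5, 0.2),
             c(0, 0, 0, 1))
  ds <- make_panel(list(list(id = "a", times = c(0, 1), stages = c(1, 2))))
  ll <- panel_log_likelihood(ds, P)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_transitions"), 1L)
})

test_that("C++ likelihood matches the R reference on a simulated cohort", {
  cfg <- default_study_config(seed = 77)
  cfg$arms$HCP$n <- 30L
  cfg$arms$control$n <- 60L
  ds <- simulate_cohort(cfg)
  fd <- stagechain:::build_fit_data(ds, cfg$spec)
  theta <- stagechain:::pack_params(cfg$params, cfg$spec)
  ll_cpp <- stagechain:::cpp_panel_loglik(theta, fd$X, fd$terms,
                                          length(cfg$spec$covariates),
                                          FALSE, 0)
  provider <- function(subj) {
    x <- stagechain:::scaled_profile(as.list(subj), cfg$spec)
    transition_matrix_for(x, cfg$params, cfg$spec)
  }
  expect_equal(ll_cpp, panel_log_likelihood(ds, provider), tolerance = 1e-10)
})

test_that("the C++ analytic gradient matches central differences", {
  withr::local_seed(99)
  X <- matrix(rnorm(30), 15, 2)
  terms <- cbind(1:15, sample(1:3, 15, TRUE), sample(1:4, 15, TRUE),
                 sample(c(1L, 3L, 4L), 15, TRUE))
  storage.mode(terms) <- "integer"
  for (antisym in c(FALSE, TRUE)) {
    q <- 9L + 3L * 2L + if (antisym) 0L else 2L * 2L
    theta <- rnorm(q, 0, 0.5)
    g <- stagechain:::cpp_panel_loglik_grad(theta, X, terms, 2L, antisym, 0.1)
    num <- sapply(seq_len(q), function(j) {
      h <- 1e-6
      up <- dn <- theta
      up[j] <- up[j] + h
      dn[j] <- dn[j] - h
      (stagechain:::cpp_panel_loglik(up, X, terms, 2L, antisym, 0.1) -
         stagechain:::cpp_panel_loglik(dn, X, terms, 2L, antisym, 0.1)) / (2 * h)
    })
    expect_equal(as.numeric(g$gradient), num, tolerance = 1e-6)
    expect_equal(g$loglik,
                 stagechain:::cpp_panel_loglik(theta, X, terms, 2L, antisym, 0.1))
  }
})
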