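shape04 <- harmonic_shape(D = 0.4)

test_that("single-subject ML recovers known parameters on the study grid", {
  truth <- c(A = 4, B = 0.2, phi = 0.3)
  R <- 30
  est <- t(vapply(seq_len(R), function(r) {
    s <- make_series(truth["A"], truth["B"], truth["phi"], D = 0.4,
                     n_days = 7, seed = 100 + r)
    p <- fit_subject(s, shape04)
    c(p$A, p$B, p$phi)
  }, numeric(3)))
  # replicate mean within 3 Monte-Carlo SEs of the truth, per parameter
  for (j in 1:3) {
    mc_se <- sd(est[, j]) / sqrt(R)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * mc_se + 1e-3)
  }
})

test_that("constant counts give the flat-rhythm boundary and the right level", {
  s <- activity_series("flat", day = rep(1:2, each = 96),
                       bin = rep(1:96, 2), count = rep(20L, 192))
  p <- fit_subject(s, shape04)
  expect_equal(p$A, log(20), tolerance = 1e-3)
  expect_true(attr(p, "boundary"))
  expect_lt(exp(-p$B), 1e-6)
})

test_that("fitted log-likelihood beats a coarse brute-force grid around the optimum", {
  s <- make_series(3.5, 0.4, -0.2, D = 0.4, n_days = 2, seed = 7)
  p <- fit_subject(s, shape04)
  ll_fit <- attr(p, "loglik")
  grid_ps <- (1:96 - 0.5) / 96
  best <- -Inf
  for (A in p$A + seq(-0.5, 0.5, by = 0.1))
    for (B in p$B + seq(-0.5, 0.5, by = 0.1))
      best <- max(best, max(vapply(grid_ps, function(ps)
        ref_loglik(s, A, B, ps, 0.4), numeric(1))))
  expect_gte(ll_fit, best - 1e-8)
})

test_that("degenerate or invalid series are rejected with clear errors", {
  z <- activity_series("zero", day = rep(1, 96), bin = 1:96,
                       count = rep(0L, 96))
  expect_error(fit_subject(z, shape04), "degenerate")
  expect_error(activity_series("neg", day = rep(1, 96), bin = 1:96,
                               count = c(-1L, rep(1L, 95))),
               "non-negative")
  expect_error(activity_series("frac", day = rep(1, 96), bin = 1:96,
                               count = c(1.5, rep(1, 95))),
               "integers")
  short <- activity_series("short", day = rep(1, 5), bin = 1:5,
                           count = rep(1L, 5))
  expect_error(fit_subject(short, shape04), "observations")
})

test_that("shared-shape fit matches a one-dimensional golden-section search", {
  set.seed(21)
  truth <- data.frame(A = rnorm(5, 4, 0.3), B = rnorm(5, 0.3, 0.2),
                      phi = rnorm(5, 0, 0.5))
  cohort <- lapply(1:5, function(i)
    make_series(truth$A[i], truth$B[i], truth$phi[i], D = 0.4, n_days = 2,
                seed = 300 + i, id = paste0("S", i)))
  params <- lapply(1:5, function(i)
    subject_params(truth$A[i], truth$B[i], truth$phi[i]))

  pooled_ll <- function(D) sum(vapply(1:5, function(i)
    ref_loglik(cohort[[i]], truth$A[i], truth$B[i],
               plogis(truth$phi[i]), D), numeric(1)))
  # golden-section search, written out as an independent 1-D oracle
  gr <- (sqrt(5) - 1) / 2
  a <- -1; b <- 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- pooled_ll(x1); f2 <- pooled_ll(x2)
  while (b - a > 1e-8) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- pooled_ll(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- pooled_ll(x1)
    }
  }
  D_gold <- (a + b) / 2

  sh <- fit_shape(cohort, params, harmonic_shape(D = 0))
  expect_equal(sh$coeffs, D_gold, tolerance = 1e-5)
  expect_true(attr(sh, "identifiable"))
  # recovery: nuisance parameters at truth keep D near its generating value
  expect_lt(abs(sh$coeffs - 0.4), 0.05)
})

test_that("a rhythm-free cohort leaves the incoming shape unchanged and flagged", {
  s <- activity_series("flat", day = rep(1, 96), bin = 1:96,
                       count = rep(15L, 96))
  p <- subject_params(log(15), 25, 0)  # amplitude multiplier ~ 1e-11
  sh <- fit_shape(list(s), list(p), harmonic_shape(D = 0.37))
  expect_identical(sh$coeffs, 0.37)
  expect_false(attr(sh, "identifiable"))
})

test_that("stage-1 alternation converges with a monotone likelihood trace", {
  spec <- cohort_spec(n_subjects = 10, group_sizes = c(7, 3), n_days = 2)
  co <- simulate_cohort(spec, seed = 5)
  fit <- fit_cohort(co$series)
  expect_true(fit$converged)
  expect_lte(fit$n_outer_iters, 25)
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  expect_lt(abs(fit$shape$coeffs - 0.4), 0.1)
  expect_true(all(is.finite(fit$subjects$A)))
  expect_true(all(fit$subjects$converged))
})

test_that("stage-1 is deterministic and invariant to subject order", {
  spec <- cohort_spec(n_subjects = 6, group_sizes = c(4, 2), n_days = 1)
  co <- simulate_cohort(spec, seed = 9)
  f1 <- fit_cohort(co$series)
  f2 <- fit_cohort(co$series)
  expect_identical(f1$subjects, f2$subjects)
  expect_identical(f1$shape$coeffs, f2$shape$coeffs)

  set.seed(1)
  f3 <- fit_cohort(sample(co$series))
  expect_identical(f1$subjects, f3$subjects)
  expect_identical(f1$trace, f3$trace)
})

test_that("all-zero subjects are excluded with a warning, or abort when too many", {
  spec <- cohort_spec(n_subjects = 8, group_sizes = c(6, 2), n_days = 1)
  co <- simulate_cohort(spec, seed = 13)
  zero <- activity_series("Z01", day = rep(1, 96), bin = 1:96,
                          count = rep(0L, 96))
  expect_warning(fit <- fit_cohort(c(co$series, list(zero))),
                 "all-zero")
  expect_identical(fit$excluded, "Z01")
  expect_equal(nrow(fit$subjects), 8)

  zeros <- lapply(1:4, function(i)
    activity_series(paste0("Z", i), day = rep(1, 96), bin = 1:96,
                    count = rep(0L, 96)))
  expect_error(fit_cohort(c(co$series[1:6], zeros)), "20%")
})
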