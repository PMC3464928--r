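test_that("the generator is seed-deterministic and seed-sensitive", {
  spec <- cohort_spec(n_subjects = 4, group_sizes = c(2, 2), n_days = 1)
  c1 <- simulate_cohort(spec, seed = 5)
  c2 <- simulate_cohort(spec, seed = 5)
  c3 <- simulate_cohort(spec, seed = 6)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$series, `[[`, "data"),
                   lapply(c2$series, `[[`, "data"))
  expect_false(identical(c1$truth$A, c3$truth$A))
})

test_that("empirical bin means match the model intensity (law of large numbers)", {
  spec <- cohort_spec(n_subjects = 2, group_sizes = c(1, 1),
                      n_days = 10000, sd_A = 0, sd_B = 0, sd_phi = 0)
  co <- simulate_cohort(spec, seed = 17)
  s <- co$series[[1]]
  tg <- time_grid(96)
  lam <- exp(log_intensity(tg, subject_params(co$truth$A[1], co$truth$B[1],
                                              co$truth$phi[1]), spec$shape))
  emp <- tapply(s$data$count, s$data$bin, mean)
  expect_true(all(abs(emp / lam - 1) < 0.01))
})

test_that("counts are Poisson-dispersed around the bin means", {
  spec <- cohort_spec(n_subjects = 2, group_sizes = c(1, 1), n_days = 1000)
  co <- simulate_cohort(spec, seed = 19)
  d <- co$series[[2]]$data
  m <- tapply(d$count, d$bin, mean)
  v <- tapply(d$count, d$bin, var)
  idx <- m >= 5
  disp <- v[idx] / m[idx]
  expect_true(all(disp > 0.8 & disp < 1.2))
})

test_that("null cohorts have balanced true parameters across groups", {
  spec <- cohort_spec(n_subjects = 400, group_sizes = c(200, 200),
                      n_days = 1)
  co <- simulate_cohort(spec, seed = 23)
  tr <- co$truth
  for (p in c("A", "B", "phi")) {
    d <- mean(tr[[p]][tr$group == 1]) - mean(tr[[p]][tr$group == 0])
    se <- sqrt(var(tr[[p]][tr$group == 1]) / 200 +
                 var(tr[[p]][tr$group == 0]) / 200)
    expect_lt(abs(d), 3 * se)
  }
})

test_that("intensity overflow is caught with advice to rescale", {
  spec <- cohort_spec(n_subjects = 2, group_sizes = c(1, 1), n_days = 1,
                      mean_A = 40)
  expect_error(simulate_cohort(spec, seed = 1), "rescale")
})

test_that("correlated random effects are honoured", {
  S <- matrix(c(0.16, 0.05, 0, 0.05, 0.04, 0, 0, 0, 0.25), 3, 3)
  spec <- cohort_spec(n_subjects = 600, group_sizes = c(300, 300),
                      n_days = 1, param_cov = S)
  co <- simulate_cohort(spec, seed = 29)
  expect_gt(cor(co$truth$A, co$truth$B), 0.3)
  expect_lt(abs(cor(co$truth$A, co$truth$phi)), 0.2)
})

test_that("spec validation catches inconsistent group sizes and covariances", {
  expect_error(cohort_spec(n_subjects = 10, group_sizes = c(5, 4)),
               "sum to n_subjects")
  expect_error(cohort_spec(param_cov = matrix(1, 2, 2)), "3x3")
})

test_that("type-I study refuses nonzero effects; alpha = 1 always rejects", {
  spec_alt <- cohort_spec(n_subjects = 6, group_sizes = c(4, 2),
                          n_days = 1, effect_phi = 1)
  expect_error(type1_error_study(spec_alt, n_reps = 100), "zero group effects")

  spec0 <- cohort_spec(n_subjects = 6, group_sizes = c(4, 2), n_days = 1)
  tab <- type1_error_study(spec0, n_reps = 100, alpha = 1, seed = 3)
  expect_equal(tab$rate, c(1, 1, 1))
  expect_equal(tab$parameter, c("A", "B", "phi"))
  expect_true(all(tab$ci_low <= 1 & tab$ci_high == 1))
})

test_that("power concentrates on the parameter carrying the effect", {
  spec <- cohort_spec(n_subjects = 12, group_sizes = c(8, 4), n_days = 1,
                      effect_phi = 1)
  tab <- power_study(spec, n_reps = 100, alpha = 0.05, seed = 7)
  pow <- setNames(tab$rate, tab$parameter)
  expect_gt(pow["phi"], pow["A"])
  expect_gt(pow["phi"], pow["B"])
  expect_gt(pow["phi"], 0.5)
})

test_that("study tables are seed-deterministic", {
  spec <- cohort_spec(n_subjects = 6, group_sizes = c(4, 2), n_days = 1)
  t1 <- type1_error_study(spec, n_reps = 100, alpha = 0.2, seed = 11)
  t2 <- type1_error_study(spec, n_reps = 100, alpha = 0.2, seed = 11)
  expect_identical(t1, t2)
})
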