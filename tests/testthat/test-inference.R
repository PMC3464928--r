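# two_sample_test and adjusted_regression operate on stage-1 parameter
# tables; these tests build such tables directly so the inference layer is
# exercised independently of the fitting layer.
make_table <- function(A, B, phi, prefix = "S") {
  n <- length(A)
  data.frame(subject = sprintf("%s%03d", prefix, seq_len(n)),
             A = A, B = B, phi = phi, stringsAsFactors = FALSE)
}

test_that("identical groups give zero difference and p = 1", {
  tab <- make_table(A = rep(c(1, 2, 3), 2), B = rep(c(0.1, 0.2, 0.3), 2),
                    phi = rep(c(-1, 0, 1), 2))
  g <- rep(c(0, 1), each = 3)
  res <- two_sample_test(tab, g)
  expect_equal(res$difference, c(0, 0, 0))
  expect_equal(res$p_value, c(1, 1, 1))
})

test_that("pooled t-test matches stats::t.test on a hand-sized example", {
  tab <- make_table(A = c(2, 3, 4, 1, 2, 3), B = c(1, 2, 3, 2, 3, 4),
                    phi = c(0, 1, 2, 1, 2, 3))
  g <- c(0, 0, 0, 1, 1, 1)
  res <- two_sample_test(tab, g)
  # group 1 is group 0 shifted by -1 (A) and +1 (B, phi)
  expect_equal(res$difference, c(-1, 1, 1))
  for (i in seq_len(3)) {
    p <- c("A", "B", "phi")[i]
    ref <- t.test(tab[[p]][g == 1], tab[[p]][g == 0], var.equal = TRUE)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(res$difference[i], unname(diff(rev(ref$estimate))),
                 tolerance = 1e-12)
  }
  # Welch variant agrees with t.test's default
  resw <- two_sample_test(tab, g, var_equal = FALSE)
  refw <- t.test(tab$A[g == 1], tab$A[g == 0])
  expect_equal(resw$p_value[1], refw$p.value, tolerance = 1e-12)
})

test_that("t-test is invariant to a location shift of the estimates", {
  set.seed(31)
  tab <- make_table(A = rnorm(20), B = rnorm(20), phi = rnorm(20))
  g <- rep(c(0, 1), 10)
  r1 <- two_sample_test(tab, g)
  tab2 <- tab; tab2$A <- tab2$A + 100
  r2 <- two_sample_test(tab2, g)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
})

test_that("groups with fewer than 2 subjects are refused", {
  tab <- make_table(A = 1:4, B = 1:4, phi = 1:4)
  expect_error(two_sample_test(tab, c(0, 0, 0, 1)), "at least 2")
})

test_that("labels can be matched by subject id in any order", {
  tab <- make_table(A = c(1, 2, 5, 6), B = c(1, 2, 5, 6),
                    phi = c(1, 2, 5, 6))
  g <- setNames(c(1, 1, 0, 0), rev(tab$subject))  # reversed name order
  res <- two_sample_test(tab, g)
  expect_equal(res$difference[1], mean(c(5, 6)) - mean(c(1, 2)))
})

test_that("OLS on a group dummy reproduces the pooled t-test exactly", {
  set.seed(37)
  tab <- make_table(A = rnorm(24, 4), B = rnorm(24, 0.3),
                    phi = rnorm(24))
  g <- rep(c(0, 1), each = 12)
  tt <- two_sample_test(tab, g)
  reg <- adjusted_regression(tab, g)
  expect_equal(reg$difference, tt$difference, tolerance = 1e-10)
  expect_equal(reg$se, tt$se, tolerance = 1e-10)
  expect_equal(reg$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("a duplicated exposure among covariates triggers a rank error", {
  set.seed(41)
  tab <- make_table(A = rnorm(12), B = rnorm(12), phi = rnorm(12))
  g <- rep(c(0, 1), 6)
  covs <- data.frame(subject = tab$subject, dup = g)
  expect_error(adjusted_regression(tab, g, covs), "rank deficient.*dup")
})

test_that("adjusted regression recovers a planted continuous effect", {
  set.seed(43)
  R <- 20
  hits <- vapply(seq_len(R), function(r) {
    n <- 40
    bmi <- runif(n, 18, 35)
    race <- factor(sample(c("Other", "Hispanic", "AfricanAmerican"),
                          n, replace = TRUE), levels = c("Other",
                          "Hispanic", "AfricanAmerican"))
    tab <- make_table(A = rnorm(n, 4, 0.3), B = rnorm(n, 0.3, 0.2),
                      phi = 0.1 * bmi + rnorm(n, 0, 0.4))
    covs <- data.frame(subject = tab$subject, race = race)
    res <- adjusted_regression(tab, setNames(bmi, tab$subject), covs)
    row <- res[res$parameter == "phi", ]
    abs(row$difference - 0.1) <= 3 * row$se
  }, logical(1))
  # the planted slope should be covered by +-3 SE in essentially all runs
  expect_gte(mean(hits), 0.9)
})

test_that("missing covariates trigger complete-case analysis with a message", {
  set.seed(47)
  tab <- make_table(A = rnorm(12), B = rnorm(12), phi = rnorm(12))
  g <- rep(c(0, 1), 6)
  covs <- data.frame(subject = tab$subject,
                     fas = c(NA, runif(11, 0, 9)))
  expect_message(res <- adjusted_regression(tab, g, covs), "dropping 1")
  expect_equal(unique(res$n), 11)
})
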