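#' Stage-2 group comparison of circadian parameters by t-test
#'
#' Treats the per-subject stage-1 estimates of A (mean level), B
#' (log-amplitude) and phi (unconstrained phase) as data and compares them
#' between two groups with a two-sided two-sample t-test. The default is
#' the pooled-variance (Student) test, whose difference/SE layout matches
#' an ordinary regression on a group dummy; Welch's unequal-variance test
#' is available via `var_equal = FALSE`. The phase is tested on the
#' unconstrained logit scale; for display, the difference in mean phase
#' fraction is also converted to clock hours.
#'
#' @param fit a `circshape_fit` from [fit_cohort()], or a data frame with
#'   columns `subject`, `A`, `B`, `phi`.
#' @param groups binary group labels (0/1): either a vector named by
#'   subject id, or a data frame with columns `subject` and `group`.
#' @param var_equal pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @return Object of class `group_inference`: data frame with one row per
#'   parameter (`A`, `B`, `phi`) and columns `parameter`, `difference`
#'   (group 1 minus group 0), `se`, `df`, `p_value`, `method`, `n0`, `n1`;
#'   attribute `phi_star_diff_hours` gives the group difference in mean
#'   phase fraction times 24.
#' @export
two_sample_test <- function(fit, groups, var_equal = TRUE) {
  tab <- stage1_table(fit)
  g <- align_groups(tab$subject, groups)
  if (!all(g %in% 0:1)) stop("'groups' must be binary 0/1 labels")
  n0 <- sum(g == 0); n1 <- sum(g == 1)
  if (n0 < 2 || n1 < 2)
    stop("each group needs at least 2 subjects to estimate a variance (have ",
         n0, " and ", n1, ")")
  method <- if (var_equal) "t_test" else "t_test_welch"
  rows <- lapply(c("A", "B", "phi"), function(p) {
    x1 <- tab[[p]][g == 1]; x0 <- tab[[p]][g == 0]
    if (any(!is.finite(c(x0, x1)))) stop("non-finite estimates for ", p)
    diff <- mean(x1) - mean(x0)
    if (var_equal) {
      sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
        (n0 + n1 - 2)
      se <- sqrt(sp2 * (1 / n0 + 1 / n1))
      df <- n0 + n1 - 2
    } else {
      v1 <- stats::var(x1) / n1; v0 <- stats::var(x0) / n0
      se <- sqrt(v1 + v0)
      df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
    }
    p_value <- if (se == 0) {
      if (diff == 0) 1 else 0
    } else 2 * stats::pt(abs(diff / se), df, lower.tail = FALSE)
    data.frame(parameter = p, difference = diff, se = se, df = df,
               p_value = p_value, method = method, n0 = n0, n1 = n1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ps <- stats::plogis(tab$phi)
  attr(out, "phi_star_diff_hours") <-
    24 * (mean(ps[g == 1]) - mean(ps[g == 0]))
  class(out) <- c("group_inference", "data.frame")
  out
}

#' Stage-2 covariate-adjusted regression of circadian parameters
#'
#' Regresses each per-subject parameter estimate (A, B, phi) on an exposure
#' (binary group indicator or a continuous variable such as BMI) plus
#' adjustment covariates, by ordinary least squares, and reports the
#' exposure coefficient with its SE and two-sided p-value. Factors are
#' expanded to indicator columns against their first level (set the
#' reference with [stats::relevel()] or `factor(levels = ...)`). Subjects
#' with any missing covariate are dropped (complete-case) with a message.
#' With no covariates and a binary exposure this reproduces the
#' pooled-variance t-test exactly.
#'
#' @param fit a `circshape_fit` or a data frame with columns `subject`,
#'   `A`, `B`, `phi`.
#' @param exposure exposure values: vector named by subject id, or a data
#'   frame with columns `subject` and one exposure column.
#' @param covariates optional data frame of adjustment covariates with a
#'   `subject` column; remaining columns enter the model.
#' @return Object of class `group_inference`: one row per parameter with
#'   `parameter`, `difference` (the exposure coefficient), `se`, `df`,
#'   `p_value`, `method = "adjusted_regression"`, `n` (complete cases) and
#'   attribute `covariates` (the adjustment column names).
#' @export
adjusted_regression <- function(fit, exposure, covariates = NULL) {
  tab <- stage1_table(fit)
  ex <- align_groups(tab$subject, exposure, what = "exposure")
  dat <- data.frame(.exposure = ex, tab[, c("A", "B", "phi")])
  covnames <- character(0)
  if (!is.null(covariates)) {
    if (!is.data.frame(covariates) || !"subject" %in% names(covariates))
      stop("'covariates' must be a data frame with a 'subject' column")
    idx <- match(tab$subject, as.character(covariates$subject))
    if (any(is.na(idx)))
      stop("covariate table is missing subjects: ",
           paste(tab$subject[is.na(idx)], collapse = ", "))
    cv <- covariates[idx, setdiff(names(covariates), "subject"), drop = FALSE]
    covnames <- names(cv)
    dat <- cbind(dat, cv)
  }
  cc <- stats::complete.cases(dat)
  if (sum(!cc) > 0)
    message("dropping ", sum(!cc), " subject(s) with missing covariates")
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(covnames) + 3)
    stop("too few complete cases for the adjusted regression")

  rhs <- paste(c(".exposure", covnames), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  rows <- lapply(c("A", "B", "phi"), function(p) {
    fml <- stats::as.formula(paste(p, "~", rhs))
    m <- stats::lm(fml, data = dat)
    sm <- summary(m)$coefficients
    est <- sm[".exposure", ]
    data.frame(parameter = p, difference = est[["Estimate"]],
               se = est[["Std. Error"]],
               df = m$df.residual,
               p_value = est[["Pr(>|t|)"]],
               method = "adjusted_regression",
               n0 = NA_integer_, n1 = NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n <- nrow(dat)
  attr(out, "covariates") <- covnames
  class(out) <- c("group_inference", "data.frame")
  out
}

#' @export
print.group_inference <- function(x, ...) {
  cat("Stage-2 inference on circadian parameters\n")
  df <- as.data.frame(x)
  df$difference <- formatC(df$difference, digits = 4, format = "f")
  df$se <- formatC(df$se, digits = 4, format = "f")
  df$p_value <- formatC(df$p_value, digits = 4, format = "g")
  print(df, row.names = FALSE)
  h <- attr(x, "phi_star_diff_hours")
  if (!is.null(h))
    cat(sprintf("phase difference on the clock: %.2f hours (group 1 - group 0)\n", h))
  invisible(x)
}

# internal: accept a circshape_fit or a bare parameter table
stage1_table <- function(fit) {
  if (inherits(fit, "circshape_fit")) {
    tab <- fit$subjects
    tab <- tab[tab$converged, , drop = FALSE]
  } else if (is.data.frame(fit)) {
    tab <- fit
  } else stop("expected a 'circshape_fit' or a parameter data frame")
  need <- c("subject", "A", "B", "phi")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  tab$subject <- as.character(tab$subject)
  tab
}

# internal: align a labels vector / data frame to the subject order
align_groups <- function(subjects, groups, what = "groups") {
  if (is.data.frame(groups)) {
    cols <- setdiff(names(groups), "subject")
    if (!"subject" %in% names(groups) || length(cols) != 1)
      stop("'", what, "' data frame needs columns 'subject' and one value column")
    g <- groups[[cols]]
    names(g) <- as.character(groups$subject)
    groups <- g
  }
  if (!is.null(names(groups)) && all(nzchar(names(groups)))) {
    idx <- match(subjects, names(groups))
    if (any(is.na(idx)))
      stop("'", what, "' is missing subjects: ",
           paste(subjects[is.na(idx)], collapse = ", "))
    groups <- groups[idx]
  } else if (length(groups) != length(subjects)) {
    stop("'", what, "' must be named by subject id or match the number of subjects")
  }
  as.numeric(groups)
}
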