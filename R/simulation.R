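#' Specification of a synthetic actigraphy cohort
#'
#' Describes the cohort the generator draws: the study-like default is 96
#' subjects in two groups of 77 and 19, each observed for 7 days in 96
#' fifteen-minute bins per day (672 counts per subject). Subject parameters
#' are drawn independently from normal distributions on the unconstrained
#' scales, with optional additive group effects, and counts are Poisson
#' around the shape-invariant intensity. Population means/SDs and the shape
#' coefficient are package defaults chosen to give realistic rhythmic count
#' data (day-time peak counts in the low hundreds per 15-minute bin); see
#' the methods vignette.
#'
#' @param n_subjects total number of subjects (default 96).
#' @param group_sizes sizes of group 0 and group 1 (default `c(77, 19)`);
#'   must sum to `n_subjects`.
#' @param n_days days of monitoring per subject (default 7).
#' @param bins_per_day within-day bins (default 96).
#' @param mean_A,sd_A population mean and SD of the log mean level
#'   (defaults 4.0, 0.4).
#' @param mean_B,sd_B population mean and SD of the log-amplitude parameter
#'   (defaults 0.3, 0.2).
#' @param mean_phi,sd_phi population mean and SD of the unconstrained phase
#'   (defaults 0, 0.5).
#' @param effect_A,effect_B,effect_phi additive group-1 effects on the
#'   unconstrained scales (defaults 0: a null cohort).
#' @param shape shared [harmonic_shape()] (default two harmonics, D = 0.4).
#' @param param_cov optional 3x3 covariance matrix for correlated
#'   (A, B, phi) random effects; overrides the SDs.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 96, group_sizes = c(77, 19),
                        n_days = 7, bins_per_day = 96,
                        mean_A = 4.0, sd_A = 0.4,
                        mean_B = 0.3, sd_B = 0.2,
                        mean_phi = 0, sd_phi = 0.5,
                        effect_A = 0, effect_B = 0, effect_phi = 0,
                        shape = harmonic_shape(D = 0.4),
                        param_cov = NULL) {
  stopifnot(n_subjects >= 2, length(group_sizes) == 2,
            all(group_sizes >= 0), n_days >= 1, bins_per_day >= 8,
            sd_A >= 0, sd_B >= 0, sd_phi >= 0,
            inherits(shape, "harmonic_shape"))
  if (sum(group_sizes) != n_subjects)
    stop("group sizes must sum to n_subjects")
  if (!is.null(param_cov)) {
    param_cov <- as.matrix(param_cov)
    if (!identical(dim(param_cov), c(3L, 3L)) ||
        !isSymmetric(unname(param_cov)))
      stop("'param_cov' must be a symmetric 3x3 matrix")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 group_sizes = as.integer(group_sizes),
                 n_days = as.integer(n_days),
                 bins_per_day = as.integer(bins_per_day),
                 mean_A = mean_A, sd_A = sd_A,
                 mean_B = mean_B, sd_B = sd_B,
                 mean_phi = mean_phi, sd_phi = sd_phi,
                 effect_A = effect_A, effect_B = effect_B,
                 effect_phi = effect_phi,
                 shape = shape, param_cov = param_cov),
            class = "cohort_spec")
}

#' Simulate a synthetic actigraphy cohort
#'
#' Draws per-subject (A, B, phi) from the population distributions in the
#' spec (plus group effects), then draws every count independently as
#' Poisson with the shape-invariant intensity
#' `exp(A + exp(-B) f(t + phi*))`; day replicates reuse the same within-day
#' intensity (the model has no day effect). Fully reproducible given
#' `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed driving all randomness of the draw.
#' @return A list of class `simulated_cohort`: `series` (list of
#'   [activity_series()]), `truth` (data frame of true `subject`, `group`,
#'   `A`, `B`, `phi`, `phi_star`), `spec`, `seed`.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_subjects
  group <- rep(c(0L, 1L), spec$group_sizes)
  if (is.null(spec$param_cov)) {
    A <- stats::rnorm(n, spec$mean_A, spec$sd_A)
    B <- stats::rnorm(n, spec$mean_B, spec$sd_B)
    phi <- stats::rnorm(n, spec$mean_phi, spec$sd_phi)
  } else {
    re <- MASS::mvrnorm(n, mu = c(spec$mean_A, spec$mean_B, spec$mean_phi),
                        Sigma = spec$param_cov)
    A <- re[, 1]; B <- re[, 2]; phi <- re[, 3]
  }
  A <- A + spec$effect_A * group
  B <- B + spec$effect_B * group
  phi <- phi + spec$effect_phi * group

  tg <- time_grid(spec$bins_per_day)
  beta <- c(1, spec$shape$coeffs)
  max_eta <- max(A) + max(exp(-B)) * sum(abs(beta))
  if (max_eta > 25)
    stop("simulated log intensity exceeds exp(25): rescale mean_A/sd_A ",
         "or the amplitude parameters")
  nobs <- spec$n_days * spec$bins_per_day
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("S%0", width, "d"), seq_len(n))
  series <- vector("list", n)
  for (i in seq_len(n)) {
    lam <- exp(A[i] + exp(-B[i]) *
                 shape_f(tg + stats::plogis(phi[i]), beta))
    counts <- stats::rpois(nobs, rep(lam, times = spec$n_days))
    series[[i]] <- activity_series(
      subject_id = ids[i],
      day = rep(seq_len(spec$n_days), each = spec$bins_per_day),
      bin = rep(seq_len(spec$bins_per_day), times = spec$n_days),
      count = counts,
      bins_per_day = spec$bins_per_day,
      group = group[i]
    )
  }
  truth <- data.frame(subject = ids, group = group, A = A, B = B, phi = phi,
                      phi_star = stats::plogis(phi),
                      stringsAsFactors = FALSE)
  structure(list(series = series, truth = truth, spec = spec,
                 seed = as.integer(seed)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d subjects (%d + %d), %d day(s) x %d bins = %d obs/subject, seed %d\n",
    x$spec$n_subjects, x$spec$group_sizes[1], x$spec$group_sizes[2],
    x$spec$n_days, x$spec$bins_per_day,
    x$spec$n_days * x$spec$bins_per_day, x$seed))
  invisible(x)
}

# internal: one simulate -> stage-1 fit -> stage-2 t-test replicate;
# returns the three p-values or NULL on fit failure
replicate_pvalues <- function(spec, seed, config) {
  co <- simulate_cohort(spec, seed = seed)
  fit <- tryCatch(
    suppressWarnings(fit_cohort(co$series, config)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  groups <- stats::setNames(co$truth$group, co$truth$subject)
  res <- tryCatch(two_sample_test(fit, groups), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  stats::setNames(res$p_value, res$parameter)
}

rejection_table <- function(pmat, n_target, alpha, conf_level) {
  rows <- lapply(colnames(pmat), function(p) {
    pv <- pmat[, p]
    rej <- sum(pv < alpha)
    n_ok <- length(pv)
    ci <- stats::binom.test(rej, n_ok, conf.level = conf_level)$conf.int
    data.frame(parameter = p, n_reps = n_ok, rejections = rej,
               rate = rej / n_ok, ci_low = ci[1], ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "conf_level") <- conf_level
  attr(out, "n_failed") <- n_target - out$n_reps[1]
  out
}

#' Type-I-error study of the two-stage procedure
#'
#' Repeatedly simulates null cohorts (zero group effects), runs the full
#' two-stage pipeline (stage-1 alternating estimation, then the stage-2
#' t-test on A, B and phi), and reports the proportion of replicates whose
#' p-value falls below `alpha` for each parameter, with an exact binomial
#' confidence interval. A valid alpha-level test keeps each interval
#' covering `alpha`. Replicates whose stage-1 fit fails are dropped from
#' the denominator and counted in attribute `n_failed`.
#'
#' @param spec a [cohort_spec()] with all group effects zero.
#' @param n_reps number of replicate cohorts (>= 100).
#' @param alpha nominal test level (default 0.05).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param config stage-1 [fit_config()].
#' @param conf_level confidence level of the exact binomial interval
#'   (default 0.95).
#' @return Data frame with one row per parameter: `parameter`, `n_reps`,
#'   `rejections`, `rate`, `ci_low`, `ci_high`; attributes `alpha`,
#'   `conf_level`, `n_failed`.
#' @export
type1_error_study <- function(spec, n_reps = 2000, alpha = 0.05, seed = 1L,
                              config = fit_config(), conf_level = 0.95) {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 100,
            alpha > 0, alpha <= 1)
  if (spec$effect_A != 0 || spec$effect_B != 0 || spec$effect_phi != 0)
    stop("type-I-error study requires zero group effects; ",
         "use power_study() for nonzero effects")
  run_rejection_study(spec, n_reps, alpha, seed, config, conf_level)
}

#' Power study of the two-stage procedure
#'
#' Same pipeline as [type1_error_study()] but with nonzero group effects in
#' the spec: the per-parameter rejection rates are empirical power.
#'
#' @inheritParams type1_error_study
#' @param spec a [cohort_spec()], typically with nonzero group effects.
#' @return As [type1_error_study()].
#' @export
power_study <- function(spec, n_reps = 500, alpha = 0.05, seed = 1L,
                        config = fit_config(), conf_level = 0.95) {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 100,
            alpha > 0, alpha <= 1)
  run_rejection_study(spec, n_reps, alpha, seed, config, conf_level)
}

run_rejection_study <- function(spec, n_reps, alpha, seed, config,
                                conf_level) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, n_reps)
  pvals <- vector("list", n_reps)
  for (r in seq_len(n_reps))
    pvals[[r]] <- replicate_pvalues(spec, rep_seeds[r], config)
  ok <- !vapply(pvals, is.null, logical(1))
  if (!any(ok)) stop("all replicates failed to fit")
  pmat <- do.call(rbind, pvals[ok])
  rejection_table(pmat, n_reps, alpha, conf_level)
}
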