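#' Harmonic circadian shape
#'
#' The common circadian shape shared by all subjects is a sum of `K` cosine
#' harmonics of the (rescaled) 24-hour day,
#' \deqn{f(t) = \sum_{k=1}^{K} \beta_k \cos\{2k\pi (t + \phi^*)\},}
#' with \eqn{\beta_1 \equiv 1} fixed for identifiability; only the
#' higher-harmonic coefficients \eqn{(\beta_2, \ldots, \beta_K)} are free.
#' For the default two-harmonic shape the single free coefficient is the
#' classical second-harmonic weight `D`.
#'
#' @param D second-harmonic coefficient (used when `coeffs` is `NULL`;
#'   gives the two-harmonic shape `cos + D cos2`).
#' @param coeffs numeric vector `(beta_2, ..., beta_K)` of higher-harmonic
#'   coefficients; overrides `D` and sets `K = length(coeffs) + 1`.
#' @return An object of class `harmonic_shape` with elements `K` and
#'   `coeffs` (length `K - 1`; the first-harmonic coefficient is not stored).
#' @examples
#' harmonic_shape(D = 0.4)
#' harmonic_shape(coeffs = c(0.4, -0.1)) # K = 3
#' @export
harmonic_shape <- function(D = 0, coeffs = NULL) {
  if (is.null(coeffs)) {
    stopifnot(is.numeric(D), length(D) == 1, is.finite(D))
    coeffs <- D
  }
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) < 1 || any(!is.finite(coeffs)))
    stop("harmonic coefficients must be finite; need at least one (K >= 2)")
  structure(list(K = length(coeffs) + 1L, coeffs = coeffs),
            class = "harmonic_shape")
}

#' @export
print.harmonic_shape <- function(x, ...) {
  cat("Harmonic circadian shape: K =", x$K,
      "(first-harmonic coefficient fixed at 1)\n")
  cat("  higher-harmonic coefficients:",
      paste(formatC(x$coeffs, digits = 4, format = "fg"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subject-level circadian parameters
#'
#' Bundles one subject's parameters on the unconstrained estimation scale:
#' `A` (log mean activity level), `B` (log-amplitude parameter; the
#' amplitude multiplier on the log-intensity scale is `exp(-B)`, so larger
#' `B` means a flatter rhythm), and `phi` (unconstrained phase). The derived
#' phase fraction `phi_star = inverse_logit_phase(phi)` lies strictly in
#' (0, 1) and is the horizontal shift of the whole curve as a fraction of
#' the 24-hour day.
#'
#' @param A log-scale overall activity level.
#' @param B log-amplitude parameter (amplitude multiplier `exp(-B)`).
#' @param phi unconstrained phase.
#' @return An object of class `subject_params` with fields `A`, `B`, `phi`
#'   and the derived `phi_star`.
#' @export
subject_params <- function(A, B, phi) {
  stopifnot(is.finite(A), is.finite(B), is.finite(phi))
  structure(list(A = as.numeric(A), B = as.numeric(B), phi = as.numeric(phi),
                 phi_star = inverse_logit_phase(phi)),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf(
    "Subject parameters: A = %.4f, B = %.4f (amplitude multiplier %.4f), phi = %.4f (phi* = %.4f)\n",
    x$A, x$B, exp(-x$B), x$phi, x$phi_star))
  invisible(x)
}

#' Inverse-logit phase transform
#'
#' Maps an unconstrained phase parameter to the open interval (0, 1), the
#' phase shift expressed as a fraction of the 24-hour period. Numerically
#' stable for large `|phi|` (saturates smoothly, never overflows).
#'
#' @param phi numeric vector of finite unconstrained phases.
#' @return `exp(phi) / (1 + exp(phi))`, elementwise, strictly in (0, 1).
#' @examples
#' inverse_logit_phase(0)     # 0.5
#' inverse_logit_phase(1.13)  # ~0.756
#' @export
inverse_logit_phase <- function(phi) {
  if (!is.numeric(phi) || any(!is.finite(phi)))
    stop("'phi' must be finite numeric")
  # branch on sign so neither exp() can overflow: exp(phi) stays in (0, 1]
  # on the negative branch and exp(-phi) on the positive one
  out <- numeric(length(phi))
  neg <- phi < 0
  e <- exp(phi[neg])
  out[neg] <- e / (1 + e)
  out[!neg] <- 1 / (1 + exp(-phi[!neg]))
  # the transform saturates within one ulp of 0/1 for |phi| beyond ~745/37;
  # clamp to the nearest representable interior value so the phase fraction
  # honours the open-interval contract
  pmin(pmax(out, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Evaluate the harmonic shape function
#'
#' Computes \eqn{f(t) = \sum_k \beta_k \cos\{2k\pi(t + \phi^*)\}} with
#' \eqn{\beta_1 = 1}. The phase fraction `phi_star` shifts the whole curve
#' identically across harmonics (shape invariance); a positive `phi_star`
#' moves the peak earlier in the day by `phi_star * 24` hours. The result is
#' periodic in `t` with period 1.
#'
#' @param t numeric vector of day-times on the rescaled clock (any real;
#'   evaluated modulo 1).
#' @param phi_star phase-shift fraction in (0, 1) (scalar).
#' @param shape a [harmonic_shape()].
#' @return numeric vector of shape values.
#' @export
shape_function <- function(t, phi_star, shape) {
  stopifnot(inherits(shape, "harmonic_shape"),
            is.numeric(t), all(is.finite(t)),
            length(phi_star) == 1, is.finite(phi_star))
  beta <- c(1, shape$coeffs)
  u <- t + phi_star
  out <- 0
  for (k in seq_along(beta)) out <- out + beta[k] * cos(2 * pi * k * u)
  out
}

#' Log intensity of the shape-invariant Poisson model
#'
#' The activity count in bin `t` is modelled as Poisson with mean
#' \eqn{\lambda(t)} where
#' \deqn{\log \lambda(t) = A + e^{-B} f(t + \phi^*).}
#'
#' @param t numeric vector of day-times.
#' @param params a [subject_params()].
#' @param shape a [harmonic_shape()].
#' @return numeric vector of log intensities; `exp()` of it is the strictly
#'   positive Poisson mean.
#' @export
log_intensity <- function(t, params, shape) {
  stopifnot(inherits(params, "subject_params"))
  params$A + exp(-params$B) * shape_function(t, params$phi_star, shape)
}

#' Summaries of a fitted circadian curve
#'
#' Reduces one subject's intensity curve \eqn{\lambda(t)} to the three
#' quantities circadian analyses report: the mean level (average intensity
#' over one period), the peak-to-trough amplitude (highest minus lowest
#' intensity), and the clock time of peak activity in hours. Amplitude and
#' peak time are found by a dense-grid scan (default 1440 points, i.e.
#' 1-minute resolution).
#'
#' @param params a [subject_params()].
#' @param shape a [harmonic_shape()].
#' @param n_grid number of grid points per period for the scan (>= 1000
#'   recommended).
#' @return A list of class `curve_summary` with `mean_level`, `amplitude`
#'   (>= 0, intensity scale) and `peak_time_hours` in [0, 24).
#' @export
curve_summary <- function(params, shape, n_grid = 1440) {
  stopifnot(n_grid >= 3)
  t <- seq_len(n_grid) / n_grid
  lam <- exp(log_intensity(t, params, shape))
  peak <- which.max(lam)
  structure(list(
    mean_level = mean(lam),
    amplitude = max(lam) - min(lam),
    peak_time_hours = (24 * t[peak]) %% 24
  ), class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf(
    "Curve summary: mean level %.3f, peak-to-trough amplitude %.3f, peak at %.2f h\n",
    x$mean_level, x$amplitude, x$peak_time_hours))
  invisible(x)
}

#' Within-day time grid
#'
#' Times for equally spaced within-day bins on the rescaled [0, 1] clock.
#' Bin `j` carries the right-endpoint time `j / n_bins_per_day`; with the
#' default 96 bins, bin 1 is the 12:00-12:15 AM segment at t = 1/96.
#'
#' @param n_bins_per_day number of bins per day (default 96, 15-minute bins).
#' @return numeric vector of length `n_bins_per_day`, strictly increasing in
#'   (0, 1].
#' @export
time_grid <- function(n_bins_per_day = 96) {
  n <- as.integer(n_bins_per_day)
  stopifnot(n >= 1)
  seq_len(n) / n
}
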