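#' Stage-1 fitting configuration
#'
#' @param K number of harmonics in the shared shape (default 2).
#' @param max_outer_iters maximum alternations between the per-subject fits
#'   and the shared-shape fit (default 100).
#' @param tol relative convergence tolerance on the shape coefficients and
#'   the pooled log-likelihood (default 1e-6).
#' @param phase_grid_size number of phase-fraction grid points used to
#'   profile each subject's likelihood over the phase (default 96; >= 8).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(K = 2, max_outer_iters = 100, tol = 1e-6,
                       phase_grid_size = 96) {
  stopifnot(K >= 2, max_outer_iters >= 1, tol > 0, phase_grid_size >= 8)
  structure(list(K = as.integer(K),
                 max_outer_iters = as.integer(max_outer_iters),
                 tol = tol,
                 phase_grid_size = as.integer(phase_grid_size)),
            class = "fit_config")
}

# ---- likelihood kernels (internal) ----------------------------------------

# Poisson log-likelihood kernel sum(y*eta - exp(eta)); the data-dependent
# constant -sum(lfactorial(y)) is added only in reported log-likelihoods.
pois_kernel <- function(y, eta) {
  eta <- pmin(eta, 300)
  sum(y * eta) - sum(exp(eta))
}

pois_full_loglik <- function(y, eta) {
  pois_kernel(y, eta) - sum(lfactorial(y))
}

# shape value and its first two derivatives in u = t + phi_star
shape_f <- function(u, beta) {
  out <- 0
  for (k in seq_along(beta)) out <- out + beta[k] * cos(2 * pi * k * u)
  out
}
shape_df <- function(u, beta) {
  out <- 0
  for (k in seq_along(beta)) out <- out - beta[k] * (2 * pi * k) * sin(2 * pi * k * u)
  out
}
shape_d2f <- function(u, beta) {
  out <- 0
  for (k in seq_along(beta)) out <- out - beta[k] * (2 * pi * k)^2 * cos(2 * pi * k * u)
  out
}

subject_eta <- function(t, par, beta) {
  # par = c(A, B, phi) on the unconstrained scale
  ps <- stats::plogis(par[3])
  par[1] + exp(-par[2]) * shape_f(t + ps, beta)
}

# ---- per-subject fit -------------------------------------------------------

# Vectorised Newton solve of the 2-parameter Poisson GLM
# log lambda = a + c * f(t + phi_star_g) at every phase grid point at once.
# Returns the best grid point with c > 0 (negative c is phase-flip aliasing
# of the first harmonic and is discarded).
profile_phase_grid <- function(t, y, beta, grid_size) {
  n <- length(y)
  ps <- (seq_len(grid_size) - 0.5) / grid_size
  FF <- matrix(0, n, grid_size)
  for (k in seq_along(beta))
    FF <- FF + beta[k] * cos(2 * pi * k * outer(t, ps, "+"))
  sy <- sum(y)
  syF <- colSums(FF * y)
  a <- rep(log(mean(y) + 0.5 / n), grid_size)
  cc <- rep(0.05, grid_size)
  for (it in 1:30) {
    Eta <- pmin(FF * rep(cc, each = n) + rep(a, each = n), 30)
    Mu <- exp(Eta)
    MuF <- Mu * FF
    h11 <- colSums(Mu); h12 <- colSums(MuF); h22 <- colSums(MuF * FF)
    s1 <- sy - h11
    s2 <- syF - h12
    det <- h11 * h22 - h12^2
    det[det < 1e-10] <- 1e-10
    da <- pmin(pmax((h22 * s1 - h12 * s2) / det, -2), 2)
    dc <- pmin(pmax((h11 * s2 - h12 * s1) / det, -2), 2)
    a <- a + da
    cc <- cc + dc
    if (max(abs(da), abs(dc)) < 1e-9) break
  }
  Eta <- pmin(FF * rep(cc, each = n) + rep(a, each = n), 30)
  ll <- colSums(Eta * y) - colSums(exp(Eta))
  ll[cc <= 0] <- -Inf
  if (all(!is.finite(ll))) {
    # no phase with positive first-harmonic loading (essentially flat data):
    # fall back to a vanishing amplitude at an arbitrary phase
    g <- which.max(colSums(Eta * y) - colSums(exp(Eta)))
    return(list(A = a[g], C = 1e-8, phi_star = ps[g]))
  }
  g <- which.max(ll)
  list(A = a[g], C = max(cc[g], 1e-10), phi_star = ps[g])
}

neg_loglik_subject <- function(par, t, y, beta) {
  if (any(!is.finite(par)) || par[2] < -200) return(1e15)
  eta <- subject_eta(t, par, beta)
  if (any(eta > 300)) return(1e15)
  -(sum(y * eta) - sum(exp(eta)))
}

neg_grad_subject <- function(par, t, y, beta) {
  ps <- stats::plogis(par[3])
  C <- exp(-min(par[2], 200))
  u <- t + ps
  f <- shape_f(u, beta)
  eta <- pmin(par[1] + C * f, 300)
  r <- y - exp(eta)
  dps <- ps * (1 - ps)
  -c(sum(r),
     -C * sum(r * f),
     C * dps * sum(r * shape_df(u, beta)))
}

#' Fit one subject's circadian parameters for a fixed shared shape
#'
#' Maximum-likelihood estimation of (A, B, phi) for a single subject given
#' the shared harmonic shape: the likelihood is profiled over a grid of
#' phase fractions (at each grid point the model is a 2-parameter Poisson
#' GLM solved by Newton iteration), then the best grid point is polished by
#' a quasi-Newton search over all three parameters jointly. Grid profiling
#' guards against the multimodality of the likelihood in the phase.
#'
#' @param series an [activity_series()] with at least one positive count.
#' @param shape the shared [harmonic_shape()].
#' @param config a [fit_config()].
#' @param init optional `subject_params` warm start; its log-likelihood is
#'   always matched or beaten by the returned fit.
#' @param grid if `FALSE` and `init` is given, skip the phase-grid profile
#'   and only polish from the warm start (used by [fit_cohort()] on later
#'   outer iterations, once the shared shape has stabilised).
#' @return A [subject_params()] with attributes `loglik` (full Poisson
#'   log-likelihood), `converged`, `boundary` (amplitude multiplier at the
#'   zero boundary, i.e. no detectable rhythm) and `se` (approximate
#'   standard errors from the observed information).
#' @export
fit_subject <- function(series, shape, config = fit_config(), init = NULL,
                        grid = TRUE) {
  stopifnot(inherits(series, "activity_series"),
            inherits(shape, "harmonic_shape"))
  t <- series$data$t
  y <- series$data$count
  K <- shape$K
  if (length(y) < 3 * (K + 1))
    stop("subject ", series$subject_id, ": need at least ", 3 * (K + 1),
         " observations")
  if (all(y == 0))
    stop("subject ", series$subject_id,
         ": degenerate series (all counts zero); no finite mean level exists")
  beta <- c(1, shape$coeffs)

  cand <- list()
  if (grid || is.null(init)) {
    g <- profile_phase_grid(t, y, beta, config$phase_grid_size)
    cand <- list(c(g$A, -log(g$C), stats::qlogis(g$phi_star)))
  }
  if (!is.null(init)) cand <- c(cand, list(c(init$A, init$B, init$phi)))
  vals <- vapply(cand, neg_loglik_subject, numeric(1), t = t, y = y, beta = beta)
  best_start <- cand[[which.min(vals)]]

  opt <- stats::optim(best_start, neg_loglik_subject, gr = neg_grad_subject,
                      t = t, y = y, beta = beta, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  par <- if (opt$value <= min(vals)) opt$par else best_start
  par[2] <- min(par[2], 35)  # cap the flat-rhythm boundary
  ll <- -neg_loglik_subject(par, t, y, beta) - sum(lfactorial(y))

  out <- subject_params(par[1], par[2], par[3])
  attr(out, "loglik") <- ll
  attr(out, "converged") <- opt$convergence == 0 || opt$value > min(vals)
  attr(out, "boundary") <- exp(-par[2]) < 1e-6
  attr(out, "se") <- subject_se(par, t, y, beta)
  out
}

# observed-information standard errors for (A, B, phi); NA where the
# information matrix is singular (e.g. at the flat-rhythm boundary)
subject_se <- function(par, t, y, beta) {
  ps <- stats::plogis(par[3])
  C <- exp(-min(par[2], 200))
  u <- t + ps
  f <- shape_f(u, beta); f1 <- shape_df(u, beta); f2 <- shape_d2f(u, beta)
  dps <- ps * (1 - ps)
  mu <- exp(pmin(par[1] + C * f, 300))
  r <- y - mu
  G <- cbind(1, -C * f, C * dps * f1)  # d eta / d(A, B, phi)
  H <- crossprod(G, G * mu)
  # second-derivative (curvature of eta) corrections for observed information
  H[2, 2] <- H[2, 2] - sum(r * (C * f))
  H[2, 3] <- H[2, 3] + C * dps * sum(r * f1)
  H[3, 2] <- H[2, 3]
  H[3, 3] <- H[3, 3] - sum(r * (C * (f2 * dps^2 + f1 * dps * (1 - 2 * ps))))
  se <- rep(NA_real_, 3)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V)) {
    d <- diag(V)
    se[d > 0] <- sqrt(d[d > 0])
  }
  names(se) <- c("A", "B", "phi")
  se
}

# ---- shared-shape fit ------------------------------------------------------

#' Fit the shared harmonic shape with subject parameters held fixed
#'
#' For fixed per-subject (A, B, phi) the log intensity is linear in the
#' higher-harmonic coefficients, so the pooled fit is a (K-1)-parameter
#' Poisson GLM with the first harmonic absorbed into an offset; it is
#' solved by Newton iteration with step halving, guaranteeing the pooled
#' log-likelihood does not decrease relative to the incoming shape. When
#' the pooled data carry essentially no rhythm (near-zero curvature, e.g.
#' all subjects flat), the incoming shape is returned unchanged with
#' attribute `identifiable = FALSE`.
#'
#' @param cohort list of [activity_series()].
#' @param params list of [subject_params()], one per series.
#' @param shape incoming [harmonic_shape()] (starting value; defines K).
#' @return A [harmonic_shape()] with attribute `identifiable`.
#' @export
fit_shape <- function(cohort, params, shape) {
  cohort <- check_cohort(cohort)
  if (length(params) != length(cohort))
    stop("'params' must have one entry per series")
  K <- shape$K
  nh <- K - 1L
  tt <- unlist(lapply(cohort, function(s) s$data$t))
  yy <- unlist(lapply(cohort, function(s) s$data$count))
  ns <- vapply(cohort, function(s) nrow(s$data), integer(1))
  A <- rep(vapply(params, `[[`, numeric(1), "A"), ns)
  C <- rep(exp(-vapply(params, `[[`, numeric(1), "B")), ns)
  ps <- rep(vapply(params, `[[`, numeric(1), "phi_star"), ns)
  u <- tt + ps
  off <- A + C * cos(2 * pi * u)
  X <- matrix(0, length(yy), nh)
  for (k in 2:K) X[, k - 1] <- C * cos(2 * pi * k * u)

  b <- shape$coeffs
  ll0 <- pois_kernel(yy, off + X %*% b)
  # curvature at the incoming shape
  mu0 <- exp(pmin(off + X %*% b, 300))
  curv <- crossprod(X, X * as.numeric(mu0))
  if (max(abs(diag(curv))) < 1e-6) {
    out <- shape
    attr(out, "identifiable") <- FALSE
    return(out)
  }
  ll <- ll0
  for (it in 1:100) {
    eta <- pmin(off + X %*% b, 300)
    mu <- as.numeric(exp(eta))
    score <- crossprod(X, yy - mu)
    info <- crossprod(X, X * mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      bnew <- b + lam * step
      llnew <- pois_kernel(yy, off + X %*% bnew)
      if (llnew >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (llnew < ll) break
    moved <- max(abs(lam * step))
    b <- as.numeric(bnew); ll <- llnew
    if (moved < 1e-10) break
  }
  if (ll < ll0) b <- shape$coeffs  # never worse than the incoming shape
  out <- harmonic_shape(coeffs = b)
  attr(out, "identifiable") <- TRUE
  out
}

# ---- stage-1 alternation ---------------------------------------------------

#' Stage-1 two-step estimation for a cohort
#'
#' Alternates (i) per-subject maximum-likelihood fits of (A, B, phi) for the
#' current shared shape and (ii) the pooled maximum-likelihood fit of the
#' shared higher-harmonic coefficients with subject parameters fixed, until
#' both the shape coefficients and the pooled log-likelihood stabilise.
#' Each step is a conditional maximisation, so the pooled log-likelihood
#' trace is non-decreasing. Subjects whose counts are all zero carry no
#' information about a mean level on the log scale; they are excluded with
#' a warning (an error if more than 20% of the cohort is degenerate).
#'
#' @param cohort list of [activity_series()] (>= 2 subjects).
#' @param config a [fit_config()].
#' @return An object of class `circshape_fit`: list with
#'   \item{subjects}{data frame of per-subject estimates: `subject`, `A`,
#'     `B`, `phi`, `phi_star`, `loglik`, `converged`, `boundary`,
#'     `se_A`, `se_B`, `se_phi`}
#'   \item{shape}{estimated [harmonic_shape()] (for K = 2, coefficient `D`)}
#'   \item{total_loglik}{pooled Poisson log-likelihood at the optimum}
#'   \item{n_outer_iters, converged}{outer-loop diagnostics}
#'   \item{trace}{data frame of (iteration, shape coefficients, pooled
#'     log-likelihood), recorded after each full alternation}
#'   \item{excluded}{subject ids excluded as degenerate}
#' @export
fit_cohort <- function(cohort, config = fit_config()) {
  cohort <- check_cohort(cohort)
  if (length(cohort) < 2) stop("need at least 2 subjects")
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  cohort <- cohort[order(ids)]  # deterministic pooling order
  ids <- ids[order(ids)]

  degen <- vapply(cohort, function(s) all(s$data$count == 0), logical(1))
  excluded_ids <- ids[degen]
  if (mean(degen) > 0.2)
    stop("more than 20% of subjects have all-zero counts; failed subjects: ",
         paste(excluded_ids, collapse = ", "))
  if (any(degen)) {
    warning("excluding ", sum(degen), " all-zero subject(s): ",
            paste(excluded_ids, collapse = ", "))
    cohort <- cohort[!degen]
    ids <- ids[!degen]
  }
  if (length(cohort) < 2) stop("fewer than 2 non-degenerate subjects remain")

  shape <- harmonic_shape(coeffs = rep(0, config$K - 1))
  params <- vector("list", length(cohort))
  trace <- vector("list", config$max_outer_iters)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_outer_iters) {
    iter <- iter + 1L
    for (i in seq_along(cohort))
      params[[i]] <- fit_subject(cohort[[i]], shape, config,
                                 init = params[[i]], grid = iter <= 2)
    coeffs_old <- shape$coeffs
    shape <- fit_shape(cohort, params, shape)
    ll <- sum(vapply(seq_along(cohort), function(i) {
      d <- cohort[[i]]$data
      p <- params[[i]]
      pois_full_loglik(d$count,
                       subject_eta(d$t, c(p$A, p$B, p$phi), c(1, shape$coeffs)))
    }, numeric(1)))
    trace[[iter]] <- c(iter = iter, shape$coeffs, loglik = ll)
    dcoef <- max(abs(shape$coeffs - coeffs_old))
    if (dcoef < config$tol * (1 + max(abs(coeffs_old))) &&
        is.finite(ll_old) &&
        abs(ll - ll_old) < config$tol * (1 + abs(ll_old))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("stage-1 alternation did not converge in ",
            config$max_outer_iters, " iterations")

  trace <- as.data.frame(do.call(rbind, trace[seq_len(iter)]))
  names(trace) <- c("iter", paste0("beta", 2:config$K), "loglik")

  se <- t(vapply(params, function(p) attr(p, "se"), numeric(3)))
  subjects <- data.frame(
    subject = ids,
    A = vapply(params, `[[`, numeric(1), "A"),
    B = vapply(params, `[[`, numeric(1), "B"),
    phi = vapply(params, `[[`, numeric(1), "phi"),
    phi_star = vapply(params, `[[`, numeric(1), "phi_star"),
    loglik = vapply(params, function(p) attr(p, "loglik"), numeric(1)),
    converged = vapply(params, function(p) attr(p, "converged"), logical(1)),
    boundary = vapply(params, function(p) attr(p, "boundary"), logical(1)),
    se_A = se[, 1], se_B = se[, 2], se_phi = se[, 3],
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, shape = shape,
                 total_loglik = ll_old, n_outer_iters = iter,
                 converged = converged, trace = trace,
                 excluded = excluded_ids,
                 config = config),
            class = "circshape_fit")
}

#' @export
print.circshape_fit <- function(x, ...) {
  cat("Shape-invariant Poisson fit (stage 1)\n")
  cat(sprintf("  %d subjects, K = %d harmonics\n",
              nrow(x$subjects), x$shape$K))
  cat(sprintf("  shared shape coefficients: %s\n",
              paste(formatC(x$shape$coeffs, digits = 4, format = "f"),
                    collapse = ", ")))
  cat(sprintf("  pooled log-likelihood: %.2f after %d outer iteration(s)%s\n",
              x$total_loglik, x$n_outer_iters,
              if (x$converged) " (converged)" else " (NOT converged)"))
  invisible(x)
}
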