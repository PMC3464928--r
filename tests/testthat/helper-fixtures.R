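# Build one subject's Poisson series from known parameters on the
# day x bin grid; used throughout as the ground-truth generator for
# single-subject tests (cohort-level tests use simulate_cohort()).
make_series <- function(A, B, phi, D = 0.4, n_days = 7, bins_per_day = 96,
                        seed = 1, id = "S1") {
  set.seed(seed)
  tg <- time_grid(bins_per_day)
  lam <- exp(A + exp(-B) * shape_function(tg, plogis(phi),
                                          harmonic_shape(D = D)))
  activity_series(
    subject_id = id,
    day = rep(seq_len(n_days), each = bins_per_day),
    bin = rep(seq_len(bins_per_day), times = n_days),
    count = rpois(n_days * bins_per_day, rep(lam, n_days)),
    bins_per_day = bins_per_day
  )
}

# Restrict every subject of a cohort to its first n_days of monitoring.
subset_days <- function(series, nd) lapply(series, function(s) {
  keep <- s$data$day <= nd
  activity_series(s$subject_id, s$data$day[keep], s$data$bin[keep],
                  s$data$count[keep], bins_per_day = s$bins_per_day,
                  group = s$group)
})

# Full Poisson log-likelihood of a series at given parameters and shape;
# an independent reference used when comparing fits against brute force.
ref_loglik <- function(series, A, B, phi_star, D) {
  t <- series$data$t
  y <- series$data$count
  lam <- exp(A + exp(-B) * (cos(2 * pi * (t + phi_star)) +
                              D * cos(4 * pi * (t + phi_star))))
  sum(dpois(y, lam, log = TRUE))
}
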