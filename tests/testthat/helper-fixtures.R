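# Shared fixtures: default acquisition protocol, agent model, and lazily
# built (session-cached) calibration curve and phantom helpers.

test_protocol <- cest_protocol()
test_model <- iopamidol_model()

# pipeline-default calibration; acidocest caches it per fingerprint so the
# forward simulations run once per test session
test_curve <- function() default_calibration(test_protocol, test_model)

# small phantom spec used across tests
small_spec <- function(mean_ph = 6.8, sd = 0, core_rim = 0, snr = Inf,
                       matrix = c(32, 32), n_slices = 1, seed = 1, ...) {
  phantom_spec(matrix = matrix, n_slices = n_slices,
               ph_field = list(mean = mean_ph, core_rim = core_rim, sd = sd),
               snr = snr, seed = seed, ...)
}

# two-pool reference systems for propagator checks
two_pool <- function(k = 300, f = 2e-4, shift = 4.2) {
  list(water_pool(),
       cest_pool("solute", shift, T1 = 1, T2 = 0.01, fraction = f,
                 exchange_rate = k))
}

# exact permutation oracle for the two-group log-rank test: enumerate all
# group relabelings and compare the chi-square statistic
logrank_perm_p <- function(time, status, group) {
  obs <- survival::survdiff(survival::Surv(time, status) ~ group)$chisq
  n <- length(group)
  idx1 <- which(group == unique(group)[1])
  combs <- utils::combn(n, length(idx1))
  stats <- apply(combs, 2, function(sel) {
    g <- rep("b", n); g[sel] <- "a"
    if (length(unique(g)) < 2) return(NA_real_)
    survival::survdiff(survival::Surv(time, status) ~ g)$chisq
  })
  mean(stats >= obs - 1e-12, na.rm = TRUE)
}

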