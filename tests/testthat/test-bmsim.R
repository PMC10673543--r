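# Bloch-McConnell propagator: physical limits, equivalence with explicit
# time-stepping integration, and water-shift estimation.

test_that("zero saturation amplitude leaves the system at equilibrium", {
  prot <- cest_protocol(b1_amplitude = 0, offsets = seq(-6, 6, 0.5))
  zs <- simulate_zspectrum(two_pool(), prot)
  expect_equal(zs$z_values, rep(1, length(prot$offsets)), tolerance = 1e-8)

  prot_tiny <- cest_protocol(saturation_duration = 1e-9,
                             offsets = seq(-6, 6, 0.5))
  zs2 <- simulate_zspectrum(two_pool(), prot_tiny)
  expect_equal(zs2$z_values, rep(1, length(prot_tiny$offsets)),
               tolerance = 1e-6)
})

test_that("without exchange there is no saturation transfer at the amide offset", {
  # free-water relaxation keeps direct saturation negligible at 5.5 ppm
  water <- water_pool(T1 = 2, T2 = 2)
  solute <- cest_pool("solute", 5.5, T1 = 1, T2 = 0.01,
                      fraction = 2e-4, exchange_rate = 0)
  prot <- cest_protocol(offsets = c(5.5))
  z <- simulate_zspectrum(list(water, solute), prot)$z_values
  expect_gt(z, 0.99)
  # and the non-exchanging solute is invisible: equal to water alone
  z_w <- simulate_zspectrum(list(water), prot)$z_values
  expect_equal(z, z_w, tolerance = 1e-9)
})

test_that("matrix-exponential propagation matches explicit fine-step ODE integration", {
  skip_if_not_installed("deSolve")
  # full 5 s pulse on the 2-pool system; 1 s on the 3-pool system with the
  # semisolid pool, whose fast transverse dynamics make adaptive
  # integration expensive (method equivalence is duration-independent)
  cases <- list(
    list(pools = two_pool(), tsat = 5, offsets = c(0.5, 4.2)),
    list(pools = c(two_pool(k = 1000, f = 1e-4, shift = 5.5),
                   list(cest_pool("mt", -2.4, 1, 1e-5, 0.03, 30))),
         tsat = 1, offsets = c(0.5, 5.5)))
  for (cs in cases) {
    prot <- cest_protocol(saturation_duration = cs$tsat,
                          offsets = cs$offsets)
    pools <- acidocest:::validate_pools(cs$pools)
    n <- length(pools)
    m0 <- numeric(3 * n + 1)
    m0[3 * seq_len(n)] <- vapply(pools, `[[`, 0, "fraction")
    m0[3 * n + 1] <- 1
    z_main <- simulate_zspectrum(pools, prot)$z_values
    z_ode <- vapply(sort(cs$offsets), function(off) {
      A <- acidocest:::bm_generator(pools, off, prot$b1_amplitude,
                                    prot$field_strength)
      sol <- deSolve::ode(
        y = m0, times = c(0, cs$tsat),
        func = function(t, y, p) list(as.numeric(A %*% y)),
        method = "lsoda", rtol = 1e-11, atol = 1e-13, maxsteps = 500000)
      sol[2, 1 + 3]
    }, 0)
    expect_equal(z_main, z_ode, tolerance = 1e-6)
  }
})

test_that("Z stays within [0, 1] over randomized physical parameter sweeps", {
  set.seed(42)
  prot <- cest_protocol(offsets = seq(-8, 8, 1))
  for (i in 1:25) {
    pools <- list(
      water_pool(T1 = runif(1, 0.5, 4), T2 = runif(1, 0.02, 0.2)),
      cest_pool("s1", runif(1, 1, 6), runif(1, 0.3, 2), runif(1, 0.005, 0.05),
                runif(1, 1e-5, 5e-3), runif(1, 0, 5000)),
      cest_pool("s2", runif(1, -4, -1), runif(1, 0.3, 2), runif(1, 1e-5, 0.01),
                runif(1, 1e-4, 0.1), runif(1, 0, 100)))
    z <- simulate_zspectrum(pools, prot)$z_values
    expect_true(all(z >= -1e-10 & z <= 1 + 1e-10))
  }
})

test_that("saturation transfer grows with exchange rate in the slow-intermediate regime", {
  # slow-to-intermediate regime: rates below the saturation amplitude
  # omega1 = 2 pi gamma B1 ~ 800 rad/s (and far below the shift separation)
  rates <- c(20, 50, 150, 400, 700)
  prot <- cest_protocol(offsets = c(4.2))
  st <- vapply(rates, function(k)
    1 - simulate_zspectrum(two_pool(k = k), prot)$z_values, 0)
  expect_true(all(diff(st) >= -1e-10))
})

test_that("non-physical pool parameters are rejected", {
  expect_error(cest_pool("x", 4.2, T1 = -1, T2 = 0.01, fraction = 1e-4,
                         exchange_rate = 10), "T1")
  expect_error(cest_pool("x", 4.2, T1 = 1, T2 = 0.01, fraction = 1.2,
                         exchange_rate = 10), "fraction")
  expect_error(simulate_zspectrum(list(two_pool()[[2]]), cest_protocol()),
               "water")
})

test_that("water shift is recovered from the spectral minimum", {
  prot <- cest_protocol(offsets = seq(-3, 3, 0.1))
  zs <- simulate_zspectrum(list(water_pool()), prot)
  expect_equal(water_shift_of(zs), 0, tolerance = 1e-3)

  shifted <- zspectrum(zs$offsets, zs$z_values)
  shifted$offsets <- shifted$offsets  # translation: resample the same dip at +0.3
  zs03 <- zspectrum(seq(-3, 3, 0.1),
                    approx(zs$offsets + 0.3, zs$z_values,
                           xout = seq(-3, 3, 0.1), rule = 2)$y)
  expect_equal(water_shift_of(zs03), 0.3, tolerance = 0.02)

  # injected B0 offset at finite SNR: the estimator is unbiased and its
  # RMSE sits near the information limit of the flat-bottomed dip
  pools <- c(list(water_pool()), background_pools())
  prot2 <- cest_protocol(offsets = seq(-3, 3, 0.1) + 0.1)
  # simulate with the water at +0.1 ppm by shifting the evaluation grid
  z_true <- simulate_zspectrum(pools, cest_protocol(offsets = prot2$offsets - 0.1))
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- zspectrum(prot2$offsets,
                       pmax(z_true$z_values + rnorm(length(z_true$z_values),
                                                    0, 1 / 50), 0))
    water_shift_of(noisy, smoothing = default_smoothing()) - 0.1
  }, 0)
  expect_lt(abs(mean(errs)), 0.01)
  expect_lt(sqrt(mean(errs^2)), 0.025)

  # dip not bracketed
  zs_nar <- zspectrum(seq(1, 3, 0.1), rep(0.9, 21))
  expect_error(water_shift_of(zs_nar), "water dip")
})
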