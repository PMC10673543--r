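# Z-spectrum processing: spline behaviour, ST readout, B0 correction,
# delta-ST contract, mask locality.

test_that("zero smoothing interpolates samples exactly; constants stay constant", {
  x <- seq(-5, 5, 0.5)
  pools <- c(list(water_pool()), background_pools())
  zs <- simulate_zspectrum(pools, cest_protocol(offsets = x))
  f <- smooth_zspectrum(zs, smoothing = 0)
  expect_equal(f(x), zs$z_values, tolerance = 1e-12)

  zc <- zspectrum(x, rep(0.7, length(x)))
  fc <- smooth_zspectrum(zc, smoothing = default_smoothing())
  expect_equal(fc(seq(-4.9, 4.9, 0.05)), rep(0.7, 197), tolerance = 1e-9)

  expect_error(smooth_zspectrum(zspectrum(x[1:5], rep(0.5, 5))), "at least 8")
  expect_error(zspectrum(c(1, 1, 2, 3, 4, 5, 6, 7), rep(0.5, 8)),
               "strictly increasing")
})

test_that("smoothing reduces deviation from the noiseless truth", {
  prot <- cest_protocol()
  truth <- simulate_zspectrum(c(list(water_pool()), background_pools()), prot)
  set.seed(21)
  noisy_z <- truth$z_values + rnorm(length(truth$z_values), 0, 1 / 40)
  noisy <- zspectrum(prot$offsets, noisy_z)
  sm <- smooth_zspectrum(noisy, smoothing = default_smoothing())
  rms_raw <- sqrt(mean((noisy_z - truth$z_values)^2))
  rms_sm <- sqrt(mean((sm(prot$offsets) - truth$z_values)^2))
  expect_lt(rms_sm, rms_raw)
})

test_that("the cached linear-smoother path equals the reference spline", {
  prot <- cest_protocol()
  set.seed(5)
  y <- 0.8 + 0.1 * sin(prot$offsets) + rnorm(length(prot$offsets), 0, 0.02)
  zs <- zspectrum(prot$offsets, y)
  lam <- default_smoothing()
  ref <- smooth_zspectrum(zs, lam)
  S <- acidocest:::spline_hat_matrix(prot$offsets, lam)
  fast <- stats::splinefun(prot$offsets, drop(S %*% y), method = "natural")
  p <- seq(-9.5, 9.5, 0.17)
  expect_equal(fast(p), ref(p), tolerance = 1e-7)
})

test_that("ST readout responds to the agent and respects B0 correction", {
  prot <- cest_protocol()
  base <- c(list(water_pool()), background_pools())
  agent <- c(base, iopamidol_pools(test_model, 6.8))
  z_noag <- simulate_zspectrum(base, prot)
  z_ag <- simulate_zspectrum(agent, prot)
  f_noag <- smooth_zspectrum(z_noag, default_smoothing())
  f_ag <- smooth_zspectrum(z_ag, default_smoothing())
  expect_gt(st_at(f_ag, 4.2), st_at(f_noag, 4.2))

  # Z identically 1 gives ST 0
  ones <- smooth_zspectrum(zspectrum(prot$offsets,
                                     rep(1, length(prot$offsets))), 0)
  expect_equal(st_at(ones, 4.2), 0, tolerance = 1e-9)

  # a 0.3 ppm B0 shift, once corrected, reproduces the unshifted ST to 2%
  shifted <- zspectrum(prot$offsets,
                       splinefun(prot$offsets + 0.3, z_ag$z_values,
                                 method = "natural")(prot$offsets))
  f_sh <- smooth_zspectrum(shifted, default_smoothing())
  ws <- water_shift_of(shifted, smoothing = default_smoothing())
  expect_equal(ws, 0.3, tolerance = 0.02)
  st_ref <- st_at(f_ag, 4.2)
  expect_lt(abs(st_at(f_sh, 4.2, water_shift = ws) - st_ref) / st_ref, 0.02)
})

test_that("delta-ST of identical stacks is exactly zero and unreliable", {
  a <- generate_animal(small_spec(agent_mM = 0, snr = Inf, seed = 6))
  proc <- process_stacks(a$pre, a$pre, a$truth$tumor_mask)
  for (d in proc$delta) {
    expect_true(all(d$values[a$truth$tumor_mask] == 0))
    expect_false(any(d$reliability))
  }
})

test_that("delta-ST is positive at both offsets on a noiseless agent phantom", {
  a <- generate_animal(small_spec(mean_ph = 6.8, snr = Inf, seed = 6))
  proc <- process_stacks(a$pre, a$post, a$truth$tumor_mask)
  msk <- a$truth$tumor_mask
  expect_true(all(proc$delta[["4.2"]]$values[msk] > 0))
  expect_true(all(proc$delta[["5.5"]]$values[msk] > 0))
  expect_true(all(proc$delta[["4.2"]]$reliability[msk]))
})

test_that("geometry mismatches and missing-phase voxels are handled", {
  v1 <- array(0.1, c(4, 4, 1)); v2 <- array(0.1, c(4, 5, 1))
  expect_error(delta_st(st_map(v1, 4.2, "pre"), st_map(v2, 4.2, "post")),
               "geometry")
  pre <- v1; pre[2, 2, 1] <- NA
  d <- delta_st(st_map(pre, 4.2, "pre"), st_map(v1 + 0.1, 4.2, "post"))
  expect_false(d$reliability[2, 2, 1])
  expect_true(d$reliability[1, 1, 1])
})

test_that("agent contrast grows monotonically with concentration", {
  concs <- c(1, 3, 10, 30)
  st <- vapply(concs, function(cc)
    acidocest:::agent_delta_st(test_model, 6.8, test_protocol,
                               background = background_pools(),
                               concentration_mM = cc,
                               smoothing = default_smoothing()),
    c(d42 = 0, d55 = 0))
  expect_true(all(diff(st["d42", ]) > 0))
  expect_true(all(diff(st["d55", ]) > 0))
})

test_that("voxels outside the mask never influence in-mask outputs", {
  a <- generate_animal(small_spec(mean_ph = 6.75, sd = 0.05, snr = 40, seed = 8))
  msk <- a$truth$tumor_mask
  p1 <- process_stacks(a$pre, a$post, msk)
  b <- a
  out <- !msk
  for (k in seq_along(b$pre$protocol$offsets)) {
    sl_pre <- b$pre$voxels[, , , k]; sl_pre[out] <- 999
    b$pre$voxels[, , , k] <- sl_pre
    sl_post <- b$post$voxels[, , , k]; sl_post[out] <- 999
    b$post$voxels[, , , k] <- sl_post
  }
  p2 <- process_stacks(b$pre, b$post, msk)
  expect_identical(p1$delta[["4.2"]]$values[msk], p2$delta[["4.2"]]$values[msk])
  expect_identical(p1$delta[["5.5"]]$values[msk], p2$delta[["5.5"]]$values[msk])
})
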