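# Phantom generator: determinism, noise model, ground-truth bookkeeping,
# cohort construction.

test_that("no agent and no noise make pre and post stacks identical", {
  a <- generate_animal(small_spec(agent_mM = 0, snr = Inf, seed = 2))
  expect_equal(a$pre$voxels, a$post$voxels, tolerance = 1e-10)
})

test_that("identical seeds give bit-identical phantoms", {
  sp <- small_spec(sd = 0.05, snr = 40, seed = 11)
  a1 <- generate_animal(sp)
  a2 <- generate_animal(sp)
  expect_identical(a1$pre$voxels, a2$pre$voxels)
  expect_identical(a1$post$voxels, a2$post$voxels)
  expect_identical(a1$truth$ph_map, a2$truth$ph_map)
  # and a different seed does not
  a3 <- generate_animal(small_spec(sd = 0.05, snr = 40, seed = 12))
  expect_false(identical(a1$pre$voxels, a3$pre$voxels))
})

test_that("ground-truth mask mean equals the configured pH mean", {
  sp <- small_spec(mean_ph = 6.73, sd = 0.06, core_rim = 0.25, seed = 5)
  a <- generate_animal(sp)
  expect_equal(mean(a$truth$ph_map[a$truth$tumor_mask]), 6.73,
               tolerance = 1e-9)
})

test_that("Rician noise approaches the Gaussian limit at high SNR", {
  set.seed(3)
  s <- rep(100, 2e5)
  sigma <- 100 / 500                      # SNR 500
  noisy <- acidocest:::add_rician(array(s, length(s)), sigma)
  expect_equal(sd(noisy), sigma, tolerance = 0.05)
  expect_equal(mean(noisy), 100 + sigma^2 / (2 * 100), tolerance = 1e-3)
  # at low signal the Rician floor appears (mean > signal)
  floor_sample <- acidocest:::add_rician(array(0, 2e4), 1)
  expect_equal(mean(floor_sample), sqrt(pi / 2), tolerance = 0.05)
})

test_that("noiseless uniform phantom closes the forward/inverse loop", {
  a <- generate_animal(small_spec(mean_ph = 6.8, snr = Inf, seed = 3))
  r <- animal_phe(a, test_curve())
  expect_equal(r$phe$mean_pHe, 6.80, tolerance = 0.02)
  expect_gt(r$phe$coverage, 0.95)
})

test_that("tumor geometry outside the matrix is rejected", {
  expect_error(phantom_spec(matrix = c(32, 32), n_slices = 1,
                            tumor = list(center = c(30, 30),
                                         radii = c(8, 8),
                                         slice_profile = 1)),
               "exceeds")
})

test_that("cohort generation is deterministic and carries the survival rule", {
  tmpl <- small_spec(mean_ph = 6.77, sd = 0.04, core_rim = 0.2)
  c1 <- generate_cohort(tmpl, n_per_group = 3, seed = 9, imaging = FALSE)
  c2 <- generate_cohort(tmpl, n_per_group = 3, seed = 9, imaging = FALSE)
  expect_identical(c1$table, c2$table)
  tb <- c1$table
  expect_setequal(unique(tb$group), c("control", "treated"))
  expect_true(all(tb$diameter_A >= tb$diameter_B))
  # event time is the first day the volume rule fires
  one <- tb[tb$animal_id == tb$animal_id[1], ]
  vol <- tumor_volume(one$diameter_A, one$diameter_B)
  if (one$event_flag[1] == 1) {
    expect_equal(one$event_time[1], one$day[min(which(vol > 800))])
  } else {
    expect_true(all(vol <= 800))
  }
})

test_that("single-animal groups build but the statistics stage refuses tests", {
  tmpl <- small_spec()
  coh <- generate_cohort(tmpl, n_per_group = 1, seed = 4, imaging = FALSE)
  expect_equal(nrow(unique(coh$table[, c("animal_id", "group")])), 2)
  expect_error(cohort_report(coh$table), "at least 2 animals")
})

test_that("null group effects produce no systematic pH separation", {
  tmpl <- small_spec(mean_ph = 6.8, sd = 0.04, snr = 40)
  pvals <- vapply(1:3, function(i) {
    coh <- generate_cohort(tmpl, n_per_group = 4,
                           group_effects = list(control = list(ph = 0, growth = 1),
                                                sham = list(ph = 0, growth = 1)),
                           seed = 100 + i)
    m <- vapply(coh$animals, function(a)
      animal_phe(a, test_curve())$phe$mean_pHe, 0)
    g <- vapply(coh$animals, `[[`, "", "group")
    s <- split(m, g)
    t_test_from_summary(
      summary_stat("a", mean(s[[1]]), sd(s[[1]]), length(s[[1]])),
      summary_stat("b", mean(s[[2]]), sd(s[[2]]), length(s[[2]])))$p
  }, 0)
  # under the null it is vanishingly unlikely that every replicate rejects
  expect_false(all(pvals < 0.05))
})
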