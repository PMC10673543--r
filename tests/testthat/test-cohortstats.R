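# Cohort statistics: volume formula, summary t, ANOVA/Bonferroni,
# Shapiro-Wilk, Kaplan-Meier with a permutation oracle.

test_that("caliper volume follows V = A B^2 / 2 and scales cubically", {
  expect_equal(tumor_volume(10, 5), 125)
  d <- c(3, 7.5, 12)
  expect_equal(tumor_volume(d, d), d^3 / 2)
  expect_equal(tumor_volume(9, 0), 0)
  expect_error(tumor_volume(4, 5), "longest")
  set.seed(2)
  for (i in 1:10) {
    B <- runif(1, 1, 10); A <- B * runif(1, 1, 2); k <- runif(1, 0.5, 3)
    expect_equal(tumor_volume(k * A, k * B), k^3 * tumor_volume(A, B),
                 tolerance = 1e-12)
  }
})

test_that("summary t-test matches hand-computed pooled t and raw-data t.test", {
  # identical groups
  g <- summary_stat("a", 5, 1, 6)
  expect_equal(t_test_from_summary(g, g), list(t = 0, df = 10, p = 1))

  # hand-computed oracle for the tumor-weight comparison:
  # sp2 = (5*0.15^2 + 5*0.09^2)/10 = 0.0153, t = 0.42/sqrt(0.0153/3) = 5.8812
  sp2 <- (5 * 0.15^2 + 5 * 0.09^2) / 10
  t_hand <- (1.16 - 0.74) / sqrt(sp2 * (2 / 6))
  res <- t_test_from_summary(summary_stat("ctrl", 1.16, 0.15, 6),
                             summary_stat("trt", 0.74, 0.09, 6))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$t, 5.8812, tolerance = 1e-4)
  expect_equal(res$df, 10)

  # equals t.test on raw data to 1e-12, across simulated cohorts
  set.seed(14)
  for (i in 1:6) {
    x <- rnorm(4 + i, 10, 2); y <- rnorm(9 - i, 9, 3)
    rs <- t_test_from_summary(
      summary_stat("x", mean(x), sd(x), length(x)),
      summary_stat("y", mean(y), sd(y), length(y)))
    rt <- t.test(x, y, var.equal = TRUE)
    expect_equal(rs$t, unname(rt$statistic), tolerance = 1e-12)
    expect_equal(rs$p, rt$p.value, tolerance = 1e-12)
  }

  expect_error(t_test_from_summary(summary_stat("a", 1, 0, 6),
                                   summary_stat("b", 2, 0, 6)),
               "zero pooled variance")
  expect_error(t_test_from_summary(summary_stat("a", 1, 1, 1), g), "n >= 2")
})

test_that("Welch variant matches t.test(var.equal = FALSE)", {
  set.seed(15)
  x <- rnorm(6, 0, 1); y <- rnorm(9, 0.5, 3)
  rs <- welch_test_from_summary(
    summary_stat("x", mean(x), sd(x), length(x)),
    summary_stat("y", mean(y), sd(y), length(y)))
  rt <- t.test(x, y)
  expect_equal(rs$t, unname(rt$statistic), tolerance = 1e-12)
  expect_equal(rs$df, unname(rt$parameter), tolerance = 1e-9)
})

test_that("ANOVA with Bonferroni inflates raw p and reduces to t^2 = F for 2 groups", {
  set.seed(8)
  gs <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1))
  res <- anova_bonferroni(gs)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj <= 1))
  expect_equal(res$pairwise$p_adj,
               pmin(1, 3 * res$pairwise$p_raw), tolerance = 1e-12)

  two <- gs[1:2]
  res2 <- anova_bonferroni(two)
  tt <- t_test_from_summary(
    summary_stat("a", mean(two$a), sd(two$a), 6),
    summary_stat("b", mean(two$b), sd(two$b), 6))
  expect_equal(res2$F, tt$t^2, tolerance = 1e-9)
  expect_error(anova_bonferroni(list(a = rnorm(5), b = numeric(0))), "n >= 2")
})

test_that("two-way ANOVA reports group, time and interaction terms", {
  set.seed(9)
  d <- expand.grid(g = c("c", "t"), day = c(0, 7, 14), rep = 1:5)
  y <- rnorm(nrow(d)) + (d$g == "t") * (d$day / 14) * 2
  res <- anova_two_way(y, d$g, d$day)
  rn <- trimws(rownames(res$table))
  expect_setequal(rn[1:3], c("group", "time", "group:time"))
  expect_true(all(res$within_time$p_adj >= res$within_time$p_raw))
})

test_that("Shapiro-Wilk wrapper enforces its domain and has calibrated p-values", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  set.seed(10)
  p_null <- replicate(200, shapiro_wilk(rnorm(20))$p)
  ks <- ks.test(p_null, "punif")
  expect_gt(ks$p.value, 0.01)
  p_exp <- replicate(200, shapiro_wilk(rexp(50))$p)
  expect_gt(mean(p_exp < 0.05), 0.5)
})

test_that("Kaplan-Meier and log-rank behave on toy and simulated cohorts", {
  # identical event times in both groups: p = 1
  tb <- data.frame(animal_id = sprintf("m%d", 1:8),
                   group = rep(c("a", "b"), each = 4),
                   event_time = rep(c(5, 8, 11, 14), 2),
                   event_flag = 1)
  expect_equal(km_survival(tb)$logrank_p, 1, tolerance = 1e-9)

  # hand-computed KM products on a 6-animal toy table (all events observed):
  # deaths at 3, 5, 9 in a group of 3: S = 2/3, 1/3, 0
  tb2 <- data.frame(animal_id = sprintf("m%d", 1:6),
                    group = rep(c("a", "b"), each = 3),
                    event_time = c(3, 5, 9, 4, 8, 12),
                    event_flag = 1)
  km <- km_survival(tb2)
  sa <- summary(km$fit)$surv[summary(km$fit)$strata == "group=a"]
  expect_equal(sa, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # clearly separated groups reach significance at n = 6/group
  tb3 <- data.frame(animal_id = sprintf("m%d", 1:12),
                    group = rep(c("a", "b"), each = 6),
                    event_time = c(3, 4, 5, 6, 7, 8, 15, 16, 17, 18, 19, 20),
                    event_flag = 1)
  expect_lt(km_survival(tb3)$logrank_p, 0.05)

  # asymptotic log-rank p tracks the exact permutation oracle at n = 12
  set.seed(12)
  t1 <- rexp(6, 1 / 10); t2 <- rexp(6, 1 / 20)
  tm <- c(t1, t2); st <- rep(1, 12); gr <- rep(c("a", "b"), each = 6)
  p_perm <- logrank_perm_p(tm, st, gr)
  tb4 <- data.frame(animal_id = sprintf("m%d", 1:12), group = gr,
                    event_time = tm, event_flag = st)
  expect_lt(abs(km_survival(tb4)$logrank_p - p_perm), 0.06)

  # all-censored group: curves returned, flagged unstable
  tb5 <- tb3; tb5$event_flag[tb5$group == "b"] <- 0
  res5 <- km_survival(tb5)
  expect_true(res5$unstable)
  expect_s3_class(res5$fit, "survfit")
})

test_that("malformed cohort TSV rows raise line-numbered errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("animal_id\tgroup\tday\tdiameter_A\tdiameter_B\tbody_weight\tevent_time\tevent_flag",
               "m01\tcontrol\t0\t4.1\t3.2\t20.1\t21\t1",
               "m02\tcontrol\t0\t4.4"), f)
  expect_error(read_cohort_tsv(f), "line 3")
  f2 <- tempfile(fileext = ".tsv")
  tb <- data.frame(animal_id = "m01", group = "g", day = 0,
                   diameter_A = 4, diameter_B = 3, body_weight = 20,
                   event_time = 21, event_flag = 1)
  write_cohort_tsv(tb, f2)
  expect_equal(read_cohort_tsv(f2), tb)
})
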