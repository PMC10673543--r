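# Cohort-level efficacy readouts: caliper tumor volume, group comparisons
# from raw data or printed summaries, ANOVA with Bonferroni correction,
# normality checks, and Kaplan-Meier survival with log-rank tests.

#' Caliper tumor volume
#'
#' `V = A * B^2 / 2` with `A` the longest and `B` the shortest of two
#' perpendicular caliper diameters (mm); the result is in mm^3.
#'
#' @param A,B Diameters in mm, `A >= B >= 0` (vectorised).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(A, B) {
  if (any(B < 0)) stop("diameters must be non-negative")
  if (any(A < B)) stop("A must be the longest diameter (A >= B)")
  A * B^2 / 2
}

#' Group summary statistic
#'
#' @param group Group label.
#' @param mean,sd,n Group mean, standard deviation (>= 0) and size.
#' @return Object of class `summary_stat`.
#' @export
summary_stat <- function(group, mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 1)
  structure(list(group = group, mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stat")
}

#' Pooled-variance unpaired t-test from printed summaries
#'
#' Classic (Student) two-sample t-test recomputed from `mean +- SD` and `n`
#' per group: `t = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))` with the pooled
#' variance `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `df = n1 + n2 - 2`, two-sided p from the t distribution. This is the
#' equal-variance Student test (not Welch), matching equal-n designs whose
#' publications report only group summaries.
#'
#' @param g1,g2 [summary_stat()] objects with `n >= 2`.
#' @return List with `t`, `df`, `p`.
#' @examples
#' t_test_from_summary(summary_stat("ctrl", 1.16, 0.15, 6),
#'                     summary_stat("trt", 0.74, 0.09, 6))
#' @export
t_test_from_summary <- function(g1, g2) {
  stopifnot(inherits(g1, "summary_stat"), inherits(g2, "summary_stat"))
  if (g1$n < 2 || g2$n < 2) stop("both groups need n >= 2")
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  if (sp2 == 0) {
    if (g1$mean == g2$mean) return(list(t = 0, df = df, p = 1))
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Welch variant of the summary t-test
#'
#' Available behind a separate function for unequal-variance designs.
#'
#' @inheritParams t_test_from_summary
#' @return List with `t`, `df` (Welch-Satterthwaite), `p`.
#' @export
welch_test_from_summary <- function(g1, g2) {
  stopifnot(inherits(g1, "summary_stat"), inherits(g2, "summary_stat"))
  if (g1$n < 2 || g2$n < 2) stop("both groups need n >= 2")
  v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) {
    if (g1$mean == g2$mean) return(list(t = 0, df = g1$n + g2$n - 2, p = 1))
    stop("zero variance with unequal means: t undefined")
  }
  tt <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Fits the one-way ANOVA F-test over all groups, then runs pooled-variance
#' pairwise t-tests for the requested comparisons and adjusts them with the
#' pure Bonferroni rule `p_adj = min(1, m * p_raw)` for `m` comparisons
#' (alpha splitting, not Holm).
#'
#' @param groups Named list of numeric sample vectors (>= 2 groups, each
#'   `n >= 2`).
#' @param comparisons List of 2-element character vectors naming the
#'   pairwise contrasts; default all pairs.
#' @return List with `F`, `df`, `p_overall` and a data.frame `pairwise`
#'   (`group1`, `group2`, `p_raw`, `p_adj`).
#' @export
anova_bonferroni <- function(groups, comparisons = NULL) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs n >= 2 (empty/singleton group)")
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), ns), levels = names(groups))
  fit <- stats::aov(y ~ f)
  tab <- summary(fit)[[1]]
  if (is.null(comparisons))
    comparisons <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(comparisons)
  pw <- do.call(rbind, lapply(comparisons, function(cp) {
    a <- groups[[cp[1]]]; b <- groups[[cp[2]]]
    tt <- t_test_from_summary(
      summary_stat(cp[1], mean(a), stats::sd(a), length(a)),
      summary_stat(cp[2], mean(b), stats::sd(b), length(b)))
    data.frame(group1 = cp[1], group2 = cp[2], p_raw = tt$p,
               p_adj = min(1, m * tt$p))
  }))
  list(F = tab$`F value`[1], df = tab$Df, p_overall = tab$`Pr(>F)`[1],
       pairwise = pw)
}

#' Two-way ANOVA for group-by-time designs
#'
#' `y ~ group * time` with both factors crossed; reports the factor and
#' interaction F-tests plus Bonferroni-adjusted group contrasts within each
#' time level.
#'
#' @param y Numeric response.
#' @param group,time Factors (coerced) of the same length as `y`.
#' @return List with the ANOVA `table` and `within_time` pairwise contrasts.
#' @export
anova_two_way <- function(y, group, time) {
  group <- factor(group); time <- factor(time)
  stopifnot(length(y) == length(group), length(y) == length(time))
  fit <- stats::aov(y ~ group * time)
  tab <- summary(fit)[[1]]
  lv <- levels(time)
  m <- length(lv) * choose(nlevels(group), 2)
  rows <- list()
  for (tl in lv) {
    sel <- time == tl
    gs <- split(y[sel], droplevels(group[sel]))
    if (length(gs) < 2 || any(lengths(gs) < 2)) next
    for (cp in utils::combn(names(gs), 2, simplify = FALSE)) {
      tt <- t_test_from_summary(
        summary_stat(cp[1], mean(gs[[cp[1]]]), stats::sd(gs[[cp[1]]]), length(gs[[cp[1]]])),
        summary_stat(cp[2], mean(gs[[cp[2]]]), stats::sd(gs[[cp[2]]]), length(gs[[cp[2]]])))
      rows[[length(rows) + 1]] <- data.frame(
        time = tl, group1 = cp[1], group2 = cp[2],
        p_raw = tt$p, p_adj = min(1, m * tt$p))
    }
  }
  list(table = tab, within_time = do.call(rbind, rows))
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p-value; refuses degenerate inputs.
#'
#' @param x Numeric sample, `3 <= n <= 5000`, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", length(x))
  if (stats::sd(x) == 0) stop("constant sample: W undefined")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Kaplan-Meier survival curves with log-rank test
#'
#' One curve per group from per-animal event times, plus the two-group (or
#' k-group) log-rank test. When any group has no observed events the test
#' is flagged unstable but curves are still returned.
#'
#' @param table Cohort `data.frame` with columns `animal_id`, `group`,
#'   `event_time`, `event_flag` (one row per animal is extracted).
#' @return List with `fit` ([survival::survfit()]), `logrank_p`,
#'   `chisq`, `unstable`.
#' @export
km_survival <- function(table) {
  need <- c("animal_id", "group", "event_time", "event_flag")
  if (!all(need %in% names(table)))
    stop("cohort table must contain: ", paste(need, collapse = ", "))
  per <- unique(table[, need])
  if (anyDuplicated(per$animal_id))
    stop("inconsistent event records per animal")
  surv <- survival::Surv(per$event_time, per$event_flag)
  fit <- survival::survfit(surv ~ group, data = per)
  unstable <- any(tapply(per$event_flag, per$group, sum) == 0)
  lr <- tryCatch(survival::survdiff(surv ~ group, data = per),
                 error = function(e) NULL)
  p <- if (is.null(lr)) NA_real_ else
    stats::pchisq(lr$chisq, length(lr$n) - 1, lower.tail = FALSE)
  list(fit = fit, logrank_p = p,
       chisq = if (is.null(lr)) NA_real_ else lr$chisq,
       unstable = unstable)
}

#' Cohort statistics report
#'
#' Per-day group summaries (mean +- SD) of tumor volume with the selected
#' longitudinal test, body-weight summaries, and the survival comparison;
#' written as a TSV plus a human-readable text report.
#'
#' @param table Cohort `data.frame` as produced by [generate_cohort()].
#' @param out_prefix Path prefix; writes `<prefix>_volume.tsv` and
#'   `<prefix>_report.txt`. `NULL` skips writing.
#' @param longitudinal `"two_way_anova"` (group x day) or `"per_day_t"`.
#' @return List with `volume` (per-day summaries and p-values),
#'   `survival`, and `method` labels, invisibly written to files.
#' @export
cohort_report <- function(table, out_prefix = NULL,
                          longitudinal = c("two_way_anova", "per_day_t")) {
  longitudinal <- match.arg(longitudinal)
  groups <- unique(table$group)
  if (min(table(unique(table[, c("animal_id", "group")])$group)) < 2)
    stop("statistics refused: every group needs at least 2 animals")
  table$volume <- tumor_volume(table$diameter_A, table$diameter_B)
  agg <- do.call(rbind, lapply(split(table, table[, c("day", "group")]),
    function(d) data.frame(day = d$day[1], group = d$group[1],
                           mean = mean(d$volume), sd = stats::sd(d$volume),
                           n = nrow(d))))
  agg <- agg[order(agg$day, agg$group), ]
  if (longitudinal == "two_way_anova") {
    aw <- anova_two_way(table$volume, table$group, table$day)
    pday <- aw$within_time
    names(pday)[names(pday) == "time"] <- "day"
  } else {
    days <- sort(unique(table$day))
    pday <- do.call(rbind, lapply(days, function(d) {
      sub <- table[table$day == d, ]
      gs <- split(sub$volume, sub$group)
      cp <- utils::combn(names(gs), 2, simplify = FALSE)
      do.call(rbind, lapply(cp, function(p2) {
        tt <- t_test_from_summary(
          summary_stat(p2[1], mean(gs[[p2[1]]]), stats::sd(gs[[p2[1]]]), length(gs[[p2[1]]])),
          summary_stat(p2[2], mean(gs[[p2[2]]]), stats::sd(gs[[p2[2]]]), length(gs[[p2[2]]])))
        data.frame(day = d, group1 = p2[1], group2 = p2[2],
                   p_raw = tt$p, p_adj = min(1, length(cp) * length(days) * tt$p))
      }))
    }))
  }
  km <- km_survival(table)
  res <- list(volume = list(summaries = agg, pairwise = pday),
              survival = list(logrank_p = km$logrank_p,
                              unstable = km$unstable),
              method = c(longitudinal = longitudinal,
                         survival = "Kaplan-Meier + log-rank"))
  if (!is.null(out_prefix)) {
    utils::write.table(merge(agg, pday, by = "day", all = TRUE),
                       paste0(out_prefix, "_volume.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    txt <- c("Cohort statistics report",
             sprintf("Longitudinal test: %s", longitudinal),
             "", "Tumor volume (mm^3), mean +- SD per day and group:",
             sprintf("  day %2g  %-10s %8.1f +- %7.1f (n=%d)",
                     agg$day, agg$group, agg$mean, agg$sd, agg$n),
             "", "Pairwise comparisons (Bonferroni-adjusted):",
             sprintf("  day %2s  %s vs %s: p_raw=%.3g p_adj=%.3g",
                     pday$day, pday$group1, pday$group2, pday$p_raw,
                     pday$p_adj),
             "", sprintf("Survival: log-rank p = %.4g%s", km$logrank_p,
                         if (km$unstable) " (unstable: all-censored group)" else ""))
    writeLines(txt, paste0(out_prefix, "_report.txt"))
  }
  res
}

#' Read / write a cohort table as TSV
#'
#' @param table Cohort `data.frame`.
#' @param path File path.
#' @return `path` (write); the `data.frame` (read). Malformed rows raise a
#'   line-numbered error.
#' @export
write_cohort_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  nfield <- lengths(strsplit(lines, "\t"))
  bad <- which(nfield != length(header))
  if (length(bad))
    stop("malformed cohort TSV at line ", bad[1], ": expected ",
         length(header), " fields, found ", nfield[bad[1]])
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  num <- intersect(c("day", "diameter_A", "diameter_B", "body_weight",
                     "event_time", "event_flag"), names(d))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    if (anyNA(v) && !anyNA(d[[cn]]))
      stop("malformed cohort TSV: non-numeric '", cn, "' at line ",
           which(is.na(v))[1] + 1)
    d[[cn]] <- v
  }
  d
}
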