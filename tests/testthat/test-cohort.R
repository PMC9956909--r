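test_that("zero-SD groups reproduce their means exactly and seeds are reproducible", {
  g <- tibble::tibble(group = c("wt", "ko"), parameter = "trt",
                      mean = c(250, 125), sd = 0, n = 6)
  tab <- simulate_cohort(cohort_spec(g, seed = 61))
  expect_equal(tab$value[tab$group == "wt"], rep(250, 6))
  expect_equal(tab$value[tab$group == "ko"], rep(125, 6))
  expect_identical(tab, simulate_cohort(cohort_spec(g, seed = 61)))
  # both eyes per animal, no averaging
  expect_equal(sort(unique(tab$eye)), c("left", "right"))
  expect_equal(max(table(tab$animal_id[tab$group == "wt"])), 2L)
})

test_that("simulated group means recover the preset within sampling error", {
  preset <- xrcc5_summary() |>
    dplyr::filter(parameter == "trt_auto")
  reps <- 20
  means <- sapply(seq_len(reps), function(r) {
    tab <- simulate_cohort(cohort_spec(preset, seed = 100 + r))
    c(wt = mean(tab$value[tab$group == "wt"]),
      ko = mean(tab$value[tab$group == "ko"]))
  })
  # replicate-averaged sample means: tolerance 3 * SD / sqrt(n * reps)
  expect_lt(abs(mean(means["wt", ]) - 254.9), 3 * 3.1 / sqrt(10 * reps))
  expect_lt(abs(mean(means["ko", ]) - 225.6), 3 * 4.2 / sqrt(10 * reps))
})

test_that("amplitude truncation never produces negative values", {
  g <- tibble::tibble(group = "old", parameter = "photopic_a_amplitude",
                      mean = 8.8, sd = 3.9, n = 200)
  tab <- simulate_cohort(cohort_spec(g, seed = 62))
  expect_true(all(tab$value >= 0))
})

test_that("summarize_cohort matches a brute-force loop", {
  set.seed(63)
  tab <- tibble::tibble(group = rep(c("a", "b"), each = 25),
                        value = rnorm(50, 100, 12))
  got <- summarize_cohort(tab, group)
  for (g in c("a", "b")) {
    v <- tab$value[tab$group == g]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(got$mean[got$group == g], m)
    expect_equal(got$sd[got$group == g], s)
    expect_equal(got$n[got$group == g], 25L)
  }
})

test_that("welch_from_summary matches the closed form and t.test on raw data", {
  same <- welch_from_summary(10, 2, 8, 10, 2, 8)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # arithmetic oracle for the knockout thickness comparison:
  # diff 29.3, SE = sqrt(3.1^2/10 + 4.2^2/10) = 1.6508
  w <- welch_from_summary(254.9, 3.1, 10, 225.6, 4.2, 10)
  se <- sqrt(3.1^2 / 10 + 4.2^2 / 10)
  expect_equal(w$statistic, 29.3 / se)
  expect_equal(w$statistic, 17.75, tolerance = 0.001)
  expect_lt(w$p_value, 1e-4)

  set.seed(64)
  x <- rnorm(12, 5, 2); y <- rnorm(17, 6, 3)
  ours <- welch_from_summary(mean(x), sd(x), 12, mean(y), sd(y), 17)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p_value, ref$p.value)

  expect_error(welch_from_summary(1, 0, 5, 2, 0, 5), "degenerate")
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("welch p agrees with a permutation test on simulated raw data", {
  scenarios <- list(c(d = 0.0), c(d = 0.7), c(d = 1.2))
  for (k in seq_along(scenarios)) {
    set.seed(70 + k)
    x <- rnorm(15, 0, 1); y <- rnorm(15, scenarios[[k]]["d"], 1.3)
    w <- welch_from_summary(mean(x), sd(x), 15, mean(y), sd(y), 15)
    obs <- abs(mean(x) - mean(y))
    pooled <- c(x, y)
    perm <- replicate(4000, {
      idx <- sample(30, 15)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    p_perm <- (sum(perm >= obs) + 1) / 4001
    expect_lt(abs(w$p_value - p_perm), 0.05)
  }
})

test_that("two-way ANOVA matches a hand-computed balanced-design oracle", {
  set.seed(65)
  d <- tidyr::expand_grid(geno = c("wt", "ko"),
                          quadrant = c("sup", "inf", "nas", "tem"),
                          rep = 1:6) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 230, 8) +
                    ifelse(geno == "ko", -20, 0))
  fit <- two_way_anova(d, "geno", "quadrant")
  tab <- tidy(fit)

  # balanced design: Type II equals the classical sequential decomposition
  grand <- mean(d$value)
  ss_a <- sum(tapply(d$value, d$geno, function(v) length(v) * (mean(v) - grand)^2))
  ss_b <- sum(tapply(d$value, d$quadrant, function(v) length(v) * (mean(v) - grand)^2))
  cell_means <- tapply(d$value, list(d$geno, d$quadrant), mean)
  a_means <- tapply(d$value, d$geno, mean)
  b_means <- tapply(d$value, d$quadrant, mean)
  ss_ab <- 6 * sum((sweep(sweep(cell_means, 1, a_means), 2, b_means) + grand)^2)
  ss_e <- sum((d$value - cell_means[cbind(d$geno, d$quadrant)])^2)
  expect_equal(tab$sumsq[tab$term == "geno"], ss_a)
  expect_equal(tab$sumsq[tab$term == "quadrant"], ss_b)
  expect_equal(tab$sumsq[tab$term == "geno:quadrant"], ss_ab)
  expect_equal(tab$sumsq[tab$term == "Residuals"], ss_e)
  f_a <- (ss_a / 1) / (ss_e / 40)
  expect_equal(tab$statistic[tab$term == "geno"], f_a)
  expect_equal(tab$p_value[tab$term == "geno"], stats::pf(f_a, 1, 40, lower.tail = FALSE))
  expect_gt(nrow(glance(fit)), 0)
})

test_that("an additive group shift shows up as a main effect, not an interaction", {
  set.seed(66)
  d <- tidyr::expand_grid(group = c("wt", "ko"), lum = c("L1", "L2", "L3"),
                          rep = 1:30) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 0, 1) +
                    ifelse(group == "ko", 1.5, 0))
  tab <- tidy(two_way_anova(d, "group", "lum"))
  expect_lt(tab$p_value[tab$term == "group"], 1e-6)
  expect_gt(tab$p_value[tab$term == "group:lum"], 0.01)
})

test_that("null two-way ANOVA keeps its type-I error near the nominal level", {
  reps <- 300
  set.seed(67)
  hits <- 0
  for (r in seq_len(reps)) {
    d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5) |>
      dplyr::mutate(value = rnorm(dplyr::n()))
    tab <- tidy(two_way_anova(d, "a", "b"))
    hits <- hits + (tab$p_value[tab$term == "a"] < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.035)
})

test_that("singular and degenerate designs are rejected", {
  d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  expect_error(two_way_anova(dplyr::filter(d, !(a == "x" & b == "u")), "a", "b"),
               "Singular")
  expect_error(two_way_anova(dplyr::mutate(d, a = "x"), "a", "b"), "levels")
})

test_that("post-hoc adjustments follow their closed forms and never shrink p", {
  set.seed(68)
  d <- tidyr::expand_grid(age = c("w10", "w50", "w100"), q = c("q1", "q2"),
                          rep = 1:8) |>
    dplyr::mutate(value = rnorm(dplyr::n(), 100, 10) +
                    ifelse(age == "w100", -12, 0))
  fit <- two_way_anova(d, "age", "q")

  sid <- posthoc(fit, "sidak")
  expect_equal(sid$p_adjusted, pmin(1, 1 - (1 - sid$p_raw)^3))
  expect_true(all(sid$p_adjusted >= sid$p_raw))
  expect_true(all(sid$p_adjusted >= 0 & sid$p_adjusted <= 1))

  tuk <- posthoc(fit, "tukey")
  expect_true(all(tuk$p_adjusted >= tuk$p_raw - 1e-12))

  # with only two levels Tukey collapses to the unadjusted comparison
  d2 <- dplyr::filter(d, age != "w50")
  tuk2 <- posthoc(two_way_anova(d2, "age", "q"), "tukey")
  expect_equal(tuk2$p_adjusted, tuk2$p_raw, tolerance = 1e-8)

  expect_error(posthoc(fit, "bonferroni"))
})

test_that("family-wise error of Sidak-adjusted comparisons stays controlled under the null", {
  reps <- 250
  set.seed(69)
  fw <- 0
  for (r in seq_len(reps)) {
    d <- tidyr::expand_grid(a = c("x", "y", "z"), b = c("u", "v"), rep = 1:4) |>
      dplyr::mutate(value = rnorm(dplyr::n()))
    ph <- posthoc(two_way_anova(d, "a", "b"), "sidak")
    fw <- fw + any(ph$p_adjusted < 0.05)
  }
  expect_lt(fw / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("aging ratios reproduce the published retention percentages", {
  a <- aging_summary() |>
    dplyr::filter(parameter == "scotopic_a_amplitude") |>
    dplyr::rename(group = age_weeks)
  r <- aging_ratio(a, 10)
  expect_equal(r$percent_of_reference[r$group == 10], 100)
  expect_equal(r$percent_of_reference[r$group == 100], 100 * 45.1 / 176.3)
  expect_lt(r$percent_of_reference[r$group == 100], 30)

  b <- aging_summary() |>
    dplyr::filter(parameter == "scotopic_b_amplitude") |>
    dplyr::rename(group = age_weeks)
  rb <- aging_ratio(b, 10)
  expect_equal(rb$percent_of_reference[rb$group == 50], 100 * 236.9 / 389.0)
  expect_equal(rb$percent_of_reference[rb$group == 50], 60.9, tolerance = 0.001)

  expect_error(aging_ratio(a, 999), "not found")
  zero <- tibble::tibble(group = c("r", "s"), mean = c(0, 5))
  expect_error(aging_ratio(zero, "r"), "zero")
})

test_that("simulate then summarize recovers every preset cell", {
  preset <- aging_summary() |>
    dplyr::filter(parameter %in% c("trt_auto", "scotopic_b_amplitude")) |>
    dplyr::rename(group = age_weeks) |>
    dplyr::mutate(group = as.character(group))
  tab <- simulate_cohort(cohort_spec(preset, seed = 71))
  got <- summarize_cohort(tab, group, parameter)
  joined <- dplyr::inner_join(got, preset, by = c("group", "parameter"),
                              suffix = c("_sim", "_true"))
  expect_equal(nrow(joined), nrow(preset))
  expect_identical(joined$n_sim, as.integer(joined$n_true))
  expect_true(all(abs(joined$mean_sim - joined$mean_true) <
                    3 * joined$sd_true / sqrt(joined$n_true) + 1e-9))
})
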