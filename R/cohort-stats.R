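#' Group summary statistics
#'
#' Collapses a long-format cohort table to (mean, SD, n) per cell, the
#' form in which cohort results are reported: sample mean, sample SD
#' (n - 1 denominator) and the number of observations (eyes).
#'
#' @param table A data frame with a `value` column.
#' @param ... Grouping columns (tidy-select), e.g. `group, parameter`.
#' @param value Name of the value column.
#' @return A tibble with the grouping columns plus `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(table, ..., value = "value") {
  stopifnot(is.data.frame(table), value %in% names(table))
  table |>
    group_by(...) |>
    summarise(mean = mean(.data[[value]]),
              sd = sd(.data[[value]]),
              n = dplyr::n(), .groups = "drop")
}

#' Welch two-sample test from summary statistics
#'
#' Computes the unequal-variance two-sample t statistic directly from
#' (mean, SD, n) pairs:
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' This is the closed-form check used to verify published group
#' differences when only summary triples are printed.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param comparison Label carried into the result.
#' @return A one-row tibble: `comparison`, `estimate` (mean1 - mean2),
#'   `statistic`, `df`, `p_value`.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               comparison = "group1 - group2") {
  if (n1 < 2 || n2 < 2) abort("Welch test needs n >= 2 in both groups.")
  if (sd1 < 0 || sd2 < 0) abort("SDs must be >= 0.")
  if (sd1 == 0 && sd2 == 0)
    abort("Welch test is degenerate when both SDs are zero.")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(comparison = comparison, estimate = mean1 - mean2,
         statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Welch tests for every parameter of a two-group summary table
#'
#' Convenience wrapper over [welch_from_summary()] for tables shaped like
#' [xrcc5_summary()]: one Welch test per parameter comparing the two
#' levels of `group`.
#'
#' @param summary_tbl Tibble with `parameter`, `group`, `mean`, `sd`, `n`.
#' @param group1,group2 The two group labels to compare.
#' @return A tibble with one row per parameter.
#' @export
welch_test_table <- function(summary_tbl, group1, group2) {
  pars <- unique(summary_tbl$parameter)
  purrr::map(pars, function(p) {
    g1 <- summary_tbl[summary_tbl$parameter == p & summary_tbl$group == group1, ]
    g2 <- summary_tbl[summary_tbl$parameter == p & summary_tbl$group == group2, ]
    if (nrow(g1) != 1L || nrow(g2) != 1L)
      abort(paste0("Parameter '", p, "' does not have exactly one row per group."))
    welch_from_summary(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n,
                       comparison = paste0(p, ": ", group1, " - ", group2)) |>
      mutate(parameter = p, .before = 1)
  }) |> bind_rows()
}

#' Two-way factorial ANOVA
#'
#' Fits `value ~ factor_a * factor_b` and computes Type II sums of squares
#' (the standard choice for unbalanced factorials such as 96 control
#' versus 10 mutant eyes), F statistics and p-values for both main
#' effects and the interaction. Observations are eyes; both eyes of an
#' animal enter without averaging unless `average_eyes = TRUE`, which
#' collapses to one value per animal and cell first (eye pseudo-replication
#' caveat).
#'
#' @param table Long-format data frame.
#' @param factor_a,factor_b Factor column names (strings).
#' @param response Response column name.
#' @param average_eyes Average the two eyes of each animal first
#'   (requires an `animal_id` column).
#' @return An object of class `screen_anova` with the fitted `lm` and the
#'   Type II table; see [tidy()] and [glance()].
#' @export
two_way_anova <- function(table, factor_a, factor_b, response = "value",
                          average_eyes = FALSE) {
  stopifnot(is.data.frame(table),
            all(c(factor_a, factor_b, response) %in% names(table)))
  df <- as.data.frame(table)
  if (average_eyes) {
    if (!"animal_id" %in% names(df))
      abort("`average_eyes = TRUE` needs an `animal_id` column.")
    df <- df |>
      group_by(.data$animal_id, .data[[factor_a]], .data[[factor_b]]) |>
      summarise(.resp = mean(.data[[response]]), .groups = "drop") |>
      as.data.frame()
    names(df)[names(df) == ".resp"] <- response
  }
  df[[factor_a]] <- factor(df[[factor_a]])
  df[[factor_b]] <- factor(df[[factor_b]])
  if (nlevels(df[[factor_a]]) < 2 || nlevels(df[[factor_b]]) < 2)
    abort("Both factors need at least 2 levels.")
  form <- stats::as.formula(
    paste(response, "~", factor_a, "*", factor_b))
  fit <- lm(form, data = df)
  if (any(is.na(stats::coef(fit))))
    abort("Singular design: some factor-level combinations are empty.")
  aov_tab <- car::Anova(fit, type = 2)
  tab <- tibble(
    term = rownames(aov_tab),
    sumsq = aov_tab$`Sum Sq`,
    df = aov_tab$Df,
    statistic = aov_tab$`F value`,
    p_value = aov_tab$`Pr(>F)`
  )
  structure(list(fit = fit, table = tab, factor_a = factor_a,
                 factor_b = factor_b, response = response, data = df),
            class = "screen_anova")
}

#' @export
print.screen_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type II):", x$response, "~",
      x$factor_a, "*", x$factor_b, "\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' @rdname two_way_anova
#' @param x A `screen_anova` object.
#' @method tidy screen_anova
#' @export
tidy.screen_anova <- function(x, ...) x$table

#' @rdname two_way_anova
#' @method glance screen_anova
#' @export
glance.screen_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, df.residual = x$fit$df.residual,
         nobs = length(stats::residuals(x$fit)))
}

#' Post-hoc multiple comparisons after a two-way ANOVA
#'
#' Pairwise comparisons of the levels of `factor_a`, either across the
#' whole design (`by = NULL`) or within each level of the second factor
#' (`by = factor_b`, the per-luminance family layout used for ERG
#' intensity series). `"tukey"` uses the studentized-range distribution;
#' `"sidak"` applies the closed-form adjustment
#' `p_adj = 1 - (1 - p)^m` over each family of `m` comparisons.
#'
#' @param anova_fit A [two_way_anova()] result.
#' @param method `"tukey"` or `"sidak"`.
#' @param by Optional conditioning factor name (commonly the second
#'   factor); `NULL` compares marginal means.
#' @return A tibble: `contrast`, optional `by` column, `estimate`,
#'   `statistic`, `df`, `p_raw`, `p_adjusted`, `method`.
#' @export
posthoc <- function(anova_fit, method = c("tukey", "sidak"), by = NULL) {
  stopifnot(inherits(anova_fit, "screen_anova"))
  method <- match.arg(method)
  emm <- emmeans::emmeans(anova_fit$fit, specs = anova_fit$factor_a, by = by,
                          data = anova_fit$data)
  adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = method))
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  out <- as_tibble(adj[setdiff(names(adj), c("p.value", "SE"))])
  names(out)[names(out) == "t.ratio"] <- "statistic"
  out$p_raw <- raw$p.value
  out$p_adjusted <- pmin(pmax(adj$p.value, raw$p.value), 1)
  out$method <- method
  out
}

#' Amplitude retention relative to a reference group
#'
#' Expresses each group's mean as a percentage of a reference group's
#' mean (e.g., ERG amplitudes at each age relative to the youngest age),
#' the quantity behind statements like "responses dropped below 30% at
#' 100 weeks".
#'
#' @param summary_tbl Tibble with a group column and a `mean` column, one
#'   row per group (e.g., one parameter's rows of [aging_summary()]).
#' @param reference Reference group label.
#' @param group_col Name of the group column.
#' @return The input with a `percent_of_reference` column added.
#' @export
aging_ratio <- function(summary_tbl, reference, group_col = "group") {
  stopifnot(is.data.frame(summary_tbl),
            all(c(group_col, "mean") %in% names(summary_tbl)))
  ref_rows <- summary_tbl[[group_col]] == reference
  if (!any(ref_rows)) abort(paste0("Reference group '", reference, "' not found."))
  ref_mean <- mean(summary_tbl$mean[ref_rows])
  if (ref_mean == 0) abort("Reference group mean is zero.")
  summary_tbl |>
    mutate(percent_of_reference = 100 * .data$mean / ref_mean)
}
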