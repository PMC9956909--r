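#' Cohort simulation specification
#'
#' Describes a simulated cohort as a set of groups, each with per-parameter
#' normal (mean, SD) and a number of observations (eyes). Values are drawn
#' per eye; each animal contributes both eyes without averaging. Amplitude
#' and thickness parameters are truncated at zero (a negative amplitude or
#' thickness is not physical), implemented by rejection sampling.
#'
#' @param groups A tibble with columns `group`, `parameter`, `mean`, `sd`,
#'   `n` (eyes) and optionally `unit`. [xrcc5_summary()] and
#'   [aging_summary()] (with `age_weeks` renamed to `group`) are
#'   ready-made presets.
#' @param eyes_per_animal Eyes contributed per animal (default 2).
#' @param truncate_at_zero Redraw negative values (default `TRUE`).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, eyes_per_animal = 2, truncate_at_zero = TRUE,
                        seed = NULL) {
  required <- c("group", "parameter", "mean", "sd", "n")
  missing <- setdiff(required, names(groups))
  if (length(missing))
    abort(paste0("`groups` is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  if (any(groups$sd < 0)) abort("Group SDs must be >= 0.")
  if (any(groups$n < 1)) abort("Each cell needs n >= 1 eyes.")
  structure(list(groups = as_tibble(groups),
                 eyes_per_animal = as.integer(eyes_per_animal),
                 truncate_at_zero = isTRUE(truncate_at_zero),
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort table from group summary statistics
#'
#' Draws one value per eye and parameter from the group's normal
#' distribution, assigning consecutive eyes to animals (left then right).
#' With `sd = 0` every value equals the group mean exactly; an identical
#' spec and seed reproduce the identical table.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `cohort_table`, long format: `animal_id`,
#'   `eye`, `group`, `parameter`, `unit`, `value`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  if (!"unit" %in% names(g)) g$unit <- NA_character_
  local_seed_eval(spec$seed, {
    rows <- purrr::pmap(
      list(g$group, g$parameter, g$unit, g$mean, g$sd, g$n),
      function(group, parameter, unit, mean, sd, n) {
        vals <- rnorm(n, mean, sd)
        if (spec$truncate_at_zero && sd > 0) {
          for (tries in 1:100) {
            neg <- vals < 0
            if (!any(neg)) break
            vals[neg] <- rnorm(sum(neg), mean, sd)
          }
          vals <- pmax(vals, 0)
        }
        eye_idx <- seq_len(n)
        animal <- (eye_idx - 1L) %/% spec$eyes_per_animal + 1L
        side <- c("left", "right")[(eye_idx - 1L) %% spec$eyes_per_animal + 1L]
        tibble(animal_id = sprintf("%s-%03d", group, animal),
               eye = side, group = as.character(group),
               parameter = parameter, unit = unit, value = vals)
      })
    out <- bind_rows(rows)
    class(out) <- c("cohort_table", class(out))
    out
  })
}
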