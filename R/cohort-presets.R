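#' Published summary presets for the knockout comparison
#'
#' Summary statistics (mean, SD, number of eyes) for the Xrcc5 knockout
#' versus wild-type comparison at 15 weeks: total retinal thickness under
#' the three measurement modes (automatic segmentation, automatic with
#' manual correction, fully manual) and the flash-ERG amplitudes and
#' implicit times at the reference luminances (scotopic 10 cd.s/m2,
#' photopic 100 cd.s/m2). Observations are eyes; both eyes of each animal
#' enter without averaging.
#'
#' @return A tibble: `parameter`, `unit`, `group` (`"wt"`/`"ko"`), `mean`,
#'   `sd`, `n`.
#' @export
xrcc5_summary <- function() {
  p <- c("trt_auto", "trt_auto_corrected", "trt_manual",
         "scotopic_a_amplitude", "scotopic_b_amplitude",
         "photopic_a_amplitude", "photopic_b_amplitude",
         "scotopic_a_implicit", "scotopic_b_implicit",
         "photopic_a_implicit", "photopic_b_implicit")
  u <- c(rep("um", 3), rep("uV", 4), rep("ms", 4))
  wt <- list(mean = c(254.9, 249.3, 224.1, 126.0, 314.9, 15.7, 134.1,
                      15.1, 35.1, 13.0, 40.6),
             sd = c(3.1, 3.0, 1.3, 37.1, 115.5, 4.4, 46.7,
                    1.5, 2.8, 1.7, 4.7),
             n = c(10, 10, 10, 96, 96, 96, 96, 96, 96, 96, 96))
  ko <- list(mean = c(225.6, 222.2, 199.6, 87.7, 181.9, 15.2, 103.8,
                      16.4, 44.8, 17.2, 47.1),
             sd = c(4.2, 3.7, 2.5, 18.7, 40.5, 4.5, 27.7,
                    1.5, 3.6, 3.2, 2.4),
             n = c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10))
  bind_rows(
    tibble(parameter = p, unit = u, group = "wt",
           mean = wt$mean, sd = wt$sd, n = wt$n),
    tibble(parameter = p, unit = u, group = "ko",
           mean = ko$mean, sd = ko$sd, n = ko$n)
  )
}

#' Published normal-range summary across six ages
#'
#' Wild-type C57Bl/6N retinal thickness (automatic segmentation) and
#' flash-ERG parameters at the ages of 10, 15, 30, 50, 70 and 100 weeks,
#' as (mean, SD, number of eyes) per age group. ERG rows refer to the
#' scotopic 10 cd.s/m2 and photopic 100 cd.s/m2 stimuli.
#'
#' @return A tibble: `parameter`, `unit`, `age_weeks`, `mean`, `sd`, `n`.
#' @export
aging_summary <- function() {
  ages <- c(10, 15, 30, 50, 70, 100)
  row <- function(parameter, unit, mean, sd, n)
    tibble(parameter = parameter, unit = unit, age_weeks = ages,
           mean = mean, sd = sd, n = n)
  bind_rows(
    row("trt_auto", "um",
        c(244.9, 246.7, 246.4, 246.2, 249.0, 194.4),
        c(9.1, 10.3, 10.2, 16.5, 7.0, 30.0),
        c(74, 66, 81, 22, 36, 18)),
    row("scotopic_a_amplitude", "uV",
        c(176.3, 135.7, 114.9, 91.0, 88.6, 45.1),
        c(62.3, 49.2, 42.1, 35.3, 30.9, 24.2),
        c(143, 403, 153, 50, 78, 31)),
    row("scotopic_b_amplitude", "uV",
        c(389.0, 321.0, 292.2, 236.9, 231.6, 130.3),
        c(127.2, 115.3, 99.4, 86.5, 89.0, 62.5),
        c(143, 403, 153, 50, 78, 31)),
    row("photopic_a_amplitude", "uV",
        c(20.8, 16.3, 14.6, 12.4, 11.0, 8.8),
        c(7.3, 5.1, 4.6, 3.4, 3.5, 3.9),
        c(88, 358, 136, 46, 64, 20)),
    row("photopic_b_amplitude", "uV",
        c(164.2, 133.2, 123.0, 110.1, 98.3, 58.7),
        c(58.9, 45.2, 40.2, 39.8, 37.7, 33.7),
        c(88, 358, 136, 46, 64, 20)),
    row("scotopic_a_implicit", "ms",
        c(14.2, 14.8, 15.2, 15.3, 15.8, 18.4),
        c(1.7, 1.8, 1.9, 2.5, 2.7, 3.0),
        c(143, 403, 153, 50, 78, 31)),
    row("scotopic_b_implicit", "ms",
        c(37.3, 35.5, 34.7, 33.1, 33.5, 34.9),
        c(4.9, 4.5, 2.5, 2.8, 3.4, 3.0),
        c(143, 403, 153, 50, 78, 31)),
    row("photopic_a_implicit", "ms",
        c(14.6, 13.4, 13.4, 12.8, 12.4, 13.7),
        c(2.0, 2.2, 2.0, 3.3, 2.1, 5.3),
        c(88, 358, 136, 46, 64, 20)),
    row("photopic_b_implicit", "ms",
        c(45.2, 41.0, 40.6, 37.1, 38.3, 42.4),
        c(7.9, 4.4, 3.8, 3.2, 3.2, 7.8),
        c(88, 358, 136, 46, 64, 20))
  )
}
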