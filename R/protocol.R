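#' Single-flash stimulus protocols
#'
#' Builds the standard full-field ERG flash series. The dark-adapted
#' (scotopic) protocol delivers 9 flash strengths log-spaced between 0.001
#' and 10 cd.s/m2 on a dark background; the light-adapted (photopic)
#' protocol delivers 5 flash strengths between 1 and 100 cd.s/m2 on a
#' rod-suppressing 30 cd/m2 background. Each flash strength is repeated
#' `n_repeats` times and the sweeps averaged downstream.
#'
#' @param condition `"scotopic"` or `"photopic"`.
#' @param n_repeats Number of sweeps recorded per flash strength (>= 1).
#' @return A tibble of class `erg_protocol` with one row per flash strength:
#'   columns `condition`, `luminance` (cd.s/m2, strictly increasing),
#'   `background` (cd/m2) and `n_repeats`.
#' @examples
#' erg_protocol("scotopic")
#' erg_protocol("photopic", n_repeats = 10)
#' @export
erg_protocol <- function(condition = c("scotopic", "photopic"), n_repeats = 20) {
  condition <- match.arg(condition)
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L || n_repeats < 1)
    abort("`n_repeats` must be a single number >= 1.")
  n_repeats <- as.integer(n_repeats)
  lum <- switch(condition,
    scotopic = 10^seq(-3, 1, length.out = 9),
    photopic = 10^seq(0, 2, length.out = 5)
  )
  # make the printed endpoints exact despite floating-point log spacing
  lum[1] <- switch(condition, scotopic = 0.001, photopic = 1)
  lum[length(lum)] <- switch(condition, scotopic = 10, photopic = 100)
  bg <- if (condition == "scotopic") 0 else 30
  out <- tibble(
    condition = condition,
    luminance = lum,
    background = bg,
    n_repeats = n_repeats
  )
  class(out) <- c("erg_protocol", class(out))
  out
}

validate_protocol <- function(protocol) {
  if (!is.data.frame(protocol) || nrow(protocol) == 0L)
    abort("`protocol` must be a non-empty data frame of flash strengths.")
  required <- c("condition", "luminance", "n_repeats")
  missing <- setdiff(required, names(protocol))
  if (length(missing))
    abort(paste0("`protocol` is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  lum <- protocol$luminance
  if (any(!is.finite(lum)) || any(lum <= 0) || is.unsorted(lum, strictly = TRUE))
    abort("Protocol luminances must be positive, finite and strictly increasing.")
  if (any(protocol$n_repeats < 1))
    abort("Protocol `n_repeats` must be >= 1.")
  invisible(protocol)
}
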