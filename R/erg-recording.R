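#' ERG recording container
#'
#' Holds the per-eye flash-response sweep matrices for one recording
#' condition. Each element of `sweeps` is an `n_repeats x n_samples` matrix
#' in microvolts, one per flash strength; all matrices share the same sample
#' grid. `stimulus_onset` is the (1-based) sample index at which the flash
#' is delivered, so sample `stimulus_onset` has time 0.
#'
#' @param eye_id Identifier string for the eye.
#' @param laterality `"left"` or `"right"`.
#' @param condition `"scotopic"` or `"photopic"`.
#' @param sampling_rate Samples per second (the standard instrument rate is
#'   1024 samples/s).
#' @param stimulus_onset 1-based sample index of the flash.
#' @param luminances Flash strengths (cd.s/m2), one per sweep matrix.
#' @param sweeps List of `n_repeats x n_samples` numeric matrices (uV).
#' @return An object of class `erg_recording`.
#' @export
erg_recording <- function(eye_id, laterality = c("left", "right"),
                          condition = c("scotopic", "photopic"),
                          sampling_rate, stimulus_onset, luminances, sweeps) {
  laterality <- match.arg(laterality)
  condition <- match.arg(condition)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    abort("`sampling_rate` must be a positive number.")
  if (length(luminances) != length(sweeps))
    abort("`luminances` and `sweeps` must have the same length.")
  if (!length(sweeps)) abort("An ERG recording needs at least one sweep matrix.")
  if (!all(vapply(sweeps, is.matrix, logical(1))))
    abort("Every element of `sweeps` must be a numeric matrix.")
  ns <- unique(vapply(sweeps, ncol, integer(1)))
  if (length(ns) != 1L)
    abort("All sweep matrices must share the same number of samples.")
  if (stimulus_onset < 1 || stimulus_onset > ns)
    abort("`stimulus_onset` must lie within the sample range.")
  if (is.unsorted(luminances, strictly = TRUE))
    abort("`luminances` must be strictly increasing.")
  structure(
    list(
      eye_id = as.character(eye_id),
      laterality = laterality,
      condition = condition,
      sampling_rate = as.numeric(sampling_rate),
      stimulus_onset = as.integer(stimulus_onset),
      luminances = as.numeric(luminances),
      sweeps = sweeps
    ),
    class = "erg_recording"
  )
}

#' @export
print.erg_recording <- function(x, ...) {
  cat("<erg_recording> eye", x$eye_id, paste0("(", x$laterality, ", ", x$condition, ")\n"))
  cat("  ", length(x$luminances), "flash strengths:",
      paste(signif(x$luminances, 3), collapse = ", "), "cd.s/m2\n")
  cat("  ", nrow(x$sweeps[[1]]), "sweeps x", ncol(x$sweeps[[1]]),
      "samples at", x$sampling_rate, "samples/s; flash at sample",
      x$stimulus_onset, "\n")
  invisible(x)
}

# time axis in ms relative to flash onset
recording_time_ms <- function(recording) {
  n <- ncol(recording$sweeps[[1]])
  (seq_len(n) - recording$stimulus_onset) / recording$sampling_rate * 1000
}
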