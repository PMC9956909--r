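#' Generator parameters for synthetic ERG responses
#'
#' Parameterizes the synthetic flash response used to exercise the ERG
#' measurement stage. Component amplitudes follow a saturating
#' (Hill / Naka-Rushton) intensity-response function
#' \deqn{A(I) = A_{max} I^h / (I^h + k^h)}
#' with half-saturation luminance `semi_sat` (k) and exponent `hill` (h).
#' The a-wave is a negative Gaussian-shaped transient centred at `a_time`;
#' the b-wave is a positive gamma-like transient peaking at `b_time`,
#' delayed relative to the a-trough, so the standard measurement rules
#' (baseline-to-trough, then trough-to-peak) apply literally.
#'
#' @param a_max,b_max Saturating a-/b-wave component amplitudes (uV, >= 0).
#' @param semi_sat Half-saturation luminance (cd.s/m2, > 0).
#' @param hill Hill exponent (> 0).
#' @param a_time,b_time Component extremum times (ms after flash onset);
#'   `a_time` must precede `b_time`.
#' @param a_width,b_width Kinetic widths (ms, Gaussian-equivalent sigma).
#' @param noise_sd Additive i.i.d. Gaussian noise SD per sample (uV, >= 0).
#' @param mains_amplitude Amplitude of optional 50 Hz interference (uV);
#'   0 (off) by default.
#' @param seed RNG seed for the sweep noise; `NULL` uses the current stream.
#' @return A list of class `erg_model_params`.
#' @export
erg_model_params <- function(a_max = 150, b_max = 350, semi_sat = 0.05,
                             hill = 1, a_time = 15, b_time = 35,
                             a_width = 4, b_width = 12, noise_sd = 10,
                             mains_amplitude = 0, seed = NULL) {
  stopifnot(is.numeric(a_max), is.numeric(b_max))
  if (a_max < 0 || b_max < 0 || a_width < 0 || b_width < 0 || noise_sd < 0)
    abort("Amplitudes, widths and `noise_sd` must all be >= 0.")
  if (hill <= 0) abort("`hill` must be > 0.")
  if (semi_sat <= 0) abort("`semi_sat` must be > 0.")
  if (a_time >= b_time) abort("`a_time` must precede `b_time`.")
  structure(
    list(a_max = a_max, b_max = b_max, semi_sat = semi_sat, hill = hill,
         a_time = a_time, b_time = b_time, a_width = a_width,
         b_width = b_width, noise_sd = noise_sd,
         mains_amplitude = mains_amplitude, seed = seed),
    class = "erg_model_params"
  )
}

# Saturating intensity-response amplitude.
naka_rushton <- function(amax, I, k, h) amax * I^h / (I^h + k^h)

# Noise-free response waveform (uV) at times t_ms (relative to flash onset).
erg_waveform <- function(t_ms, a_amp, b_amp, params) {
  post <- t_ms > 0
  a <- -a_amp * exp(-0.5 * ((t_ms - params$a_time) / params$a_width)^2)
  shape <- (params$b_time / params$b_width)^2  # gamma shape from width
  tb <- pmax(t_ms, 0) / params$b_time
  b <- b_amp * tb^shape * exp(shape * (1 - tb))
  (a + b) * post
}

#' Simulate ERG flash-response sweep sets with known ground truth
#'
#' Generates, for each flash strength of a stimulus protocol, an
#' `n_repeats x n_samples` sweep matrix at 1024 samples/s (configurable)
#' with 100 ms of pre-stimulus and 300 ms of post-stimulus signal, plus
#' additive Gaussian noise. Component amplitudes follow the saturating
#' intensity-response form of [erg_model_params()]. The returned ground
#' truth records the trough/peak of the noise-free trace, measured by the
#' same baseline-to-trough / trough-to-peak rules the analysis stage uses,
#' so generator and analysis agree exactly when noise is zero.
#'
#' @param params An [erg_model_params()] object.
#' @param protocol An [erg_protocol()] tibble (non-empty).
#' @param eye_id,laterality Metadata for the recording.
#' @param sampling_rate Samples per second.
#' @param pre_ms,post_ms Pre-/post-stimulus epoch lengths (ms; minimum
#'   100 and 300).
#' @return A list with elements `recording` (an [erg_recording()]) and
#'   `truth`, a tibble with one row per flash strength: the noise-free
#'   `a_amplitude`, `b_amplitude` (uV), `a_implicit`, `b_implicit` (ms) and
#'   the asymptotic component amplitudes `a_component`, `b_component`.
#' @export
simulate_erg_sweeps <- function(params, protocol,
                                eye_id = "sim-eye", laterality = "left",
                                sampling_rate = 1024,
                                pre_ms = 100, post_ms = 300) {
  if (!inherits(params, "erg_model_params"))
    abort("`params` must be an `erg_model_params` object.")
  validate_protocol(protocol)
  if (pre_ms < 100 || post_ms < 300)
    abort("Epochs need >= 100 ms pre-stimulus and >= 300 ms post-stimulus.")
  n_pre <- floor(pre_ms / 1000 * sampling_rate)
  n_post <- floor(post_ms / 1000 * sampling_rate)
  onset <- n_pre + 1L
  n <- n_pre + n_post
  t_ms <- (seq_len(n) - onset) / sampling_rate * 1000
  n_rep <- protocol$n_repeats[1]

  local_seed_eval(params$seed, {
    sweeps <- vector("list", nrow(protocol))
    truth <- vector("list", nrow(protocol))
    for (i in seq_len(nrow(protocol))) {
      I <- protocol$luminance[i]
      a_amp <- naka_rushton(params$a_max, I, params$semi_sat, params$hill)
      b_amp <- naka_rushton(params$b_max, I, params$semi_sat, params$hill)
      clean <- erg_waveform(t_ms, a_amp, b_amp, params)
      noise <- matrix(rnorm(n_rep * n, sd = params$noise_sd), nrow = n_rep)
      if (params$mains_amplitude > 0) {
        phase <- runif(n_rep, 0, 2 * pi)
        mains <- params$mains_amplitude *
          sin(outer(phase, 2 * pi * 50 * t_ms / 1000, `+`))
        noise <- noise + mains
      }
      sweeps[[i]] <- sweep(noise, 2, clean, `+`)
      truth[[i]] <- measure_clean_trace(clean, t_ms, I, a_amp, b_amp)
    }
    recording <- erg_recording(
      eye_id = eye_id, laterality = laterality,
      condition = protocol$condition[1], sampling_rate = sampling_rate,
      stimulus_onset = onset, luminances = protocol$luminance,
      sweeps = sweeps
    )
    list(recording = recording, truth = bind_rows(truth))
  })
}

# Ground-truth measurement on the noise-free trace: trough in the a-window,
# then peak from the trough onward (the same rules measure_waves applies).
measure_clean_trace <- function(clean, t_ms, luminance, a_amp, b_amp,
                                a_window = c(3, 50), b_end = 150) {
  ia <- which(t_ms >= a_window[1] & t_ms <= a_window[2])
  trough_rel <- which.min(clean[ia])
  trough_idx <- ia[trough_rel]
  ib <- which(t_ms >= t_ms[trough_idx] & t_ms <= b_end)
  peak_idx <- ib[which.max(clean[ib])]
  tibble(
    luminance = luminance,
    a_amplitude = -clean[trough_idx],
    b_amplitude = clean[peak_idx] - clean[trough_idx],
    a_implicit = t_ms[trough_idx],
    b_implicit = t_ms[peak_idx],
    a_component = a_amp,
    b_component = b_amp
  )
}
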