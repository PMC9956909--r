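# Small phantoms keep the segmentation tests fast while preserving the
# full geometry (OD in the center, field wide enough for the 1.5 mm ring).
small_phantom <- function(preset = "wt", noise_sd = 0, seed = 1, ...) {
  args <- list(n_bscans = 15, n_ascans = 48,
               axial_px = 2, lateral_px = 150, bscan_spacing = 450,
               noise_sd = noise_sd, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_preset, c(list(preset = preset), args))
}

# Independent closed-form waveform oracle: evaluates the two-component
# response on a fine grid (0.01 ms) and reads off trough/peak directly.
oracle_wave_extrema <- function(a_amp, b_amp, a_time = 15, b_time = 35,
                                a_width = 4, b_width = 12) {
  t <- seq(0.01, 150, by = 0.01)
  shape <- (b_time / b_width)^2
  y <- -a_amp * exp(-0.5 * ((t - a_time) / a_width)^2) +
    b_amp * (t / b_time)^shape * exp(shape * (1 - t / b_time))
  win <- t >= 3 & t <= 50
  trough_i <- which(win)[which.min(y[win])]
  after <- t >= t[trough_i]
  peak_i <- which(after)[which.max(y[after])]
  list(a_amplitude = -y[trough_i], b_amplitude = y[peak_i] - y[trough_i],
       a_implicit = t[trough_i], b_implicit = t[peak_i])
}

# brute-force sector means: an explicit double loop, independent of the
# vectorized implementation
brute_force_sectors <- function(map, grid, laterality) {
  nb <- nrow(map$values); na <- ncol(map$values)
  x <- (seq_len(na) - (na + 1) / 2) * map$lateral_px / 1000
  y <- ((nb + 1) / 2 - seq_len(nb)) * map$bscan_spacing / 1000
  acc <- list()
  for (j in seq_len(nb)) for (i in seq_len(na)) {
    if (!map$valid[j, i]) next
    dx <- x[i] - grid$od_center[1]; dy <- y[j] - grid$od_center[2]
    r <- sqrt(dx^2 + dy^2)
    if (r <= grid$od_exclusion || r > grid$outer_ring_outer) next
    ring <- if (r <= grid$inner_ring_outer) "inner" else "outer"
    ang <- atan2(dy, dx) * 180 / pi
    quad <- if (ang > 45 && ang <= 135) "superior"
    else if (ang > -135 && ang <= -45) "inferior"
    else if (ang > -45 && ang <= 45) {
      if (laterality == "right") "temporal" else "nasal"
    } else {
      if (laterality == "right") "nasal" else "temporal"
    }
    key <- paste(quad, ring)
    acc[[key]] <- c(acc[[key]], map$values[j, i])
  }
  sapply(acc, mean)
}

expect_no_flags <- function(flags, group) {
  expect_false(any(flags$flagged[flags$group == group]))
}
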