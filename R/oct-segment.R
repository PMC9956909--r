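#' Retinal boundary set
#'
#' Per-A-scan depths of the four segmented boundaries: internal limiting
#' membrane (ILM), lower edge of the outer plexiform layer (OPL), external
#' limiting membrane (ELM) and Bruch's membrane (BM). Depths are stored in
#' pixels from the top of the B-scan (the depth is the number of image
#' rows above the boundary) and converted to um only at reporting time.
#' At every valid A-scan the ordering ILM <= OPL <= ELM <= BM must hold.
#'
#' @param ilm,opl,elm,bm Numeric `n_bscans x n_ascans` depth matrices (px).
#' @param valid Logical matrix: where the boundaries are defined.
#' @param mode One of `"auto"`, `"auto_corrected"`, `"manual"`,
#'   `"ground_truth"`.
#' @param volume The source [oct_volume()] (supplies the geometry).
#' @param check Validate the ordering invariant (default `TRUE`).
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(ilm, opl, elm, bm, valid, mode, volume, check = TRUE) {
  mode <- match.arg(mode, c("auto", "auto_corrected", "manual", "ground_truth"))
  dims <- dim(ilm)
  for (m in list(opl, elm, bm, valid))
    if (!identical(dim(m), dims))
      abort("All boundary matrices must share dimensions.")
  if (check) {
    bad <- valid & (is.na(ilm) | is.na(opl) | is.na(elm) | is.na(bm))
    if (any(bad)) abort("Valid A-scans must have all four depths defined.")
    viol <- valid & !(ilm <= opl & opl <= elm & elm <= bm)
    if (any(viol)) {
      idx <- which(viol, arr.ind = TRUE)
      show <- head(idx, 5L)
      abort(paste0(
        "Boundary ordering ILM <= OPL <= ELM <= BM violated at ",
        sum(viol), " A-scan(s), e.g. (bscan, ascan): ",
        paste(apply(show, 1L, function(r) paste0("(", r[1], ",", r[2], ")")),
              collapse = " "), "."))
    }
  }
  structure(
    list(ilm = ilm, opl = opl, elm = elm, bm = bm, valid = valid,
         mode = mode,
         axial_px = volume$axial_px, lateral_px = volume$lateral_px,
         bscan_spacing = volume$bscan_spacing, laterality = volume$laterality,
         od_center = volume$od_center, od_radius = volume$od_radius),
    class = "boundary_set"
  )
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("<boundary_set>", nrow(x$ilm), "B-scans x", ncol(x$ilm),
      "A-scans, mode:", x$mode, "\n")
  cat("  valid A-scans:", sum(x$valid), "/", length(x$valid), "\n")
  invisible(x)
}

#' Long-format view of a boundary set
#' @param x A [boundary_set()].
#' @param ... Unused.
#' @return A tibble with one row per A-scan, depths in um.
#' @method as_tibble boundary_set
#' @export
as_tibble.boundary_set <- function(x, ...) {
  dims <- dim(x$ilm)
  grid <- expand.grid(bscan = seq_len(dims[1]), ascan = seq_len(dims[2]))
  tibble(
    bscan = grid$bscan, ascan = grid$ascan,
    ilm_um = as.vector(x$ilm) * x$axial_px,
    opl_um = as.vector(x$opl) * x$axial_px,
    elm_um = as.vector(x$elm) * x$axial_px,
    bm_um = as.vector(x$bm) * x$axial_px,
    valid = as.vector(x$valid), mode = x$mode
  )
}

#' Segmentation configuration
#'
#' @param sigma_px Gaussian pre-smoothing SD (pixels) applied to the
#'   B-scan before gradient computation.
#' @param max_step Maximum axial step (px) between neighbouring A-scans of
#'   one boundary path (the smoothness constraint).
#' @param min_separation_px Minimum ILM-BM separation enforced during the
#'   BM search.
#' @return A list of class `oct_segment_config`.
#' @export
oct_segment_config <- function(sigma_px = 2, max_step = 2L,
                               min_separation_px = 5L) {
  structure(list(sigma_px = sigma_px, max_step = as.integer(max_step),
                 min_separation_px = as.integer(min_separation_px)),
            class = "oct_segment_config")
}

# Separable Gaussian blur with replicate padding.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur1 <- function(mm) {  # along rows (depth)
    padded <- rbind(mm[rep(1L, r), , drop = FALSE], mm,
                    mm[rep(nrow(mm), r), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(r + 1):(r + nrow(mm)), ], nrow(mm), ncol(mm))
  }
  t(blur1(t(blur1(m))))
}

# Dynamic-programming minimum-cost path across A-scans with |step| <= max_step.
# lower/upper are per-column row bounds (inclusive). Returns a row index per
# column.
dp_path <- function(cost, lower, upper, max_step = 2L) {
  nz <- nrow(cost); nw <- ncol(cost)
  big <- 1e15
  lower <- pmax(pmin(as.integer(lower), nz), 1L)
  upper <- pmax(pmin(as.integer(upper), nz), 1L)
  swap <- lower > upper
  if (any(swap)) { lo <- lower; lower[swap] <- upper[swap]; upper[swap] <- lo[swap] }
  rows <- seq_len(nz)
  for (i in seq_len(nw))
    cost[rows < lower[i] | rows > upper[i], i] <- big
  M <- matrix(big, nz, nw)
  P <- matrix(1L, nz, nw)
  M[, 1] <- cost[, 1]
  shifts <- seq(-max_step, max_step)
  for (i in 2:nw) {
    prev <- M[, i - 1]
    best <- rep(big, nz); arg <- rows
    for (s in shifts) {
      # candidate predecessor row d - s for each row d
      src <- rows - s
      ok <- src >= 1L & src <= nz
      cand <- rep(big, nz)
      cand[ok] <- prev[src[ok]]
      better <- cand < best
      best[better] <- cand[better]
      arg[better] <- src[better]
    }
    M[, i] <- cost[, i] + best
    P[, i] <- arg
  }
  path <- integer(nw)
  path[nw] <- which.min(M[, nw])
  if (nw > 1)
    for (i in nw:2) path[i - 1] <- P[path[i], i]
  path
}

#' Segment the retinal boundaries on one B-scan
#'
#' Graph-based boundary search: the B-scan is Gaussian-smoothed, a vertical
#' gradient image computed, and each boundary found as the minimum-cost
#' smooth path across A-scans (dynamic programming, axial step limited to
#' `max_step` px per A-scan) over a signed gradient cost. The boundaries
#' are found in order ILM (dark-to-bright, shallow-preferring) then BM
#' (bright-to-dark, deep-preferring, below the ILM) then the interior OPL
#' (bright-to-dark, between ILM and BM) and ELM (dark-to-bright, between
#' OPL and BM); each search is constrained by the previously found
#' boundaries and the ordering invariant is enforced on the result.
#'
#' @param bscan Numeric matrix (depth x width), gray levels.
#' @param config An [oct_segment_config()].
#' @return A list of per-A-scan depth vectors (`ilm`, `opl`, `elm`, `bm`),
#'   in pixels.
#' @export
segment_bscan <- function(bscan, config = oct_segment_config()) {
  if (!is.matrix(bscan) || nrow(bscan) < 4L)
    abort("`bscan` must be a matrix with at least 4 rows.")
  if (diff(range(bscan)) == 0)
    abort("No boundary detectable: the B-scan is constant.")
  sm <- gauss_blur(bscan, config$sigma_px)
  g <- rbind(0, diff(sm))  # g[d, ] = sm[d, ] - sm[d - 1, ]
  nz <- nrow(g); nw <- ncol(g)
  depth_frac <- matrix((seq_len(nz) - 1) / max(nz - 1, 1), nz, nw)
  tie <- 1e-6 * max(abs(g)) * depth_frac  # breaks exact ties only

  ilm_row <- dp_path(-g + tie, rep(2L, nw), rep(nz, nw), config$max_step)
  bm_row <- dp_path(g - tie, ilm_row + config$min_separation_px,
                    rep(nz, nw), config$max_step)
  opl_row <- dp_path(g + tie, ilm_row + 1L, bm_row - 1L, config$max_step)
  elm_row <- dp_path(-g + tie, opl_row, bm_row, config$max_step)

  # a row index marks the first pixel below the boundary; the depth is the
  # pixel count above it
  ilm <- ilm_row - 1L
  bm <- bm_row - 1L
  opl <- pmin(pmax(opl_row - 1L, ilm), bm)
  elm <- pmin(pmax(elm_row - 1L, opl), bm)
  list(ilm = ilm, opl = opl, elm = elm, bm = bm)
}

#' Automatic segmentation of a whole volume
#'
#' Runs [segment_bscan()] on every B-scan and assembles a
#' [boundary_set()] with `mode = "auto"`. A-scans inside the optic-disc
#' circle are marked invalid (boundaries are undefined over the nerve
#' head).
#'
#' @param volume An [oct_volume()].
#' @param config An [oct_segment_config()].
#' @return A [boundary_set()].
#' @export
segment_volume <- function(volume, config = oct_segment_config()) {
  stopifnot(inherits(volume, "oct_volume"))
  nb <- length(volume$bscans); na <- ncol(volume$bscans[[1]])
  res <- lapply(volume$bscans, segment_bscan, config = config)
  pull <- function(name) do.call(rbind, lapply(res, `[[`, name))
  x_mm <- enface_x_mm(na, volume$lateral_px)
  y_mm <- enface_y_mm(nb, volume$bscan_spacing)
  od <- outer(y_mm - volume$od_center[2], x_mm - volume$od_center[1],
              function(dy, dx) sqrt(dx^2 + dy^2)) < volume$od_radius
  boundary_set(ilm = pull("ilm"), opl = pull("opl"), elm = pull("elm"),
               bm = pull("bm"), valid = !od, mode = "auto", volume = volume,
               check = FALSE)
}

#' Correct obviously outlying boundary points
#'
#' Emulates the manual clean-up of gross auto-segmentation failures
#' (isolated boundary detections far away from the retina): per B-scan and
#' boundary, points deviating from a 31-A-scan running median by more than
#' 5x the local median absolute deviation (floored at 0.5 px so clean
#' integer-pixel boundaries are never touched), or violating the boundary
#' ordering, are replaced by linear interpolation from their neighbours.
#' All other points are left bit-identical. A B-scan row in which more
#' than half the points are outliers cannot be repaired and is flagged
#' invalid instead of being smoothed.
#'
#' @param bounds A [boundary_set()] with `mode = "auto"`.
#' @param window Running-median window (A-scans, odd).
#' @param k Outlier threshold in multiples of the local MAD.
#' @param mad_floor Lower bound on the MAD (px).
#' @return A [boundary_set()] with `mode = "auto_corrected"`.
#' @export
correct_boundaries <- function(bounds, window = 31L, k = 5, mad_floor = 0.5) {
  stopifnot(inherits(bounds, "boundary_set"))
  if (bounds$mode != "auto")
    abort("`correct_boundaries()` expects a boundary set with mode = \"auto\".")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  nb <- nrow(bounds$ilm); na <- ncol(bounds$ilm)
  layers <- c("ilm", "opl", "elm", "bm")
  out <- bounds[layers]
  valid <- bounds$valid

  for (j in seq_len(nb)) {
    row_out <- matrix(FALSE, length(layers), na,
                      dimnames = list(layers, NULL))
    for (l in layers) {
      x <- bounds[[l]][j, ]
      w <- min(window, if (na %% 2L == 1L) na else na - 1L)
      med <- if (na >= 3) stats::runmed(x, w, endrule = "median") else x
      resid <- x - med
      local_mad <- zoo::rollapply(abs(resid), width = min(window, na),
                                  FUN = median, fill = NA, partial = TRUE)
      row_out[l, ] <- abs(resid) > k * pmax(local_mad, mad_floor)
    }
    # an ordering violation cannot be attributed to one boundary; treat the
    # whole column as outlying so it is rebuilt from clean neighbours
    ord_bad <- !(bounds$ilm[j, ] <= bounds$opl[j, ] &
                   bounds$opl[j, ] <= bounds$elm[j, ] &
                   bounds$elm[j, ] <= bounds$bm[j, ])
    for (l in layers) row_out[l, ] <- row_out[l, ] | ord_bad
    for (l in layers) {
      bad <- row_out[l, ]
      if (!any(bad)) { out[[l]][j, ] <- bounds[[l]][j, ]; next }
      if (mean(bad) > 0.5) { valid[j, ] <- FALSE; next }
      x <- bounds[[l]][j, ]
      good <- which(!bad)
      x[bad] <- approx(good, x[good], xout = which(bad), rule = 2)$y
      out[[l]][j, ] <- x
    }
  }
  # restore ordering where interpolation crossed a neighbouring boundary
  opl <- pmin(pmax(out$opl, out$ilm), out$bm)
  elm <- pmin(pmax(out$elm, opl), out$bm)
  boundary_set(ilm = out$ilm, opl = opl, elm = elm, bm = pmax(out$bm, elm),
               valid = valid, mode = "auto_corrected",
               volume = bounds, check = FALSE)
}

#' Adopt fully manual boundary placements
#'
#' Takes operator-supplied depths verbatim after validating the boundary
#' ordering. A-scans without full coverage (any `NA` depth) are marked
#' invalid; ordering violations are rejected with the offending A-scan
#' coordinates.
#'
#' @param volume An [oct_volume()].
#' @param ilm,opl,elm,bm Depth matrices in pixels (`n_bscans x n_ascans`).
#' @return A [boundary_set()] with `mode = "manual"`.
#' @export
apply_manual_boundaries <- function(volume, ilm, opl, elm, bm) {
  stopifnot(inherits(volume, "oct_volume"))
  nb <- length(volume$bscans)
  na_ <- ncol(volume$bscans[[1]])
  for (m in list(ilm, opl, elm, bm))
    if (!identical(dim(m), c(nb, na_)))
      abort("Manual depth matrices must be n_bscans x n_ascans.")
  valid <- !(is.na(ilm) | is.na(opl) | is.na(elm) | is.na(bm))
  nz <- nrow(volume$bscans[[1]])
  rng_bad <- valid & (ilm < 0 | bm > nz)
  if (any(rng_bad)) abort("Manual depths must lie within the image extent.")
  boundary_set(ilm = ilm, opl = opl, elm = elm, bm = bm, valid = valid,
               mode = "manual", volume = volume, check = TRUE)
}
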