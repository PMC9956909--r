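#' En-face layer thickness map
#'
#' Builds the en-face (B-scan x A-scan) thickness grid of a named layer
#' pair from a boundary set: `TRT` (total retinal thickness, BM - ILM),
#' `IR` (inner retina, ELM - ILM), `OR` (outer retina, BM - ELM) or `ONL`
#' (outer nuclear layer, ELM - OPL). Values are in um
#' (`pixel difference x axial_px`); pixels are masked where the boundary
#' set is invalid or inside the optic-disc circle. By construction
#' TRT = IR + OR exactly wherever all three are valid.
#'
#' @param bounds A [boundary_set()].
#' @param layer One of `"TRT"`, `"IR"`, `"OR"`, `"ONL"`.
#' @return An object of class `thickness_map`: the `values` matrix (um),
#'   the validity mask and the en-face geometry.
#' @export
thickness_map <- function(bounds, layer = c("TRT", "IR", "OR", "ONL")) {
  stopifnot(inherits(bounds, "boundary_set"))
  if (length(layer) != 1L || !layer %in% c("TRT", "IR", "OR", "ONL"))
    abort("`layer` must be one of \"TRT\", \"IR\", \"OR\", \"ONL\".")
  px <- switch(layer,
    TRT = bounds$bm - bounds$ilm,
    IR = bounds$elm - bounds$ilm,
    OR = bounds$bm - bounds$elm,
    ONL = bounds$elm - bounds$opl
  )
  nb <- nrow(px); na <- ncol(px)
  x_mm <- enface_x_mm(na, bounds$lateral_px)
  y_mm <- enface_y_mm(nb, bounds$bscan_spacing)
  od <- outer(y_mm - bounds$od_center[2], x_mm - bounds$od_center[1],
              function(dy, dx) sqrt(dx^2 + dy^2)) < bounds$od_radius
  structure(
    list(values = px * bounds$axial_px,
         valid = bounds$valid & !od,
         layer = layer, mode = bounds$mode,
         lateral_px = bounds$lateral_px, bscan_spacing = bounds$bscan_spacing,
         laterality = bounds$laterality,
         od_center = bounds$od_center, od_radius = bounds$od_radius),
    class = "thickness_map"
  )
}

#' @export
print.thickness_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat("<thickness_map>", x$layer, "(", x$mode, "),",
      nrow(x$values), "x", ncol(x$values), "px,",
      sum(x$valid), "valid\n")
  if (length(v))
    cat("  mean", round(mean(v), 1), "um, range",
        round(min(v), 1), "-", round(max(v), 1), "um\n")
  invisible(x)
}

#' Long-format view of a thickness map
#' @param x A [thickness_map()].
#' @param ... Unused.
#' @return A tibble with en-face coordinates and thickness per pixel.
#' @method as_tibble thickness_map
#' @export
as_tibble.thickness_map <- function(x, ...) {
  nb <- nrow(x$values); na <- ncol(x$values)
  grid <- expand.grid(bscan = seq_len(nb), ascan = seq_len(na))
  tibble(bscan = grid$bscan, ascan = grid$ascan,
         x_mm = rep(enface_x_mm(na, x$lateral_px), each = nb),
         y_mm = rep(enface_y_mm(nb, x$bscan_spacing), times = na),
         thickness_um = as.vector(x$values),
         valid = as.vector(x$valid), layer = x$layer)
}

#' Optic-disc-centered quadrant and ring grid
#'
#' The scanned field around the optic disc (OD) is divided into four 90
#' degree quadrants centered on the vertical and horizontal axes
#' (superior, inferior, nasal, temporal; diagonal dividers) and into an
#' inner and an outer ring. The innermost circle (the OD itself) is
#' excluded from all quantification. Nasal/temporal orientation mirrors
#' between left and right eyes.
#'
#' @param od_exclusion Radius of the excluded OD circle (mm).
#' @param inner_ring_outer Outer radius of the inner ring (mm).
#' @param outer_ring_outer Outer radius of the outer ring (mm). The
#'   defaults match the 1 and 1.5 mm manual sampling eccentricities.
#' @param od_center Grid center in en-face mm.
#' @return A list of class `sector_grid`.
#' @export
sector_grid <- function(od_exclusion = 0.25, inner_ring_outer = 1.0,
                        outer_ring_outer = 1.5, od_center = c(0, 0)) {
  if (!(0 < od_exclusion && od_exclusion < inner_ring_outer &&
          inner_ring_outer < outer_ring_outer))
    abort("Need 0 < od_exclusion < inner_ring_outer < outer_ring_outer.")
  structure(list(od_exclusion = od_exclusion,
                 inner_ring_outer = inner_ring_outer,
                 outer_ring_outer = outer_ring_outer,
                 od_center = as.numeric(od_center)),
            class = "sector_grid")
}

# Quadrant of each en-face point. Superior is +y; for the right eye the
# nasal retina is on the -x side of the en-face image, mirrored for the
# left eye.
quadrant_of <- function(dx, dy, laterality) {
  ang <- atan2(dy, dx) * 180 / pi
  q <- ifelse(ang > 45 & ang <= 135, "superior",
        ifelse(ang > -135 & ang <= -45, "inferior",
          ifelse(ang > -45 & ang <= 45, "plus_x", "minus_x")))
  if (laterality == "right") {
    q[q == "minus_x"] <- "nasal"; q[q == "plus_x"] <- "temporal"
  } else {
    q[q == "minus_x"] <- "temporal"; q[q == "plus_x"] <- "nasal"
  }
  q
}

#' Quadrant / ring sector summary of a thickness map
#'
#' Averages map pixels per quadrant and ring: quadrant membership by polar
#' angle around the grid center, ring membership by radial distance
#' (`od_exclusion < r <= inner_ring_outer` inner,
#' `inner_ring_outer < r <= outer_ring_outer` outer). The combined
#' quadrant value is the unweighted mean of the inner- and outer-ring
#' means. An empty sector is reported as missing (`NA`), never as zero.
#'
#' @param map A [thickness_map()].
#' @param grid A [sector_grid()].
#' @param laterality Eye side; defaults to the map's.
#' @return A tibble of class `sector_summary`: one row per quadrant with
#'   `inner_mean`, `outer_mean`, `combined` (um) and pixel counts.
#' @export
sector_summary <- function(map, grid = sector_grid(),
                           laterality = map$laterality) {
  stopifnot(inherits(map, "thickness_map"), inherits(grid, "sector_grid"))
  nb <- nrow(map$values); na <- ncol(map$values)
  x <- enface_x_mm(na, map$lateral_px)
  y <- enface_y_mm(nb, map$bscan_spacing)
  dx <- matrix(rep(x - grid$od_center[1], each = nb), nb, na)
  dy <- matrix(rep(y - grid$od_center[2], times = na), nb, na)
  r <- sqrt(dx^2 + dy^2)
  quad <- quadrant_of(dx, dy, laterality)
  ring <- ifelse(r > grid$od_exclusion & r <= grid$inner_ring_outer, "inner",
           ifelse(r > grid$inner_ring_outer & r <= grid$outer_ring_outer,
                  "outer", NA))
  keep <- map$valid & !is.na(ring)
  df <- tibble(quadrant = quad[keep], ring = ring[keep],
               value = map$values[keep])
  cells <- df |>
    group_by(.data$quadrant, .data$ring) |>
    summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  quadrants <- c("superior", "inferior", "nasal", "temporal")
  get <- function(q, rg, what) {
    v <- cells[cells$quadrant == q & cells$ring == rg, ][[what]]
    if (length(v)) v else if (what == "n") 0L else NA_real_
  }
  out <- tibble(
    quadrant = quadrants,
    inner_mean = vapply(quadrants, get, numeric(1), rg = "inner",
                        what = "mean", USE.NAMES = FALSE),
    outer_mean = vapply(quadrants, get, numeric(1), rg = "outer",
                        what = "mean", USE.NAMES = FALSE),
    n_inner = vapply(quadrants, get, numeric(1), rg = "inner", what = "n",
                     USE.NAMES = FALSE),
    n_outer = vapply(quadrants, get, numeric(1), rg = "outer", what = "n",
                     USE.NAMES = FALSE)
  ) |>
    mutate(combined = (.data$inner_mean + .data$outer_mean) / 2,
           layer = map$layer, laterality = laterality)
  class(out) <- c("sector_summary", class(out))
  out
}

#' Manual thickness sampling on the quadrant axes
#'
#' Evaluates a thickness map at fixed eccentricities from the optic disc
#' along the four quadrant axes (superior, inferior, nasal, temporal),
#' the manual measurement scheme: 4 quadrants x the requested distances
#' (1 and 1.5 mm by default), nearest-A-scan lookup. Points outside the
#' scanned field or on invalid pixels are reported as missing.
#'
#' @param map A [thickness_map()].
#' @param grid A [sector_grid()] (supplies the center).
#' @param distances Eccentricities from the OD center (mm).
#' @param laterality Eye side; defaults to the map's.
#' @return A tibble: `quadrant`, `distance_mm`, `thickness_um`.
#' @export
manual_quadrant_sample <- function(map, grid = sector_grid(),
                                   distances = c(1.0, 1.5),
                                   laterality = map$laterality) {
  stopifnot(inherits(map, "thickness_map"))
  nb <- nrow(map$values); na <- ncol(map$values)
  x <- enface_x_mm(na, map$lateral_px)
  y <- enface_y_mm(nb, map$bscan_spacing)
  nasal_sign <- if (laterality == "right") -1 else 1
  dirs <- list(superior = c(0, 1), inferior = c(0, -1),
               nasal = c(nasal_sign, 0), temporal = c(-nasal_sign, 0))
  rows <- purrr::map(names(dirs), function(q) {
    purrr::map(distances, function(d) {
      px <- grid$od_center[1] + dirs[[q]][1] * d
      py <- grid$od_center[2] + dirs[[q]][2] * d
      i <- which.min(abs(x - px)); j <- which.min(abs(y - py))
      inside <- abs(x[i] - px) <= map$lateral_px / 1000 / 2 + 1e-9 &&
        abs(y[j] - py) <= map$bscan_spacing / 1000 / 2 + 1e-9
      val <- if (inside && map$valid[j, i]) map$values[j, i] else NA_real_
      tibble(quadrant = q, distance_mm = d, thickness_um = val)
    }) |> bind_rows()
  })
  bind_rows(rows)
}
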