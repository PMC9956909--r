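#' Layered retinal phantom specification
#'
#' Describes a synthetic OCT volume: a piecewise-constant axial reflectance
#' profile per A-scan with transitions exactly at the ground-truth ILM,
#' OPL, ELM and BM depths. Four layers span the retina: the inner retina
#' above the OPL (ILM to top of OPL), the OPL itself, the ONL (bottom of
#' OPL to ELM) and the outer retina from the ELM to Bruch's membrane.
#' Layer thicknesses may be scalars (um) or functions of en-face position
#' `(x_mm, y_mm)` for phantoms that vary across the fundus. The wild-type
#' preset totals ~230 um, the normal mouse total retinal thickness.
#'
#' @param layer_thickness Named list/vector with entries `inner`, `opl`,
#'   `onl`, `outer`: axial extents in um, each a scalar or a
#'   `function(x_mm, y_mm)`.
#' @param layer_reflectance Named numeric: mean gray level (0-255 scale)
#'   of `vitreous`, `inner`, `opl`, `onl`, `outer`, `choroid`.
#' @param od_center,od_radius Optic-disc position and radius (mm); within
#'   the disc, boundaries are undefined and flagged invalid.
#' @param axial_px,lateral_px Pixel pitches (um/pixel).
#' @param bscan_spacing Distance between B-scans (um, default 120).
#' @param n_bscans,n_ascans Stack size (defaults 55 B-scans, matching a
#'   volume scan that covers the posterior pole).
#' @param top_margin_um Vitreous depth above the ILM (um).
#' @param depth_px Axial image size; defaults to the retina plus margins.
#' @param noise_sd Additive Gaussian noise SD (gray levels).
#' @param laterality Eye side.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A list of class `retina_phantom_spec`.
#' @export
retina_phantom_spec <- function(
    layer_thickness = list(inner = 85, opl = 20, onl = 60, outer = 65),
    layer_reflectance = c(vitreous = 13, inner = 166, opl = 192,
                          onl = 38, outer = 179, choroid = 10),
    od_center = c(0, 0), od_radius = 0.15,
    axial_px = 2, lateral_px = 50, bscan_spacing = 120,
    n_bscans = 55, n_ascans = 64,
    top_margin_um = 60, depth_px = NULL,
    noise_sd = 5, laterality = c("left", "right"), seed = NULL) {
  laterality <- match.arg(laterality)
  need <- c("inner", "opl", "onl", "outer")
  if (!all(need %in% names(layer_thickness)))
    abort("`layer_thickness` needs entries inner, opl, onl, outer.")
  ref_need <- c("vitreous", "inner", "opl", "onl", "outer", "choroid")
  if (!all(ref_need %in% names(layer_reflectance)))
    abort("`layer_reflectance` needs entries vitreous, inner, opl, onl, outer, choroid.")
  if (n_bscans < 1 || n_ascans < 1) abort("Stack size must be >= 1.")
  if (axial_px <= 0 || lateral_px <= 0 || bscan_spacing <= 0)
    abort("All pixel pitches must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(layer_thickness = layer_thickness,
         layer_reflectance = layer_reflectance,
         od_center = as.numeric(od_center), od_radius = od_radius,
         axial_px = axial_px, lateral_px = lateral_px,
         bscan_spacing = bscan_spacing,
         n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
         top_margin_um = top_margin_um, depth_px = depth_px,
         noise_sd = noise_sd, laterality = laterality, seed = seed),
    class = "retina_phantom_spec"
  )
}

#' Phantom presets for the common study conditions
#'
#' `"wt"` is a normal adult retina (total retinal thickness 230 um);
#' `"crx"` mimics an extreme photoreceptor degeneration: ONL collapsed to
#' zero, outer segments missing, total thickness ~125 um; `"xrcc5"` a
#' milder thinning driven by the ONL (~57 -> ~50 um) and inner retina.
#'
#' @param preset One of `"wt"`, `"crx"`, `"xrcc5"`.
#' @param total_um Optional total retinal thickness (um); layer
#'   thicknesses are scaled proportionally to reach it, which is how the
#'   cohort simulator injects per-eye thickness variability.
#' @param ... Passed on to [retina_phantom_spec()].
#' @return A `retina_phantom_spec`.
#' @export
phantom_preset <- function(preset = c("wt", "crx", "xrcc5"), total_um = NULL, ...) {
  preset <- match.arg(preset)
  th <- switch(preset,
    wt = list(inner = 85, opl = 20, onl = 60, outer = 65),
    crx = list(inner = 78, opl = 12, onl = 0, outer = 35),
    xrcc5 = list(inner = 74, opl = 18, onl = 50, outer = 62)
  )
  if (!is.null(total_um)) {
    s <- total_um / sum(unlist(th))
    th <- lapply(th, function(x) x * s)
  }
  retina_phantom_spec(layer_thickness = th, ...)
}

#' Simulate an OCT volume with ground-truth boundaries
#'
#' Renders every A-scan as a piecewise-constant reflectance profile with
#' transitions exactly at the ground-truth boundary depths (integer
#' pixels), adds i.i.d. Gaussian noise, and rounds to 8-bit gray levels.
#' Columns inside the optic-disc circle are rendered without layering and
#' flagged invalid in the ground truth, mirroring the excluded OD region
#' of the sector grid. The sum of the per-layer ground-truth thicknesses
#' equals the BM-ILM depth difference exactly at every A-scan.
#'
#' @param spec A [retina_phantom_spec()].
#' @return A list with `volume` (an [oct_volume()]) and `truth`
#'   (a [boundary_set()] with `mode = "ground_truth"`).
#' @export
simulate_oct_volume <- function(spec) {
  stopifnot(inherits(spec, "retina_phantom_spec"))
  nb <- spec$n_bscans; na <- spec$n_ascans
  x_mm <- enface_x_mm(na, spec$lateral_px)
  y_mm <- enface_y_mm(nb, spec$bscan_spacing)

  # per-layer thickness in integer pixels, en-face (nb x na)
  th_px <- lapply(spec$layer_thickness, function(th) {
    um <- if (is.function(th)) outer(y_mm, x_mm, function(y, x) th(x, y))
          else matrix(th, nb, na)
    if (any(um < 0)) abort("Layer thicknesses must be >= 0 everywhere.")
    round(um / spec$axial_px)
  })
  ilm <- matrix(round(spec$top_margin_um / spec$axial_px), nb, na)
  opl <- ilm + th_px$inner + th_px$opl   # lower edge of the OPL (top of ONL)
  elm <- opl + th_px$onl
  bm <- elm + th_px$outer
  opl_top <- ilm + th_px$inner

  depth <- spec$depth_px %||% (max(bm) + max(20, round(80 / spec$axial_px)))
  if (max(bm) >= depth)
    abort("Layer thicknesses exceed the axial image depth.")

  r <- spec$layer_reflectance
  od <- outer(y_mm - spec$od_center[2], x_mm - spec$od_center[1],
              function(dy, dx) sqrt(dx^2 + dy^2)) < spec$od_radius

  local_seed_eval(spec$seed, {
    bscans <- vector("list", nb)
    for (j in seq_len(nb)) {
      img <- matrix(0, depth, na)
      for (i in seq_len(na)) {
        if (od[j, i]) {
          # optic nerve head: no layered retina, a uniform moderately
          # reflective column below the ILM level
          prof <- c(rep(r[["vitreous"]], ilm[j, i]),
                    rep(r[["inner"]], depth - ilm[j, i]))
        } else {
          prof <- c(rep(r[["vitreous"]], ilm[j, i]),
                    rep(r[["inner"]], opl_top[j, i] - ilm[j, i]),
                    rep(r[["opl"]], opl[j, i] - opl_top[j, i]),
                    rep(r[["onl"]], elm[j, i] - opl[j, i]),
                    rep(r[["outer"]], bm[j, i] - elm[j, i]),
                    rep(r[["choroid"]], depth - bm[j, i]))
        }
        img[, i] <- prof
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(rnorm(depth * na, sd = spec$noise_sd), depth, na)
      bscans[[j]] <- pmin(pmax(round(img), 0), 255)
    }
    volume <- oct_volume(bscans, axial_px = spec$axial_px,
                         lateral_px = spec$lateral_px,
                         bscan_spacing = spec$bscan_spacing,
                         laterality = spec$laterality,
                         od_center = spec$od_center, od_radius = spec$od_radius)
    truth <- boundary_set(ilm = ilm, opl = opl, elm = elm, bm = bm,
                          valid = !od, mode = "ground_truth", volume = volume)
    list(volume = volume, truth = truth)
  })
}
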