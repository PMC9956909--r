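#' OCT volume container
#'
#' A stack of grayscale B-scans (cross-sections) with acquisition geometry.
#' Pixel values are gray levels on a 0-255 scale. The en-face coordinate
#' system has its origin at the center of the scanned field, x running
#' along each B-scan (lateral) and y across B-scans, with y positive
#' toward the superior retina (B-scan 1 is the most superior section).
#'
#' @param bscans List of numeric matrices (depth x width), all the same size.
#' @param axial_px Axial pixel pitch (um/pixel).
#' @param lateral_px Lateral pixel pitch within a B-scan (um/pixel).
#' @param bscan_spacing Distance between consecutive B-scans (um).
#' @param laterality `"left"` or `"right"` eye.
#' @param od_center Optic-disc center in en-face mm, `c(x, y)`.
#' @param od_radius Optic-disc radius (mm).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, axial_px, lateral_px, bscan_spacing,
                       laterality = c("left", "right"),
                       od_center = c(0, 0), od_radius = 0.15) {
  laterality <- match.arg(laterality)
  if (!length(bscans) || !all(vapply(bscans, is.matrix, logical(1))))
    abort("`bscans` must be a non-empty list of matrices.")
  dims <- vapply(bscans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("All B-scans must share the same dimensions.")
  if (axial_px <= 0 || lateral_px <= 0 || bscan_spacing <= 0)
    abort("Pixel pitches and B-scan spacing must be > 0.")
  structure(
    list(bscans = bscans, axial_px = axial_px, lateral_px = lateral_px,
         bscan_spacing = bscan_spacing, laterality = laterality,
         od_center = as.numeric(od_center), od_radius = od_radius),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1]])
  cat("<oct_volume>", length(x$bscans), "B-scans of", d[1], "x", d[2],
      "px,", x$laterality, "eye\n")
  cat("  axial", x$axial_px, "um/px, lateral", x$lateral_px,
      "um/px, B-scan spacing", x$bscan_spacing, "um\n")
  cat("  OD at (", x$od_center[1], ",", x$od_center[2], ") mm, radius",
      x$od_radius, "mm\n")
  invisible(x)
}

# En-face coordinates (mm) of A-scan columns / B-scan rows.
enface_x_mm <- function(n_ascans, lateral_px)
  (seq_len(n_ascans) - (n_ascans + 1) / 2) * lateral_px / 1000
enface_y_mm <- function(n_bscans, bscan_spacing)
  ((n_bscans + 1) / 2 - seq_len(n_bscans)) * bscan_spacing / 1000

#' Write / read an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' The B-scan stack is stored as an 8-bit multi-page grayscale TIFF
#' (gray levels 0-255, lossless for integer-valued volumes) and the
#' acquisition geometry in a JSON sidecar with keys `axial_px_um`,
#' `lateral_px_um`, `bscan_spacing_um`, `laterality`, `od_center_mm`,
#' `od_radius_mm`.
#'
#' @param volume An [oct_volume()].
#' @param path TIFF file path.
#' @param sidecar JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return `write_oct_volume()` returns `path` invisibly;
#'   `read_oct_volume()` returns an [oct_volume()].
#' @export
write_oct_volume <- function(volume, path,
                             sidecar = paste0(tools::file_path_sans_ext(path), ".json")) {
  stopifnot(inherits(volume, "oct_volume"))
  pages <- lapply(volume$bscans, function(m) pmin(pmax(m, 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(
    axial_px_um = volume$axial_px,
    lateral_px_um = volume$lateral_px,
    bscan_spacing_um = volume$bscan_spacing,
    laterality = volume$laterality,
    od_center_mm = volume$od_center,
    od_radius_mm = volume$od_radius
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(path,
                            sidecar = paste0(tools::file_path_sans_ext(path), ".json")) {
  if (!file.exists(path)) abort(paste0("No such TIFF: ", path))
  if (!file.exists(sidecar)) abort(paste0("Missing JSON sidecar: ", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("axial_px_um", "lateral_px_um", "bscan_spacing_um",
                "laterality", "od_center_mm", "od_radius_mm")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    abort(paste0("Sidecar is missing key(s): ",
                 paste(missing, collapse = ", "), "."))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("TIFF pages are ragged: all B-scans must share dimensions.")
  bscans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate gray stored with channels
    round(p * 255)
  })
  oct_volume(bscans,
             axial_px = meta$axial_px_um, lateral_px = meta$lateral_px_um,
             bscan_spacing = meta$bscan_spacing_um,
             laterality = meta$laterality,
             od_center = as.numeric(meta$od_center_mm),
             od_radius = meta$od_radius_mm)
}
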