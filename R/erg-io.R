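#' Read and write ERG recordings as CSV
#'
#' The on-disk dialect is plain UTF-8 comma-separated text, one file per
#' eye and recording condition. Each flash-strength block starts with
#' `#`-prefixed `key=value` metadata lines (`eye_id`, `laterality`,
#' `condition`, `sampling_rate`, `stimulus_onset`, `luminance`), followed
#' by a header row `time_ms,sweep_1,...,sweep_k` and one row per sample.
#' Values are written with 17 significant digits so a write-then-read
#' round-trip reproduces the recording exactly. The writer emits LF line
#' endings; the reader also accepts CRLF.
#'
#' @param recording An [erg_recording()].
#' @param path File path.
#' @return `write_erg_csv()` returns `path` invisibly; `read_erg_csv()`
#'   returns an [erg_recording()].
#' @export
write_erg_csv <- function(recording, path) {
  stopifnot(inherits(recording, "erg_recording"))
  t_ms <- recording_time_ms(recording)
  con <- file(path, open = "wb")  # binary: guarantee LF endings
  on.exit(close(con))
  for (i in seq_along(recording$luminances)) {
    m <- recording$sweeps[[i]]
    meta <- c(
      paste0("# eye_id=", recording$eye_id),
      paste0("# laterality=", recording$laterality),
      paste0("# condition=", recording$condition),
      paste0("# sampling_rate=", fmt_num(recording$sampling_rate)),
      paste0("# stimulus_onset=", recording$stimulus_onset),
      paste0("# luminance=", fmt_num(recording$luminances[i]))
    )
    header <- paste(c("time_ms", paste0("sweep_", seq_len(nrow(m)))),
                    collapse = ",")
    body <- apply(cbind(t_ms, t(m)), 1L,
                  function(r) paste(fmt_num(r), collapse = ","))
    writeLines(c(meta, header, body), con, sep = "\n")
  }
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' @rdname write_erg_csv
#' @export
read_erg_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)  # tolerate CRLF
  starts <- grep("^# eye_id=", lines)
  if (!length(starts))
    abort("Not an ERG CSV: no '# eye_id=' metadata header found.")
  ends <- c(starts[-1] - 1L, length(lines))

  meta0 <- NULL
  luminances <- numeric(0)
  sweeps <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    meta_lines <- grep("^#", block, value = TRUE)
    kv <- strsplit(sub("^#\\s*", "", meta_lines), "=", fixed = TRUE)
    meta <- setNames(vapply(kv, function(p) trimws(p[2]), character(1)),
                     vapply(kv, function(p) trimws(p[1]), character(1)))
    required <- c("eye_id", "laterality", "condition", "sampling_rate",
                  "stimulus_onset", "luminance")
    missing <- setdiff(required, names(meta))
    if (length(missing))
      abort(sprintf("Block %d metadata header is missing key(s): %s.",
                    b, paste(missing, collapse = ", ")))
    if (is.null(meta0)) meta0 <- meta

    data_lines <- block[!grepl("^#", block)]
    if (length(data_lines) < 2L)
      abort(sprintf("Block %d has no sample rows.", b))
    header <- strsplit(data_lines[1], ",", fixed = TRUE)[[1]]
    ncols <- length(header)
    cells <- strsplit(data_lines[-1], ",", fixed = TRUE)
    lens <- lengths(cells)
    if (any(lens != ncols)) {
      bad <- which(lens != ncols)[1]
      abort(sprintf(
        "Block %d (luminance %s): row %d has %d fields, expected %d (sweeps %s).",
        b, meta[["luminance"]], bad, lens[bad], ncols,
        paste(header[-1], collapse = ", ")))
    }
    vals <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
    if (anyNA(vals)) {
      flat_idx <- which(is.na(vals))[1]
      abort(sprintf("Block %d: non-numeric sample value in row %d, column '%s'.",
                    b, (flat_idx - 1L) %/% ncols + 1L,
                    header[(flat_idx - 1L) %% ncols + 1L]))
    }
    m <- matrix(vals, ncol = ncols, byrow = TRUE)
    luminances <- c(luminances, as.numeric(meta[["luminance"]]))
    sweeps[[b]] <- t(m[, -1, drop = FALSE])  # n_repeats x n_samples
  }
  ord <- order(luminances)
  erg_recording(
    eye_id = meta0[["eye_id"]],
    laterality = meta0[["laterality"]],
    condition = meta0[["condition"]],
    sampling_rate = as.numeric(meta0[["sampling_rate"]]),
    stimulus_onset = as.integer(meta0[["stimulus_onset"]]),
    luminances = luminances[ord],
    sweeps = sweeps[ord]
  )
}
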