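#' Construct a wavelength grid
#'
#' A wavelength grid is the axis a spectrometer samples on: a strictly
#' increasing vector of wavelengths in nanometres.
#'
#' @param values numeric vector of wavelengths (nm), strictly increasing,
#'   length at least 2, all finite.
#' @return A numeric vector of class `"wavelength_grid"`.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop_nirshift("a wavelength grid needs at least 2 channels", "nirshift_format_error")
  }
  if (any(!is.finite(values))) {
    stop_nirshift("wavelengths must all be finite", "nirshift_format_error")
  }
  if (any(diff(values) <= 0)) {
    stop_nirshift("wavelengths must be strictly increasing", "nirshift_format_error")
  }
  structure(values, class = "wavelength_grid")
}

#' Construct a spectra set
#'
#' The universal container used throughout the package: an absorbance matrix
#' (samples in rows, channels in columns) on a wavelength grid, with optional
#' per-sample scalar labels (here, tensile strength on an MPa-like scale) and
#' an instrument tag.
#'
#' @param grid a [wavelength_grid()] (or numeric vector coerced to one).
#' @param absorbance numeric matrix, `n_samples x n_channels`; column count
#'   must equal the grid length.
#' @param labels optional numeric vector of length `n_samples`, all finite.
#' @param instrument_id character tag naming the instrument.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(grid, absorbance, labels = NULL, instrument_id = "unknown") {
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(grid)) {
    stop_nirshift(
      sprintf("absorbance has %d columns but the grid has %d channels",
              ncol(absorbance), length(grid)),
      "nirshift_format_error"
    )
  }
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    if (length(labels) != nrow(absorbance)) {
      stop_nirshift("labels length must equal the number of samples", "nirshift_format_error")
    }
    if (any(!is.finite(labels))) {
      stop_nirshift("labels must be finite", "nirshift_format_error")
    }
  }
  structure(
    list(grid = grid, absorbance = absorbance, labels = labels,
         instrument_id = as.character(instrument_id)),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d samples x %d channels [%.1f-%.1f nm], instrument '%s', labels: %s\n",
    nrow(x$absorbance), length(x$grid), min(x$grid), max(x$grid),
    x$instrument_id, if (is.null(x$labels)) "absent" else "present"
  ))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# Row-subset a spectra set, keeping grid and instrument tag.
subset_spectra <- function(set, idx) {
  spectra_set(set$grid, set$absorbance[idx, , drop = FALSE],
              labels = if (is.null(set$labels)) NULL else set$labels[idx],
              instrument_id = set$instrument_id)
}

#' Read spectra from CSV
#'
#' The CSV dialect is comma-separated with a `.` decimal mark; the header row
#' holds the wavelengths in nm, optionally followed by a final `label` column.
#'
#' @param path file path.
#' @param has_labels if `NA` (default), a trailing `label` header is detected
#'   automatically; otherwise forces presence/absence.
#' @param instrument_id tag stored on the returned set.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path, has_labels = NA, instrument_id = "unknown") {
  if (!file.exists(path)) {
    stop_nirshift(sprintf("file not found: %s", path), "nirshift_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  labelled <- identical(tolower(header[length(header)]), "label")
  if (!is.na(has_labels) && has_labels != labelled) {
    stop_nirshift(
      sprintf("has_labels=%s but file %s a trailing 'label' column",
              has_labels, if (labelled) "has" else "lacks"),
      "nirshift_format_error"
    )
  }
  wl_cols <- if (labelled) seq_len(length(header) - 1L) else seq_along(header)
  wl <- suppressWarnings(as.numeric(header[wl_cols]))
  if (any(is.na(wl))) {
    stop_nirshift("non-numeric wavelength in header row", "nirshift_parse_error")
  }
  body <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  mat <- matrix(0, nrow(body), length(wl_cols))
  for (j in wl_cols) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & nzchar(body[[j]]))
    if (length(bad) > 0L || anyNA(v)) {
      row <- if (length(bad) > 0L) bad[1] else which(is.na(v))[1]
      stop_nirshift(sprintf("non-numeric cell at data row %d, column %d", row, j),
                    "nirshift_parse_error")
    }
    mat[, j] <- v
  }
  labels <- NULL
  if (labelled) {
    labels <- suppressWarnings(as.numeric(body[[length(header)]]))
    if (anyNA(labels) && nrow(body) > 0L) {
      stop_nirshift(sprintf("non-numeric label at data row %d", which(is.na(labels))[1]),
                    "nirshift_parse_error")
    }
    if (nrow(body) == 0L) labels <- numeric(0)
  }
  spectra_set(wavelength_grid(wl), mat, labels = labels, instrument_id = instrument_id)
}

#' Write spectra to CSV
#'
#' Writes the container with 15 significant digits so a write/read round trip
#' is lossless at working precision.
#'
#' @param set a [spectra_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  header <- format(as.numeric(set$grid), digits = 15, trim = TRUE, scientific = FALSE)
  if (!is.null(set$labels)) header <- c(header, "label")
  ok <- tryCatch({
    con <- file(path, "w")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_nirshift(sprintf("cannot write to %s", path), "nirshift_io_error")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  n <- nrow(set$absorbance)
  if (n > 0L) {
    body <- format(set$absorbance, digits = 15, trim = TRUE, scientific = TRUE)
    rows <- apply(body, 1L, paste, collapse = ",")
    if (!is.null(set$labels)) {
      rows <- paste(rows, format(set$labels, digits = 15, trim = TRUE, scientific = TRUE),
                    sep = ",")
    }
    writeLines(rows, con)
  }
  invisible(path)
}

#' Randomly split a spectra set into train and test
#'
#' The split is a seeded permutation: `floor(ratio * n)` samples to the
#' training set, the remainder to the test set. Reproducible for a fixed seed.
#'
#' @param set a [spectra_set()] with at least 2 samples.
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return A list of class `"split_result"` with elements `train`, `test`
#'   (both spectra sets), `train_idx`, `test_idx`, `ratio`, `seed`.
#' @export
random_split <- function(set, ratio, seed) {
  stopifnot(inherits(set, "spectra_set"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio >= 1) {
    stop_nirshift("ratio must lie strictly inside (0, 1)", "nirshift_argument_error")
  }
  n <- nrow(set$absorbance)
  if (n < 2L) stop_nirshift("need at least 2 samples to split", "nirshift_argument_error")
  n_train <- floor(ratio * n)
  n_train <- max(1L, min(n - 1L, n_train))
  set.seed(as.integer(seed %% 2147483647))
  perm <- sample.int(n)
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1L):n])
  structure(
    list(train = subset_spectra(set, train_idx),
         test = subset_spectra(set, test_idx),
         train_idx = train_idx, test_idx = test_idx,
         ratio = ratio, seed = as.integer(seed)),
    class = "split_result"
  )
}

#' Resample spectra onto a new wavelength grid
#'
#' Per-sample linear interpolation onto a target grid. The target must lie
#' within the source span; no extrapolation is performed. Linear interpolation
#' is exact on affine functions of wavelength and monotone near sharp peaks.
#'
#' @param set a [spectra_set()].
#' @param target a [wavelength_grid()] within the source span.
#' @return A [spectra_set()] on `target`; labels carried unchanged.
#' @export
resample_to_grid <- function(set, target) {
  stopifnot(inherits(set, "spectra_set"))
  if (!inherits(target, "wavelength_grid")) target <- wavelength_grid(target)
  src <- as.numeric(set$grid)
  tgt <- as.numeric(target)
  if (min(tgt) < min(src) || max(tgt) > max(src)) {
    stop_nirshift("target grid extends beyond the source span (no extrapolation)",
                  "nirshift_range_error")
  }
  n <- nrow(set$absorbance)
  out <- matrix(0, n, length(tgt))
  for (i in seq_len(n)) {
    out[i, ] <- stats::approx(src, set$absorbance[i, ], xout = tgt, method = "linear")$y
  }
  spectra_set(target, out, labels = set$labels, instrument_id = set$instrument_id)
}
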