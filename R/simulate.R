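#' Default component library for wood-like NIR spectra
#'
#' Three absorbing components standing in for cellulose, lignin and
#' hemicellulose, each a mixture of Gaussian absorption bands in the
#' 950-1650 nm overtone region. The peak table is synthetic: band positions
#' are loosely placed near known C-H / O-H overtone regions, but no attempt is
#' made to reproduce calibrated wood optical constants. Label coefficients are
#' scaled so that with concentrations uniform on [0.1, 1] the labels (nominal
#' tensile strength) span roughly 30-120.
#'
#' @param label_noise_sd standard deviation of additive Gaussian label noise.
#' @param center_jitter_sd per-sample band-position jitter in nm: each
#'   physical sample shifts all its absorption bands by one common draw,
#'   emulating the hydrogen-bonding and temperature effects that move NIR
#'   overtone bands between specimens. This is what gives real spectra an
#'   intrinsic dimensionality well above the component count and makes
#'   transfer maps genuinely data-hungry; 0 disables it.
#' @param width_jitter_sd per-sample relative band-width jitter (same
#'   mechanism, applied multiplicatively to the Gaussian sigmas).
#' @return A list of class `"component_library"` with per-component peak
#'   `centers` (nm), `sigmas` (nm), `amps` (absorbance), plus
#'   `label_coefficients`, `label_noise_sd` and the jitter settings.
#' @export
component_library <- function(label_noise_sd = 4, center_jitter_sd = 1.5,
                              width_jitter_sd = 0.03) {
  comps <- list(
    cellulose_like = list(
      centers = c(1200, 1490, 1580), sigmas = c(28, 22, 30), amps = c(0.55, 0.80, 0.45)),
    lignin_like = list(
      centers = c(1140, 1420), sigmas = c(25, 35), amps = c(0.65, 0.60)),
    hemicellulose_like = list(
      centers = c(1000, 1330, 1640), sigmas = c(20, 30, 24), amps = c(0.40, 0.50, 0.35))
  )
  structure(
    list(components = comps,
         label_coefficients = c(70, 35, -20),
         label_noise_sd = label_noise_sd,
         center_jitter_sd = center_jitter_sd,
         width_jitter_sd = width_jitter_sd),
    class = "component_library"
  )
}

validate_component_library <- function(library, span = c(880, 1720)) {
  stopifnot(inherits(library, "component_library"))
  if (length(library$components) < 1L) {
    stop_nirshift("component library needs at least one component", "nirshift_argument_error")
  }
  if (length(library$label_coefficients) != length(library$components)) {
    stop_nirshift("label_coefficients length must equal the number of components",
                  "nirshift_argument_error")
  }
  for (cp in library$components) {
    if (any(cp$sigmas <= 0)) {
      stop_nirshift("peak widths must be positive", "nirshift_argument_error")
    }
    if (any(cp$centers < span[1] | cp$centers > span[2])) {
      stop_nirshift("peak centers must lie within the instrument span", "nirshift_argument_error")
    }
  }
  invisible(library)
}

#' Describe a simulated spectrometer
#'
#' Captures the instrument response used by [apply_instrument()]: a Gaussian
#' convolution of given FWHM (spectral resolution), a wavelength shift, an
#' affine gain/offset distortion with a linear baseline, uniform sampling onto
#' `n_channels`, and i.i.d. Gaussian noise.
#'
#' @param n_channels number of channels (>= 2).
#' @param span numeric length-2, wavelength span in nm.
#' @param resolution_fwhm Gaussian instrument-response FWHM in nm (0 = ideal).
#' @param gain multiplicative distortion.
#' @param offset additive distortion (absorbance units).
#' @param baseline_slope additive slope per nm, anchored at the span minimum.
#' @param wavelength_shift shift in nm applied to the instrument axis.
#' @param noise_sd i.i.d. Gaussian noise sd in absorbance units.
#' @param gain_jitter_sd,offset_jitter_sd,slope_jitter_sd per-measurement
#'   variability of the gain (relative), offset (absorbance units) and
#'   baseline slope (per nm): every scan draws its own small deviations
#'   around the systematic distortion, emulating sample repositioning and
#'   instrument drift between measurements. Zero (the default) gives a
#'   perfectly repeatable instrument.
#' @return A list of class `"instrument_profile"`.
#' @export
instrument_profile <- function(n_channels, span = c(900, 1700), resolution_fwhm = 0,
                               gain = 1, offset = 0, baseline_slope = 0,
                               wavelength_shift = 0, noise_sd = 0,
                               gain_jitter_sd = 0, offset_jitter_sd = 0,
                               slope_jitter_sd = 0) {
  if (!.is_count(n_channels) || n_channels < 2) {
    stop_nirshift("n_channels must be an integer >= 2", "nirshift_argument_error")
  }
  if (resolution_fwhm < 0 || noise_sd < 0) {
    stop_nirshift("resolution_fwhm and noise_sd must be non-negative", "nirshift_argument_error")
  }
  if (gain_jitter_sd < 0 || offset_jitter_sd < 0 || slope_jitter_sd < 0) {
    stop_nirshift("jitter standard deviations must be non-negative", "nirshift_argument_error")
  }
  structure(
    list(n_channels = as.integer(n_channels), span = as.numeric(span),
         resolution_fwhm = resolution_fwhm, gain = gain, offset = offset,
         baseline_slope = baseline_slope, wavelength_shift = wavelength_shift,
         noise_sd = noise_sd, gain_jitter_sd = gain_jitter_sd,
         offset_jitter_sd = offset_jitter_sd, slope_jitter_sd = slope_jitter_sd),
    class = "instrument_profile"
  )
}

#' The two default instruments
#'
#' `master_profile()` mirrors a 512-channel, 1.56 nm-resolution spectrometer;
#' `slave_profile()` a 118-channel, 6.83 nm-resolution OEM unit on the same
#' 900-1700 nm range, with a mild gain/offset/baseline/shift distortion and
#' higher noise — the kind of response mismatch calibration transfer exists
#' to correct.
#'
#' @return An [instrument_profile()].
#' @export
master_profile <- function() {
  instrument_profile(512L, span = c(900, 1700), resolution_fwhm = 1.56,
                     gain = 1, offset = 0, baseline_slope = 0,
                     wavelength_shift = 0, noise_sd = 0.01,
                     gain_jitter_sd = 0.01, offset_jitter_sd = 0.005,
                     slope_jitter_sd = 1e-5)
}

#' @rdname master_profile
#' @export
slave_profile <- function() {
  instrument_profile(118L, span = c(900, 1700), resolution_fwhm = 6.83,
                     gain = 1.25, offset = 0.04, baseline_slope = 2e-5,
                     wavelength_shift = 2, noise_sd = 0.015,
                     gain_jitter_sd = 0.02, offset_jitter_sd = 0.01,
                     slope_jitter_sd = 2e-5)
}

# Dense reference grid the generator simulates on before instrument sampling:
# 2048 points over 880-1720 nm (covers span plus shift margin).
reference_grid <- function() wavelength_grid(seq(880, 1720, length.out = 2048))

#' Simulate a pure mixture spectrum
#'
#' Beer-Lambert-style additive mixture: absorbance is the concentration-
#' weighted sum of each component's Gaussian bands, hence exactly linear in
#' the concentrations.
#'
#' @param concentrations non-negative vector, one entry per component.
#' @param library a [component_library()].
#' @param grid a [wavelength_grid()] to evaluate on.
#' @param center_shift common band-position shift for this sample (nm).
#' @param width_scale common multiplicative band-width factor for this sample.
#' @return Numeric absorbance vector on `grid`.
#' @export
simulate_pure_spectrum <- function(concentrations, library = component_library(),
                                   grid = reference_grid(),
                                   center_shift = 0, width_scale = 1) {
  validate_component_library(library)
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (length(concentrations) != length(library$components)) {
    stop_nirshift("one concentration per component required", "nirshift_argument_error")
  }
  if (any(concentrations < 0)) {
    stop_nirshift("concentrations must be non-negative", "nirshift_argument_error")
  }
  wl <- as.numeric(grid)
  a <- numeric(length(wl))
  for (i in seq_along(library$components)) {
    cp <- library$components[[i]]
    for (p in seq_along(cp$centers)) {
      a <- a + concentrations[i] * cp$amps[p] *
        exp(-(wl - cp$centers[p] - center_shift)^2 /
              (2 * (cp$sigmas[p] * width_scale)^2))
    }
  }
  a
}

#' Pass a pure spectrum through an instrument model
#'
#' Convolves the dense-grid spectrum with a Gaussian response of the profile's
#' FWHM, shifts the wavelength axis, applies `gain * a + offset +
#' baseline_slope * (lambda - span_min)`, samples onto the instrument's
#' uniform grid by linear interpolation, and adds i.i.d. Gaussian noise.
#' Uses the current RNG state for the noise draw.
#'
#' @param pure absorbance vector on `ref_grid`.
#' @param profile an [instrument_profile()].
#' @param ref_grid the dense grid `pure` lives on.
#' @return Absorbance vector of length `profile$n_channels`.
#' @export
apply_instrument <- function(pure, profile, ref_grid = reference_grid()) {
  stopifnot(inherits(profile, "instrument_profile"))
  if (!inherits(ref_grid, "wavelength_grid")) ref_grid <- wavelength_grid(ref_grid)
  wl <- as.numeric(ref_grid)
  lo <- profile$span[1] + min(0, profile$wavelength_shift)
  hi <- profile$span[2] + max(0, profile$wavelength_shift)
  if (lo < min(wl) || hi > max(wl)) {
    stop_nirshift("reference grid does not cover the instrument span plus shift margin",
                  "nirshift_range_error")
  }
  smoothed <- pure
  if (profile$resolution_fwhm > 0) {
    sigma <- profile$resolution_fwhm / (2 * sqrt(2 * log(2)))
    dw <- wl[2] - wl[1]                      # dense reference grid is uniform
    half <- max(1L, ceiling(4 * sigma / dw))
    kern <- stats::dnorm(seq(-half, half) * dw, sd = sigma)
    kern <- kern / sum(kern)
    padded <- c(rep(pure[1], half), pure, rep(pure[length(pure)], half))
    smoothed <- stats::convolve(padded, rev(kern), type = "filter")
  }
  inst_grid <- seq(profile$span[1], profile$span[2], length.out = profile$n_channels)
  # the instrument reads the scene at (nominal wavelength + shift)
  vals <- stats::approx(wl, smoothed, xout = inst_grid + profile$wavelength_shift)$y
  gain <- profile$gain
  offset <- profile$offset
  slope <- profile$baseline_slope
  if (profile$gain_jitter_sd > 0) gain <- gain * (1 + stats::rnorm(1, sd = profile$gain_jitter_sd))
  if (profile$offset_jitter_sd > 0) offset <- offset + stats::rnorm(1, sd = profile$offset_jitter_sd)
  if (profile$slope_jitter_sd > 0) slope <- slope + stats::rnorm(1, sd = profile$slope_jitter_sd)
  vals <- gain * vals + offset + slope * (inst_grid - profile$span[1])
  if (profile$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), sd = profile$noise_sd)
  }
  vals
}

instrument_grid <- function(profile) {
  wavelength_grid(seq(profile$span[1], profile$span[2], length.out = profile$n_channels))
}

#' Generate a paired master/slave NIR dataset
#'
#' Emulates a two-spectrometer measurement campaign: `n_source` samples measured on
#' the master instrument (labelled) and `n_target` on the slave (labels held
#' out in `truth`). The first `min(n_source, n_target)` samples share the same
#' concentration draws across instruments ("paired mode"), so they can serve
#' as transfer standards for the classical methods; extra samples on either
#' side get independent draws. Concentrations are uniform on [0.1, 1] per
#' component; labels are `label_coefficients . c + N(0, label_noise_sd)`.
#'
#' @param n_source labelled master-instrument sample count.
#' @param n_target unlabelled slave-instrument sample count.
#' @param library a [component_library()].
#' @param master,slave [instrument_profile()]s.
#' @param seed integer seed; the whole dataset is a deterministic function of it.
#' @return A list of class `"paired_nir"`: `source` (labelled
#'   [spectra_set()]), `target` (unlabelled), `truth` (list with
#'   `target_labels`, `concentrations_source`, `concentrations_target`,
#'   `library`), `n_paired`, `seed`.
#' @export
generate_paired <- function(n_source = 196, n_target = 270,
                            library = component_library(),
                            master = master_profile(), slave = slave_profile(),
                            seed = 1) {
  if (!.is_count(n_source) || !.is_count(n_target)) {
    stop_nirshift("sample counts must be positive integers", "nirshift_argument_error")
  }
  validate_component_library(library)
  set.seed(derive_seed(seed, "generate_paired"))
  k <- length(library$components)
  n_pair <- min(n_source, n_target)
  conc_pair <- matrix(stats::runif(n_pair * k, 0.1, 1.0), n_pair, k)
  conc_s <- rbind(conc_pair,
                  if (n_source > n_pair)
                    matrix(stats::runif((n_source - n_pair) * k, 0.1, 1.0),
                           n_source - n_pair, k))
  conc_t <- rbind(conc_pair,
                  if (n_target > n_pair)
                    matrix(stats::runif((n_target - n_pair) * k, 0.1, 1.0),
                           n_target - n_pair, k))
  # per-sample band-shape deviations are a property of the physical specimen,
  # so paired samples share them across instruments
  jitter_of <- function(n) {
    list(shift = if (library$center_jitter_sd > 0)
                   stats::rnorm(n, sd = library$center_jitter_sd) else numeric(n),
         wscale = if (library$width_jitter_sd > 0)
                    1 + stats::rnorm(n, sd = library$width_jitter_sd) else rep(1, n))
  }
  j_pair <- jitter_of(n_pair)
  j_s_x <- jitter_of(max(0L, n_source - n_pair))
  j_t_x <- jitter_of(max(0L, n_target - n_pair))
  j_s <- list(shift = c(j_pair$shift, j_s_x$shift),
              wscale = c(j_pair$wscale, j_s_x$wscale))
  j_t <- list(shift = c(j_pair$shift, j_t_x$shift),
              wscale = c(j_pair$wscale, j_t_x$wscale))
  ref <- reference_grid()
  measure <- function(conc, profile, jit) {
    t(vapply(seq_len(nrow(conc)), function(i)
      apply_instrument(
        simulate_pure_spectrum(conc[i, ], library, ref,
                               center_shift = jit$shift[i],
                               width_scale = jit$wscale[i]),
        profile, ref),
      numeric(profile$n_channels)))
  }
  abs_s <- measure(conc_s, master, j_s)
  abs_t <- measure(conc_t, slave, j_t)
  lab <- function(conc) {
    drop(conc %*% library$label_coefficients) +
      if (library$label_noise_sd > 0)
        stats::rnorm(nrow(conc), sd = library$label_noise_sd) else 0
  }
  labels_s <- lab(conc_s)
  labels_t <- lab(conc_t)
  structure(
    list(
      source = spectra_set(instrument_grid(master), abs_s, labels = labels_s,
                           instrument_id = "master"),
      target = spectra_set(instrument_grid(slave), abs_t, labels = NULL,
                           instrument_id = "slave"),
      truth = list(target_labels = labels_t,
                   concentrations_source = conc_s,
                   concentrations_target = conc_t,
                   library = library, master = master, slave = slave),
      n_paired = n_pair, seed = as.integer(seed)
    ),
    class = "paired_nir"
  )
}

#' @export
print.paired_nir <- function(x, ...) {
  cat(sprintf(
    "<paired_nir> source: %d x %d (labelled), target: %d x %d (labels in $truth), %d paired, seed %d\n",
    nrow(x$source$absorbance), ncol(x$source$absorbance),
    nrow(x$target$absorbance), ncol(x$target$absorbance), x$n_paired, x$seed))
  invisible(x)
}

#' Write a paired dataset to disk
#'
#' Emits `source.csv` and `target.csv` spectra files, a `truth.csv` with the
#' held-out target labels and concentration draws, and a `generator.yaml`
#' sidecar recording the generator parameters.
#'
#' @param dataset a [generate_paired()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_paired <- function(dataset, dir) {
  stopifnot(inherits(dataset, "paired_nir"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(dataset$source, file.path(dir, "source.csv"))
  write_spectra_csv(dataset$target, file.path(dir, "target.csv"))
  tr <- dataset$truth
  df <- data.frame(target_label = tr$target_labels)
  for (j in seq_len(ncol(tr$concentrations_target))) {
    df[[paste0("conc_", j)]] <- tr$concentrations_target[, j]
  }
  utils::write.csv(df, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(seed = dataset$seed, n_paired = dataset$n_paired,
         label_coefficients = as.numeric(tr$library$label_coefficients),
         label_noise_sd = tr$library$label_noise_sd,
         master = unclass(tr$master), slave = unclass(tr$slave)),
    file.path(dir, "generator.yaml"))
  invisible(dir)
}
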