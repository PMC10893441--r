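test_that("pure spectra are linear in concentrations with Gaussian band shape", {
  lib <- component_library()
  grid <- nirshift:::reference_grid()
  k <- length(lib$components)

  expect_equal(simulate_pure_spectrum(rep(0, k), lib, grid),
               rep(0, length(grid)))

  c1 <- c(0.4, 0.7, 0.2)
  a1 <- simulate_pure_spectrum(c1, lib, grid)
  expect_equal(simulate_pure_spectrum(2 * c1, lib, grid), 2 * a1, tolerance = 1e-12)

  # single peak: maximum at the grid point nearest the band centre
  one <- structure(list(
    components = list(x = list(centers = 1200, sigmas = 20, amps = 1)),
    label_coefficients = 1, label_noise_sd = 0), class = "component_library")
  a <- simulate_pure_spectrum(1, one, grid)
  expect_equal(which.max(a), which.min(abs(as.numeric(grid) - 1200)))
  expect_lte(max(a), 1)

  expect_error(simulate_pure_spectrum(c(-1, 0, 0), lib, grid),
               class = "nirshift_argument_error")
})

test_that("identity instrument profile reduces to plain resampling", {
  lib <- component_library()
  grid <- nirshift:::reference_grid()
  pure <- simulate_pure_spectrum(c(0.5, 0.5, 0.5), lib, grid)
  prof <- instrument_profile(118L, resolution_fwhm = 0, noise_sd = 0)
  out <- apply_instrument(pure, prof, grid)
  ref <- resample_to_grid(spectra_set(grid, matrix(pure, 1)),
                          nirshift:::instrument_grid(prof))
  expect_lt(max(abs(out - ref$absorbance)), 1e-12)

  prof2 <- instrument_profile(118L, gain = 2)
  expect_lt(max(abs(apply_instrument(pure, prof2, grid) - 2 * out)), 1e-12)
})

test_that("instrument convolution broadens a Gaussian band as expected", {
  grid <- nirshift:::reference_grid()
  wl <- as.numeric(grid)
  sigma0 <- 15
  pure <- exp(-(wl - 1300)^2 / (2 * sigma0^2))
  fwhm <- 20
  prof <- instrument_profile(512L, resolution_fwhm = fwhm, noise_sd = 0)
  out <- apply_instrument(pure, prof, grid)
  iw <- as.numeric(nirshift:::instrument_grid(prof))
  # Gaussian (*) Gaussian: variance adds
  sig_inst <- fwhm / (2 * sqrt(2 * log(2)))
  sig_exp <- sqrt(sigma0^2 + sig_inst^2)
  amp_exp <- sigma0 / sig_exp
  expected <- amp_exp * exp(-(iw - 1300)^2 / (2 * sig_exp^2))
  expect_lt(max(abs(out - expected)) / max(expected), 0.02)
})

test_that("out-of-span instrument requests are refused", {
  grid <- wavelength_grid(seq(900, 1700, length.out = 256))
  prof <- instrument_profile(64L, span = c(850, 1700))
  expect_error(apply_instrument(rep(1, 256), prof, grid),
               class = "nirshift_range_error")
})

test_that("generate_paired mirrors the two-instrument study design", {
  ds <- generate_paired(n_source = 12, n_target = 15, seed = 2)
  expect_equal(ncol(ds$source$absorbance), 512L)
  expect_equal(ncol(ds$target$absorbance), 118L)
  expect_equal(nrow(ds$source$absorbance), 12L)
  expect_equal(nrow(ds$target$absorbance), 15L)
  expect_null(ds$target$labels)
  expect_length(ds$truth$target_labels, 15L)
  # paired mode: shared concentration draws for the overlapping prefix
  expect_equal(ds$truth$concentrations_source[1:12, ],
               ds$truth$concentrations_target[1:12, ])

  ds2 <- generate_paired(n_source = 12, n_target = 15, seed = 2)
  expect_identical(ds$source$absorbance, ds2$source$absorbance)
  expect_identical(ds$truth$target_labels, ds2$truth$target_labels)
})

test_that("noiseless labels are exactly linear in the concentrations", {
  lib <- component_library(label_noise_sd = 0)
  ds <- generate_paired(n_source = 20, n_target = 8, library = lib, seed = 4)
  expect_lt(max(abs(ds$source$labels -
                      drop(ds$truth$concentrations_source %*% lib$label_coefficients))),
            1e-12)
  # generator self-consistency: OLS of labels on concentrations recovers the
  # coefficients
  fit <- lm(ds$source$labels ~ ds$truth$concentrations_source - 1)
  expect_lt(max(abs(coef(fit) - lib$label_coefficients)), 1e-8)
})

test_that("identity slave profile agrees with resampled master up to noise", {
  lib <- component_library(label_noise_sd = 0)
  master <- instrument_profile(512L, resolution_fwhm = 0, noise_sd = 0)
  slave <- instrument_profile(118L, resolution_fwhm = 0, noise_sd = 0)
  ds <- generate_paired(n_source = 6, n_target = 6, library = lib,
                        master = master, slave = slave, seed = 9)
  res <- resample_to_grid(ds$source, ds$target$grid)
  # both routes interpolate off the dense reference grid, so agreement is at
  # the interpolation error scale, not machine precision
  expect_lt(max(abs(res$absorbance - ds$target$absorbance)), 2e-3)
})

test_that("paired datasets serialize to CSV plus YAML sidecar", {
  ds <- generate_paired(n_source = 4, n_target = 5, seed = 6)
  dir <- withr::local_tempdir()
  write_paired(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("source.csv", "target.csv", "truth.csv", "generator.yaml")))))
  back <- read_spectra_csv(file.path(dir, "source.csv"))
  expect_lt(max(abs(back$absorbance - ds$source$absorbance)), 1e-10)
  meta <- yaml::read_yaml(file.path(dir, "generator.yaml"))
  expect_equal(meta$seed, 6)
  expect_equal(meta$slave$n_channels, 118L)
})
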