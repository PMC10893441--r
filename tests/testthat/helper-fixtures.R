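# Small programmatic fixtures shared across the test files.

# A tiny spectra set with known contents.
toy_spectra <- function(n = 3, wl = c(900, 1100, 1300), labels = TRUE, seed = 1) {
  set.seed(seed)
  spectra_set(wavelength_grid(wl),
              matrix(stats::runif(n * length(wl)), n, length(wl)),
              labels = if (labels) stats::runif(n, 30, 120) else NULL,
              instrument_id = "toy")
}

# Paired random master/slave standards linked by a known linear map.
linear_pair <- function(n_std = 30, p = 12, seed = 5) {
  set.seed(seed)
  gm <- wavelength_grid(seq(1000, 1600, length.out = p))
  M <- matrix(stats::rnorm(n_std * p), n_std, p)
  Tm <- matrix(stats::rnorm(p * p), p, p) + diag(p) * 2
  list(master = spectra_set(gm, M),
       slave = spectra_set(gm, M %*% Tm),
       map = Tm, grid = gm)
}

# A small paired dataset for training tests (fast but non-trivial).
small_paired <- function(seed = 3) {
  generate_paired(n_source = 40, n_target = 48, seed = seed)
}

# Reduced-budget training configuration for desk-scale tests.
fast_config <- function(seed = 1, ...) {
  adapt_config(iterations_warmup = 150L, iterations_private = 60L,
               iterations_joint = 80L, width_private = 16L, width_shared = 8L,
               seed = seed, ...)
}

# Cache shared across acceptance-test blocks so the expensive benchmark runs
# once per session.
.accept_cache <- new.env(parent = emptyenv())

accept_benchmark <- function() {
  if (!is.null(.accept_cache$bench)) return(.accept_cache$bench)
  ds <- generate_paired(n_source = 196, n_target = 270, seed = 11)
  truth <- ds$truth$target_labels
  methods <- c("dan", "cdan", "mdd", "etd", "glot")
  seeds <- 1:5
  adapted <- matrix(NA_real_, length(seeds), length(methods),
                    dimnames = list(NULL, methods))
  baseline <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    b_cfg <- adapt_config(iterations_warmup = 400L, iterations_private = 0L,
                          iterations_joint = 0L, seed = seeds[i])
    base <- nir_adapt(ds$source, ds$target, method = "dan", config = b_cfg)
    baseline[i] <- r_squared_percent(predict(base, ds$target), truth)
    for (m in methods) {
      cfg <- adapt_config(iterations_warmup = 400L, iterations_private = 400L,
                          iterations_joint = 400L, seed = seeds[i])
      fit <- nir_adapt(ds$source, ds$target, method = m, config = cfg)
      adapted[i, m] <- r_squared_percent(predict(fit, ds$target), truth)
    }
  }
  .accept_cache$bench <- list(dataset = ds, baseline = baseline, adapted = adapted)
  .accept_cache$bench
}

accept_split_sweep <- function() {
  if (!is.null(.accept_cache$sweep)) return(.accept_cache$sweep)
  ds <- accept_benchmark()$dataset
  cfg <- adapt_config(iterations_warmup = 400L, iterations_private = 400L,
                      iterations_joint = 400L)
  .accept_cache$sweep <- split_ratio_sweep(
    c("dan", "cdan", "mdd", "etd", "glot"), ds,
    ratios = c(0.25, 0.70), reps = 3L, seed = 21, config = cfg)
  .accept_cache$sweep
}

accept_ct_sweep <- function() {
  if (!is.null(.accept_cache$ct)) return(.accept_cache$ct)
  ds <- accept_benchmark()$dataset
  .accept_cache$ct <- transfer_sample_sweep(
    c("DS", "PDS", "SST"), ds, fractions = c(0.3, 0.5, 0.7),
    seed = 11, reps = 16L)
  .accept_cache$ct
}
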