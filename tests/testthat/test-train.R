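test_that("make_model wires the right auxiliaries per method", {
  cfg <- fast_config()
  cdan <- make_model("cdan", 512, 118, cfg)
  expect_s3_class(cdan$aux$discriminator, "discriminator")
  dan <- make_model("dan", 512, 118, cfg)
  expect_length(dan$aux, 0L)
  mdd <- make_model("mdd", 512, 118, cfg)
  expect_true(!is.null(mdd$aux$aux_head))
  etd <- make_model("etd", 512, 118, cfg)
  expect_s3_class(etd$aux$attention, "attention_net")
  expect_s3_class(etd$aux$potential, "potential_net")
  expect_error(make_model("pls", 512, 118, cfg))
})

test_that("all five methods build and train end to end on a small fixture", {
  ds <- small_paired()
  tiny <- adapt_config(iterations_warmup = 8L, iterations_private = 4L,
                       iterations_joint = 4L, width_private = 8L,
                       width_shared = 4L, batch_size = 8L, seed = 1)
  for (m in c("dan", "cdan", "mdd", "etd", "glot")) {
    fit <- nir_adapt(ds$source, ds$target, method = m, config = tiny)
    expect_true(fit$trained)
    expect_equal(nrow(fit$training_log), 16L)
    expect_setequal(unique(fit$training_log$stage), c("A", "B", "C"))
    p <- predict(fit, ds$target)
    expect_length(p, nrow(ds$target$absorbance))
    expect_true(all(is.finite(p)))
  }
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- small_paired()
  cfg <- fast_config(seed = 7)
  a <- nir_adapt(ds$source, ds$target, method = "cdan", config = cfg)
  b <- nir_adapt(ds$source, ds$target, method = "cdan", config = cfg)
  expect_identical(a$training_log, b$training_log)
  expect_identical(a$backbone$private_target$W, b$backbone$private_target$W)
  expect_identical(predict(a, ds$target), predict(b, ds$target))
  c_ <- nir_adapt(ds$source, ds$target, method = "cdan", config = fast_config(seed = 8))
  expect_false(identical(predict(a, ds$target), predict(c_, ds$target)))
})

test_that("predictions are deterministic, bounded by the scaler band, and domain-routed", {
  ds <- small_paired()
  fit <- nir_adapt(ds$source, ds$target, method = "dan", config = fast_config())
  p1 <- predict(fit, ds$target)
  p2 <- predict(fit, ds$target)
  expect_identical(p1, p2)
  sc <- fit$backbone$label_scaler
  expect_true(all(p1 > sc$min - (sc$max - sc$min) * sc$lo / (sc$hi - sc$lo)))
  expect_true(all(p1 < sc$max + (sc$max - sc$min) * sc$lo / (sc$hi - sc$lo)))
  ps <- predict(fit, ds$source, domain = "source")
  expect_length(ps, nrow(ds$source$absorbance))
  expect_error(predict(fit, ds$source, domain = "target"),
               class = "nirshift_argument_error")

  untrained <- make_model("dan", 512, 118, fast_config())
  expect_error(predict(untrained, ds$target), class = "nirshift_state_error")
})

test_that("unlabelled source data is refused", {
  ds <- small_paired()
  bare <- spectra_set(ds$source$grid, ds$source$absorbance)
  expect_error(nir_adapt(bare, ds$target), class = "nirshift_argument_error")
})

test_that("the source fit converges on an easy noiseless task", {
  lib <- component_library(label_noise_sd = 0)
  master <- instrument_profile(64L, resolution_fwhm = 0, noise_sd = 0)
  ds <- generate_paired(n_source = 60, n_target = 20, library = lib,
                        master = master, slave = master, seed = 5)
  # regularization off: weight decay would bias the fit and floor the error
  cfg <- adapt_config(iterations_warmup = 3000L, iterations_private = 0L,
                      iterations_joint = 0L, width_private = 32L,
                      width_shared = 16L, dropout_rate = 0, weight_decay = 0,
                      seed = 2)
  fit <- nir_adapt(ds$source, ds$target, method = "dan", config = cfg)
  pred <- predict(fit, ds$source, domain = "source")
  expect_lt(rmse(pred, ds$source$labels), 0.1 * sd(ds$source$labels))
})

test_that("the warm-up loss decreases over averaged windows", {
  ds <- small_paired()
  cfg <- adapt_config(iterations_warmup = 300L, iterations_private = 0L,
                      iterations_joint = 0L, width_private = 16L,
                      width_shared = 8L, seed = 3)
  fit <- nir_adapt(ds$source, ds$target, method = "dan", config = cfg)
  task <- fit$training_log$task_loss[fit$training_log$stage == "A"]
  win <- colMeans(matrix(task, nrow = 50))
  expect_true(all(diff(win) < 0.005))
  expect_lt(win[length(win)], win[1])
})

test_that("with zero transfer weight the joint stage leaves the target routing alone", {
  ds <- small_paired()
  cfg0 <- fast_config(seed = 4, transfer_loss_weight = 0)
  for (m in c("dan", "mdd")) {
    full <- nir_adapt(ds$source, ds$target, method = m, config = cfg0)
    cfg_b <- cfg0
    cfg_b$iterations_joint <- 0L
    upto_b <- nir_adapt(ds$source, ds$target, method = m, config = cfg_b)
    # private_target receives only transfer gradients in stage C, so with
    # lambda = 0 it must be bit-identical to its post-stage-B state
    expect_identical(full$backbone$private_target$W,
                     upto_b$backbone$private_target$W)
  }
})

test_that("the target-private layer is frozen through the stage-B refresh", {
  # identical source and target (no shift, shared grid), full-batch and zero
  # dropout: stage B consumes no randomness and the MMD transfer gradient is
  # exactly zero, so the only thing that could move private_target would be
  # a freezing-contract violation in the supervised refresh half of stage B
  src <- toy_spectra(n = 12, wl = seq(900, 1700, length.out = 10), seed = 2)
  tgt <- spectra_set(src$grid, src$absorbance)
  cfg <- adapt_config(iterations_warmup = 30L, iterations_private = 0L,
                      iterations_joint = 0L, width_private = 6L,
                      width_shared = 4L, dropout_rate = 0, batch_size = 64L,
                      seed = 5)
  a_only <- nir_adapt(src, tgt, method = "dan", config = cfg)
  cfg$iterations_private <- 4L
  with_b <- nir_adapt(src, tgt, method = "dan", config = cfg)
  expect_identical(a_only$backbone$private_target$W,
                   with_b$backbone$private_target$W)
  # while the refresh half did move the supervised blocks
  expect_false(identical(a_only$backbone$private_source$W,
                         with_b$backbone$private_source$W))
})

test_that("residuals and plot methods work on a trained model", {
  ds <- small_paired()
  fit <- nir_adapt(ds$source, ds$target, method = "dan", config = fast_config())
  r <- residuals(fit, ds$source)
  expect_length(r, nrow(ds$source$absorbance))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_output(print(fit), "nir_adapt DAN")
  expect_output(summary(fit), "stage A")
})
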