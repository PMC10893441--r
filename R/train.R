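# Model assembly and the stage-wise training protocol.
#
# Stage A: supervised warm-up of private_source + shared + head on the
#   labelled source instrument (MSE on scaled labels).
# Stage B: private adaptation. First half: private_source and head frozen,
#   private_target (+ shared) descend the transfer loss on mixed batches —
#   the only label-free objective available. Second half: private_target
#   frozen, private_source + shared + head refreshed on source MSE.
# Stage C: joint fine-tune of everything on MSE(source) + lambda * transfer,
#   with the adversarial inner players (discriminator / auxiliary head /
#   attention / potential critic) updated by their own rules and the
#   adversarial feature gradient reversed with a 0 -> 1 coefficient ramp.

#' Assemble an adaptation model
#'
#' Wires the backbone and the requested transfer loss with its auxiliary
#' networks. `"dan"` uses multi-kernel MMD and needs no auxiliaries;
#' `"cdan"` adds a conditional discriminator and a label histogram;
#' `"mdd"` an auxiliary margin head; `"etd"` attention and Kantorovich
#' potential networks; `"glot"` none (the local term reuses the head).
#'
#' @param name one of `"dan"`, `"cdan"`, `"mdd"`, `"etd"`, `"glot"`.
#' @param n_channels_source,n_channels_target instrument channel counts.
#' @param config an [adapt_config()].
#' @param loss_options optional list of per-loss settings: `histogram_N`,
#'   `w_min` (cdan); `gamma`, `eta` (mdd); `epsilon`,
#'   `sinkhorn_iterations` (etd/glot); `local_radius` (glot).
#' @return An untrained object of class `"nir_adapt"`.
#' @export
make_model <- function(name, n_channels_source, n_channels_target,
                       config = adapt_config(), loss_options = list()) {
  name <- match.arg(name, c("dan", "cdan", "mdd", "etd", "glot"))
  set.seed(derive_seed(config$seed, paste0("init_", name)))
  backbone <- build_backbone(n_channels_source, n_channels_target,
                             width_private = config$width_private,
                             width_shared = config$width_shared,
                             dropout_rate = config$dropout_rate)
  opts <- utils::modifyList(list(
    histogram_N = 10L, w_min = 0, gamma = 4, eta = 1, mdd_inner_steps = 3L,
    epsilon = 0.05, sinkhorn_iterations = 100L, local_radius = 0.1,
    ot_batch = 64L
  ), loss_options)
  aux <- list()
  ws <- config$width_shared
  if (name == "cdan") {
    aux$discriminator <- discriminator(2L * ws)
  } else if (name == "mdd") {
    # the margin adversary needs a hidden layer: it must be able to disagree
    # with the head off the source feature manifold, otherwise collapsed
    # target features are a degenerate disparity minimizer
    aux$aux_head <- mlp(c(ws, 16L, 1L), c("relu", "sigmoid"))
    aux$mdd_cfg <- mdd_config(gamma = opts$gamma, eta = opts$eta)
  } else if (name == "etd") {
    aux$attention <- make_attention(ws)
    aux$potential <- make_potential(ws)
  }
  structure(
    list(method = name, backbone = backbone, aux = aux, config = config,
         loss_options = opts, trained = FALSE, training_log = NULL,
         histogram = NULL),
    class = "nir_adapt"
  )
}

# Initialize the target-private layer from the source one: copy each hidden
# unit's weight profile onto the target channel grid by linear interpolation
# (rescaled by the channel-spacing ratio), then match the first two moments
# of every unit's pre-activation distribution across instruments with a
# per-unit affine correction. The moment matching uses only unlabelled
# spectra and absorbs the bulk of a gain/offset-type instrument mismatch
# before any transfer loss is optimized; all five adaptation losses (and the
# no-adaptation baseline) start from the same routing.
resample_private <- function(private_source, grid_s, grid_t, Xs = NULL, Xt = NULL) {
  Ws <- private_source$W
  wl_s <- as.numeric(grid_s); wl_t <- as.numeric(grid_t)
  scale <- (length(wl_s) - 1) / (length(wl_t) - 1)
  Wt <- t(apply(Ws, 1L, function(row)
    stats::approx(wl_s, row, xout = pmin(pmax(wl_t, min(wl_s)), max(wl_s)))$y)) * scale
  bt <- private_source$b
  if (!is.null(Xs) && !is.null(Xt) && nrow(Xs) > 1L && nrow(Xt) > 1L) {
    zs <- .add_bias(Xs %*% t(Ws), private_source$b)
    zt0 <- Xt %*% t(Wt)
    sd_s <- apply(zs, 2L, stats::sd)
    sd_t <- pmax(apply(zt0, 2L, stats::sd), 1e-8)
    ck <- sd_s / sd_t
    Wt <- Wt * ck
    bt <- colMeans(zs) - ck * colMeans(zt0)
  }
  structure(list(W = Wt, b = bt, activation = private_source$activation),
            class = "dense_layer")
}

#' Fit a calibration-transfer network
#'
#' The main fitting function: trains one of the five unsupervised
#' domain-adaptation networks to predict labels from target-instrument
#' spectra using labelled source-instrument data and unlabelled
#' target-instrument data.
#'
#' @param source labelled [spectra_set()] (master instrument).
#' @param target unlabelled [spectra_set()] (slave instrument); any labels
#'   present are ignored during training.
#' @param method transfer method name, see [make_model()].
#' @param config an [adapt_config()]; `config$seed` makes the whole fit
#'   deterministic.
#' @param loss_options per-loss settings, see [make_model()].
#' @param model optionally, a pre-built [make_model()] object (overrides
#'   `method`/`config`/`loss_options`).
#' @return A trained `"nir_adapt"` object with a `training_log` data frame
#'   (iteration, stage, task_loss, transfer_loss, total).
#' @export
nir_adapt <- function(source, target, method = "dan", config = adapt_config(),
                      loss_options = list(), model = NULL) {
  stopifnot(inherits(source, "spectra_set"), inherits(target, "spectra_set"))
  if (is.null(source$labels)) {
    stop_nirshift("source spectra must be labelled", "nirshift_argument_error")
  }
  if (is.null(model)) {
    model <- make_model(method, length(source$grid), length(target$grid),
                        config = config, loss_options = loss_options)
  }
  cfg <- model$config
  bb <- model$backbone
  bb$label_scaler <- label_scaler(source$labels)
  y_scaled <- scale_labels(source$labels, bb$label_scaler)
  Xs <- source$absorbance
  Xt <- target$absorbance
  if (model$method == "cdan") {
    model$histogram <- build_label_histogram(source$labels, model$loss_options$histogram_N)
  }
  set.seed(derive_seed(cfg$seed, paste0("train_", model$method)))

  states <- list(private_source = opt_init(bb$private_source),
                 private_target = opt_init(bb$private_target),
                 shared = opt_init(bb$shared),
                 head = opt_init(bb$head))
  aux_states <- lapply(model$aux, function(a) {
    if (inherits(a, "discriminator") || inherits(a, "attention_net") ||
        inherits(a, "potential_net")) opt_init_net(a$layers)
    else if (is.list(a) && inherits(a[[1]], "dense_layer")) opt_init_net(a)
    else NULL
  })

  n_total <- cfg$iterations_warmup + cfg$iterations_private + cfg$iterations_joint
  log_stage <- character(n_total)
  log_task <- rep(NA_real_, n_total)
  log_transfer <- rep(NA_real_, n_total)
  log_i <- 0L
  push_log <- function(stage, task, transfer) {
    log_i <<- log_i + 1L
    log_stage[log_i] <<- stage
    log_task[log_i] <<- task
    log_transfer[log_i] <<- transfer
  }

  batch_idx <- function(n, size = cfg$batch_size) {
    if (n <= size) seq_len(n) else sample.int(n, size)
  }

  step_blocks <- function(grads_list, blocks, lr_factor = 1,
                          transfer_driven = FALSE) {
    cfg_use <- cfg
    cfg_use$learning_rate <- cfg$learning_rate * lr_factor
    # no weight decay on purely transfer-driven updates: decay pulls the
    # aligned target-private weights toward zero with nothing to oppose it
    if (transfer_driven) cfg_use$weight_decay <- 0
    for (blk in blocks) {
      g <- grads_list[[blk]]
      if (is.null(g)) next
      r <- opt_step_layer(bb[[blk]], g, states[[blk]], cfg_use)
      bb[[blk]] <<- r$layer
      states[[blk]] <<- r$state
    }
  }

  # mdd evaluates its disparity full-batch (the adversary overfits 32-sample
  # minibatches, which turns the pursuit into noise); etd transports a larger
  # batch than the task uses, because a 32-point cloud is not representative
  # enough of the source geometry for the plan to be meaningful; the other
  # losses share the task minibatch
  full_batch_transfer <- model$method == "mdd"
  ot_batch <- if (model$method == "etd") model$loss_options$ot_batch else NULL
  separate_transfer <- full_batch_transfer || !is.null(ot_batch)
  transfer_fwd <- function() {
    if (full_batch_transfer) {
      list(fs = forward_domain(bb, Xs, "source", "eval"),
           ft = forward_domain(bb, Xt, "target", "eval"),
           y = y_scaled)
    } else if (!is.null(ot_batch)) {
      is_ <- batch_idx(nrow(Xs), ot_batch)
      it_ <- batch_idx(nrow(Xt), ot_batch)
      list(fs = forward_domain(bb, Xs[is_, , drop = FALSE], "source", "train"),
           ft = forward_domain(bb, Xt[it_, , drop = FALSE], "target", "train"),
           y = y_scaled[is_])
    } else NULL
  }

  supervised_step <- function(blocks) {
    idx <- batch_idx(nrow(Xs))
    fwd <- forward_domain(bb, Xs[idx, , drop = FALSE], "source", "train")
    res <- fwd$f - y_scaled[idx]
    task <- mean(res^2)
    bwd <- backbone_bwd(bb, fwd, 2 * res / length(idx))
    step_blocks(list(private_source = bwd$private, shared = bwd$shared,
                     head = bwd$head), blocks)
    if (model$method == "mdd") {
      # pretrain the margin adversary to predict the labels on source, so at
      # the start of adaptation it agrees with the head on the source
      # manifold and is free only off it
      r <- mlp_fwd(fwd$g, model$aux$aux_head)
      gr <- mlp_bwd(model$aux$aux_head, r$caches,
                    matrix(2 * (drop(r$out) - y_scaled[idx]) / length(idx),
                           length(idx), 1L))
      up <- opt_step_net(model$aux$aux_head, gr$grads, aux_states$aux_head,
                         aux_cfg(cfg))
      model$aux$aux_head <<- up$layers
      aux_states$aux_head <<- up$states
    }
    task
  }

  # ---- Stage A: supervised warm-up ---------------------------------------
  for (it in seq_len(cfg$iterations_warmup)) {
    task <- supervised_step(c("private_source", "shared", "head"))
    push_log("A", task, NA_real_)
  }

  # after the warm-up the source routing is fitted; derive the target-private
  # starting point from it (this is also the no-adaptation baseline when the
  # stage B and C budgets are zero)
  bb$private_target <- resample_private(bb$private_source, source$grid,
                                        target$grid)
  states$private_target <- opt_init(bb$private_target)

  # ---- Stage B: private adaptation ---------------------------------------
  adversarial <- model$method %in% c("cdan", "mdd")
  n_b1 <- cfg$iterations_private %/% 2L
  n_b2 <- cfg$iterations_private - n_b1
  for (it in seq_len(n_b1)) {
    if (separate_transfer) {
      tf <- transfer_fwd()
      fs <- tf$fs; ft <- tf$ft; yb <- tf$y
    } else {
      is_ <- batch_idx(nrow(Xs)); it_ <- batch_idx(nrow(Xt))
      fs <- forward_domain(bb, Xs[is_, , drop = FALSE], "source", "train")
      ft <- forward_domain(bb, Xt[it_, , drop = FALSE], "target", "train")
      yb <- y_scaled[is_]
    }
    tg <- transfer_gradients(model, bb, fs, ft, yb, it / n_b1, aux_states, cfg)
    model <- tg$model; aux_states <- tg$aux_states
    # only the target-private layer moves: the shared trunk (and with it the
    # learned spectrum-to-label map) stays anchored to the source fit, so the
    # label-free transfer objective aligns rather than collapses the features
    bwd_t <- backbone_bwd(bb, ft, tg$d_ft, tg$d_gt)
    step_blocks(list(private_target = bwd_t$private), "private_target",
                lr_factor = if (adversarial) cfg$transfer_lr_factor else 1,
                transfer_driven = TRUE)
    push_log("B", NA_real_, tg$value)
  }
  for (it in seq_len(n_b2)) {
    task <- supervised_step(c("private_source", "shared", "head"))
    push_log("B", task, NA_real_)
  }

  # ---- Stage C: joint fine-tune ------------------------------------------
  lambda <- cfg$transfer_loss_weight
  n_c <- cfg$iterations_joint
  for (it in seq_len(n_c)) {
    is_ <- batch_idx(nrow(Xs))
    fs <- forward_domain(bb, Xs[is_, , drop = FALSE], "source", "train")
    res <- fs$f - y_scaled[is_]
    task <- mean(res^2)
    d_f_task <- 2 * res / length(is_)
    if (lambda > 0) {
      ramp <- it / n_c
      if (separate_transfer) {
        tf <- transfer_fwd()
        fs_tr <- tf$fs; ft <- tf$ft; yb <- tf$y
      } else {
        it_ <- batch_idx(nrow(Xt))
        ft <- forward_domain(bb, Xt[it_, , drop = FALSE], "target", "train")
        fs_tr <- fs; yb <- y_scaled[is_]
      }
      tg <- transfer_gradients(model, bb, fs_tr, ft, yb, ramp, aux_states, cfg)
      model <- tg$model; aux_states <- tg$aux_states
      if (separate_transfer) {
        bwd_task <- backbone_bwd(bb, fs, d_f_task)
        bwd_s <- backbone_bwd(bb, fs_tr, lambda * tg$d_fs, lambda * tg$d_gs)
        bwd_s <- list(private = add_grads(bwd_task$private, bwd_s$private),
                      shared = add_grads(bwd_task$shared, bwd_s$shared),
                      head = add_grads(bwd_task$head, bwd_s$head))
      } else {
        bwd_s <- backbone_bwd(bb, fs, d_f_task + lambda * tg$d_fs, lambda * tg$d_gs)
      }
      bwd_t <- backbone_bwd(bb, ft, lambda * tg$d_ft, lambda * tg$d_gt)
      head_g <- add_grads(bwd_s$head, bwd_t$head)
      if (!is.null(tg$head_grads)) {
        head_g <- add_grads(head_g, scale_grads(tg$head_grads, lambda))
      }
      # the whole of stage C runs at the damped fine-tuning rate: it refines
      # the warm-up fit and the stage-B alignment under the joint objective
      # rather than re-training from scratch
      step_blocks(list(private_source = bwd_s$private,
                       shared = add_grads(bwd_s$shared, bwd_t$shared),
                       head = head_g),
                  c("private_source", "shared", "head"),
                  lr_factor = cfg$transfer_lr_factor)
      step_blocks(list(private_target = bwd_t$private), "private_target",
                  lr_factor = cfg$transfer_lr_factor, transfer_driven = TRUE)
      push_log("C", task, tg$value)
    } else {
      bwd_s <- backbone_bwd(bb, fs, d_f_task)
      step_blocks(list(private_source = bwd_s$private, shared = bwd_s$shared,
                       head = bwd_s$head),
                  c("private_source", "shared", "head"))
      push_log("C", task, NA_real_)
    }
  }

  model$backbone <- bb
  model$trained <- TRUE
  keep <- seq_len(log_i)
  model$training_log <- data.frame(
    iteration = keep, stage = log_stage[keep],
    task_loss = log_task[keep], transfer_loss = log_transfer[keep],
    total = ifelse(is.na(log_task[keep]), 0, log_task[keep]) +
      lambda * ifelse(is.na(log_transfer[keep]), 0, log_transfer[keep]),
    row.names = NULL
  )
  model
}

add_grads <- function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db)
scale_grads <- function(g, s) list(dW = s * g$dW, db = s * g$db)

# Optimizer settings for auxiliary (inner-player) networks: same optimizer
# and rate as the main network but never weight decay — decaying an adversary
# or critic toward zero output manufactures spurious disagreement signal.
aux_cfg <- function(cfg) {
  list(optimizer = cfg$optimizer, learning_rate = cfg$learning_rate,
       momentum = cfg$momentum, weight_decay = 0)
}

# Evaluate the model's transfer loss on a pair of forward passes, update the
# loss's inner players (discriminator / margin adversary / attention /
# potential critic) by their own min-max rules, and return the gradients the
# backbone should *descend* (adversarial direction and ramp already applied).
transfer_gradients <- function(model, bb, fs, ft, y_scaled_batch, ramp,
                               aux_states, cfg) {
  method <- model$method
  acfg <- aux_cfg(cfg)
  out <- NULL
  if (method == "dan") {
    kern <- mkmmd_kernel(fs$g, ft$g)
    r <- mmd_grad(fs$g, ft$g, kern)
    out <- list(value = r$value, d_gs = r$d_gs, d_gt = r$d_gt,
                d_fs = rep(0, length(fs$f)), d_ft = rep(0, length(ft$f)))
  } else if (method == "cdan") {
    hist <- model$histogram
    w_s <- histogram_weight(unscale_predictions(y_scaled_batch, bb$label_scaler),
                            hist, model$loss_options$w_min)
    w_t <- histogram_weight(unscale_predictions(ft$f, bb$label_scaler),
                            hist, model$loss_options$w_min)
    r <- adversarial_grad(fs$f, fs$g, ft$f, ft$g, w_s, w_t, model$aux$discriminator)
    up <- opt_step_net(model$aux$discriminator$layers, r$D_grads,
                       aux_states$discriminator, acfg)
    model$aux$discriminator$layers <- up$layers
    aux_states$discriminator <- up$states
    # The discriminator has descended E'. The feature extractor now seeks
    # domain confusion through the non-saturating objective (minimize
    # -w log D on target, -w log(1-D) on source): unlike raw gradient
    # reversal of E', its gradient does not vanish while the discriminator
    # is winning, which keeps the minimax from degenerating into a random
    # walk. The prediction enters the discriminator as conditioning only,
    # so the adversarial gradient adapts the representation rather than
    # deforming the regression output directly.
    g <- confusion_grad(fs$f, fs$g, ft$f, ft$g, w_s, w_t, model$aux$discriminator)
    out <- list(value = r$value,
                d_gs = ramp * g$d_gs, d_gt = ramp * g$d_gt,
                d_fs = rep(0, length(fs$f)), d_ft = rep(0, length(ft$f)))
  } else if (method == "mdd") {
    cfgm <- model$aux$mdd_cfg
    ns <- length(fs$f); nt <- length(ft$f)
    # inner maximization: a few full adversary ascent steps per feature step
    for (k in seq_len(model$loss_options$mdd_inner_steps)) {
      rs <- mlp_fwd(fs$g, model$aux$aux_head)
      rt <- mlp_fwd(ft$g, model$aux$aux_head)
      as_ <- drop(rs$out); at_ <- drop(rt$out)
      bt <- mlp_bwd(model$aux$aux_head, rt$caches,
                    matrix(2 * (at_ - ft$f) / nt, nt, 1L))
      bs <- mlp_bwd(model$aux$aux_head, rs$caches,
                    matrix(-2 * cfgm$gamma * (as_ - fs$f) / ns, ns, 1L))
      asc <- Map(function(a, b) list(dW = -(a$dW + b$dW), db = -(a$db + b$db)),
                 bt$grads, bs$grads)
      up <- opt_step_net(model$aux$aux_head, asc, aux_states$aux_head, acfg)
      model$aux$aux_head <- up$layers
      aux_states$aux_head <- up$states
    }
    rs <- mlp_fwd(fs$g, model$aux$aux_head)
    rt <- mlp_fwd(ft$g, model$aux$aux_head)
    as_ <- drop(rs$out); at_ <- drop(rt$out)
    disp <- mdd_loss(fs$f, as_, ft$f, at_, cfgm)$disparity
    bt <- mlp_bwd(model$aux$aux_head, rt$caches,
                  matrix(2 * (at_ - ft$f) / nt, nt, 1L))
    bs <- mlp_bwd(model$aux$aux_head, rs$caches,
                  matrix(-2 * cfgm$gamma * (as_ - fs$f) / ns, ns, 1L))
    eta <- cfgm$eta
    # backbone descends eta * disparity:
    #   dD/df_t = -2(f'-f)_t/nt, dD/df_s = +2*gamma*(f'-f)_s/ns,
    #   dD/dg through the adversary with its parameters held fixed
    out <- list(value = disp,
                d_fs = ramp * eta * 2 * cfgm$gamma * (as_ - fs$f) / ns,
                d_ft = ramp * eta * -2 * (at_ - ft$f) / nt,
                d_gs = ramp * eta * bs$dX, d_gt = ramp * eta * bt$dX)
  } else if (method == "etd") {
    oc <- ot_config(model$loss_options$epsilon, model$loss_options$sinkhorn_iterations,
                    attention = model$aux$attention, potential = model$aux$potential)
    r <- etd_grad(fs$g, ft$g, fs$f, ft$f, oc)
    if (!is.null(r$attention_grads)) {
      up <- opt_step_net(model$aux$attention$layers, r$attention_grads,
                         aux_states$attention, acfg)
      model$aux$attention$layers <- up$layers
      aux_states$attention <- up$states
    }
    if (!is.null(r$potential_grads)) {
      up <- opt_step_net(model$aux$potential$layers, r$potential_grads,
                         aux_states$potential, acfg)
      model$aux$potential$layers <- up$layers
      aux_states$potential <- up$states
    }
    # as for the global-local loss below, the fitted source geometry is the
    # reference frame: the transport gradient moves only the target side
    out <- list(value = r$value, d_gs = r$d_gs * 0, d_gt = r$d_gt,
                d_fs = rep(0, length(fs$f)), d_ft = r$d_ft)
  } else {
    oc <- ot_config(model$loss_options$epsilon, model$loss_options$sinkhorn_iterations)
    r <- glot_grad(fs$g, ft$g, oc, model$loss_options$local_radius, bb$head)
    # the source representation is the reference frame: the global OT term
    # moves only the target features toward it (plus the local smoothness
    # gradient on the source side), otherwise the plan's wrong-pair pulls
    # drag the fitted source geometry away from the label map
    d_gs <- r$d_gs * 0
    if (!is.null(r$head_grads)) d_gs <- r$d_gs_local %||% d_gs
    out <- list(value = r$value, d_gs = d_gs, d_gt = r$d_gt,
                d_fs = rep(0, length(fs$f)), d_ft = rep(0, length(ft$f)),
                head_grads = r$head_grads)
  }
  out$model <- model
  out$aux_states <- aux_states
  out
}

# Non-saturating confusion gradients for the feature extractor: descend
# -mean_t[w log D] on the target side and -mean_s[w log(1-D)] on the source
# side, with the discriminator's parameters held fixed.
confusion_grad <- function(f_s, g_s, f_t, g_t, w_s, w_t, D) {
  ns <- length(f_s); nt <- length(f_t)
  Js <- cdan_joint_input(f_s, g_s)
  Jt <- cdan_joint_input(f_t, g_t)
  rs <- mlp_fwd(Js, D$layers); rt <- mlp_fwd(Jt, D$layers)
  ds <- disc_clamp(drop(rs$out)); dt <- disc_clamp(drop(rt$out))
  bs <- mlp_bwd(D$layers, rs$caches, matrix(w_s / (ns * (1 - ds)), ns, 1L))
  bt <- mlp_bwd(D$layers, rt$caches, matrix(-w_t / (nt * dt), nt, 1L))
  p <- ncol(g_s)
  from_joint <- function(dJ, f) {
    dJ[, 1:p, drop = FALSE] * f + dJ[, p + 1:p, drop = FALSE] * (1 - f)
  }
  list(d_gs = from_joint(bs$dX, f_s), d_gt = from_joint(bt$dX, f_t))
}

#' Predict labels from spectra with a trained adaptation model
#'
#' Deterministic eval-mode forward pass through the domain's private layer,
#' unscaled back to label units.
#'
#' @param object a trained `"nir_adapt"` model.
#' @param x a [spectra_set()] (or matrix) on the matching instrument grid.
#' @param domain `"target"` (default) or `"source"`.
#' @param ... unused.
#' @return Numeric label vector.
#' @export
predict.nir_adapt <- function(object, x, domain = c("target", "source"), ...) {
  domain <- match.arg(domain)
  if (!isTRUE(object$trained)) {
    stop_nirshift("model has not been trained; call nir_adapt()", "nirshift_state_error")
  }
  fwd <- forward_domain(object$backbone, x, domain, "eval")
  unscale_predictions(fwd$f, object$backbone$label_scaler)
}

#' @export
print.nir_adapt <- function(x, ...) {
  cat(sprintf("<nir_adapt %s> %s, %d source / %d target channels, private %d, shared %d\n",
              toupper(x$method), if (x$trained) "trained" else "untrained",
              ncol(x$backbone$private_source$W), ncol(x$backbone$private_target$W),
              nrow(x$backbone$private_source$W), nrow(x$backbone$shared$W)))
  if (x$trained && nrow(x$training_log) > 0) {
    tl <- x$training_log
    last_task <- utils::tail(stats::na.omit(tl$task_loss), 1)
    last_tr <- utils::tail(stats::na.omit(tl$transfer_loss), 1)
    cat(sprintf("  %d iterations; final task loss %.4g%s\n", nrow(tl), last_task,
                if (length(last_tr)) sprintf(", transfer loss %.4g", last_tr) else ""))
  }
  invisible(x)
}

#' @export
summary.nir_adapt <- function(object, ...) {
  print(object)
  if (object$trained) {
    tl <- object$training_log
    for (st in unique(tl$stage)) {
      sub <- tl[tl$stage == st, ]
      cat(sprintf("  stage %s: %d iterations, mean task %.4g, mean transfer %.4g\n",
                  st, nrow(sub), mean(sub$task_loss, na.rm = TRUE),
                  mean(sub$transfer_loss, na.rm = TRUE)))
    }
  }
  invisible(object)
}

#' @export
plot.nir_adapt <- function(x, ...) {
  tl <- x$training_log
  if (is.null(tl) || nrow(tl) == 0) {
    stop_nirshift("no training log to plot", "nirshift_state_error")
  }
  graphics::plot(tl$iteration, tl$total, type = "l", xlab = "iteration",
                 ylab = "loss", main = sprintf("%s training", toupper(x$method)), ...)
  ok <- !is.na(tl$task_loss)
  graphics::lines(tl$iteration[ok], tl$task_loss[ok], col = "steelblue")
  graphics::legend("topright", legend = c("total", "task"),
                   col = c("black", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
residuals.nir_adapt <- function(object, source, ...) {
  stopifnot(inherits(source, "spectra_set"), !is.null(source$labels))
  source$labels - predict(object, source, domain = "source")
}
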