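# Dense-network engine.
#
# The backbone is deliberately small and fully connected: an instrument-
# private input layer per domain, a shared middle layer, dropout after each
# hidden layer in place of pooling, ReLU hidden activations and a sigmoid
# regression head. Reverse-mode gradients are written out by hand; every
# layer's forward pass caches what its backward pass needs.

act_apply <- function(z, activation) {
  switch(activation,
    identity = z,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    softplus = log1p(exp(-abs(z))) + pmax(z, 0),
    stop_nirshift(sprintf("unknown activation '%s'", activation), "nirshift_argument_error"))
}

# derivative wrt pre-activation, expressed from (pre, post) to avoid recompute
act_deriv <- function(z, a, activation) {
  switch(activation,
    identity = matrix(1, nrow(z), ncol(z)),
    relu = (z > 0) * 1,
    sigmoid = a * (1 - a),
    softplus = 1 / (1 + exp(-z)))
}

#' Create a dense layer
#'
#' Weights use seeded Glorot-style uniform fan-in initialization,
#' `U(-s, s)` with `s = sqrt(6 / (n_in + n_out))`; biases start at zero.
#' Initialization consumes the current RNG stream.
#'
#' @param n_in,n_out input/output widths.
#' @param activation one of `"relu"`, `"sigmoid"`, `"identity"`, `"softplus"`.
#' @return A list of class `"dense_layer"` with `W` (`n_out x n_in`), `b`,
#'   `activation`.
#' @export
dense_layer <- function(n_in, n_out, activation = "relu") {
  s <- sqrt(6 / (n_in + n_out))
  structure(
    list(W = matrix(stats::runif(n_out * n_in, -s, s), n_out, n_in),
         b = numeric(n_out), activation = activation),
    class = "dense_layer"
  )
}

#' Forward pass of one dense layer
#'
#' Computes `activation(W y + b)` for a single input vector.
#'
#' @param y numeric input vector of length `ncol(layer$W)`.
#' @param layer a [dense_layer()].
#' @return Numeric output vector.
#' @export
dense_forward <- function(y, layer) {
  if (length(y) != ncol(layer$W)) {
    stop_nirshift(sprintf("input length %d != layer fan-in %d", length(y), ncol(layer$W)),
                  "nirshift_argument_error")
  }
  drop(act_apply(matrix(layer$W %*% y + layer$b, 1L), layer$activation))
}

# Batched forward: X is n x in, returns list(out = n x out, cache).
layer_fwd <- function(X, layer) {
  Z <- .add_bias(X %*% t(layer$W), layer$b)
  A <- act_apply(Z, layer$activation)
  list(out = A, cache = list(X = X, Z = Z, A = A))
}

# Backward: dA is n x out gradient of the loss wrt the layer output.
# Returns gradients for W, b and the layer input.
layer_bwd <- function(layer, cache, dA) {
  dZ <- dA * act_deriv(cache$Z, cache$A, layer$activation)
  list(dW = crossprod(dZ, cache$X), db = colSums(dZ), dX = dZ %*% layer$W)
}

# A plain multi-layer stack (used for discriminator / attention / potential /
# auxiliary heads).
mlp <- function(widths, activations) {
  stopifnot(length(activations) == length(widths) - 1L)
  layers <- vector("list", length(widths) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- dense_layer(widths[i], widths[i + 1L], activations[i])
  }
  layers
}

mlp_fwd <- function(X, layers) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(X, layers[[i]])
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

mlp_bwd <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    g <- layer_bwd(layers[[i]], caches[[i]], dOut)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    dOut <- g$dX
  }
  list(grads = grads, dX = dOut)
}

# Inverted dropout: mask scaled by 1/(1-rate) so eval needs no rescaling.
dropout_mask <- function(n, p, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n * p, 1L, 1 - rate), n, p) / (1 - rate)
}

#' Affine label scaler for the sigmoid head
#'
#' The sigmoid head can only emit values in (0, 1), so labels are mapped
#' affinely from `[min, max]` onto the `[0.05, 0.95]` band — the margin keeps
#' targets away from the saturated tails of the sigmoid.
#'
#' @param labels numeric labels the scaler is fit on.
#' @return A list with `min`, `max`, `lo = 0.05`, `hi = 0.95`.
#' @export
label_scaler <- function(labels) {
  lo <- min(labels); hi <- max(labels)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop_nirshift("labels must span a non-degenerate range", "nirshift_argument_error")
  }
  list(min = lo, max = hi, lo = 0.05, hi = 0.95)
}

#' @rdname label_scaler
#' @param scaler a scaler from `label_scaler()`.
#' @export
scale_labels <- function(labels, scaler) {
  scaler$lo + (labels - scaler$min) / (scaler$max - scaler$min) * (scaler$hi - scaler$lo)
}

#' @rdname label_scaler
#' @param pred predictions on the (0, 1) scale.
#' @export
unscale_predictions <- function(pred, scaler) {
  scaler$min + (pred - scaler$lo) / (scaler$hi - scaler$lo) * (scaler$max - scaler$min)
}

#' Mean squared error
#'
#' The task loss for the regression head (used in place of cross-entropy,
#' which has no meaning for scalar regression targets).
#'
#' @param pred,labels_scaled equal-length numeric vectors.
#' @return Scalar mean of squared differences.
#' @export
mse_loss <- function(pred, labels_scaled) {
  if (length(pred) == 0L || length(pred) != length(labels_scaled)) {
    stop_nirshift("pred and labels must be equal-length, non-empty", "nirshift_argument_error")
  }
  mean((pred - labels_scaled)^2)
}

#' Build the private/shared backbone
#'
#' Two instrument-private input layers (one per domain, sized to each
#' instrument's channel count) feed a shared hidden layer; dropout follows
#' each hidden layer; a one-unit sigmoid head emits the scaled prediction.
#'
#' @param n_channels_source,n_channels_target input widths.
#' @param width_private,width_shared hidden widths.
#' @param dropout_rate dropout probability in train mode.
#' @param scaler a [label_scaler()].
#' @return A list of class `"nir_backbone"`.
#' @export
build_backbone <- function(n_channels_source, n_channels_target,
                           width_private = 64L, width_shared = 32L,
                           dropout_rate = 0.2, scaler = NULL) {
  structure(
    list(
      private_source = dense_layer(n_channels_source, width_private, "relu"),
      private_target = dense_layer(n_channels_target, width_private, "relu"),
      shared = dense_layer(width_private, width_shared, "relu"),
      head = dense_layer(width_shared, 1L, "sigmoid"),
      dropout_rate = dropout_rate,
      label_scaler = scaler
    ),
    class = "nir_backbone"
  )
}

#' Forward pass through the backbone for one domain
#'
#' Routes a batch through the chosen private layer, dropout, the shared
#' layer, dropout, and the head. Dropout is active only in `"train"` mode
#' (inverted dropout, scaled by `1/(1-rate)`); `"eval"` mode is a
#' deterministic function of weights and input. The returned features `g`
#' are the head's input (the shared layer output after dropout in train
#' mode), and `f` is the head's sigmoid output.
#'
#' @param backbone a [build_backbone()] result.
#' @param x a [spectra_set()] or a plain matrix of matching channel count.
#' @param domain `"source"` or `"target"`.
#' @param mode `"train"` or `"eval"`.
#' @return A list with `f` (predictions in (0,1)), `g` (feature matrix) and,
#'   internally, the caches needed for backpropagation.
#' @export
forward_domain <- function(backbone, x, domain = c("source", "target"),
                           mode = c("eval", "train")) {
  domain <- match.arg(domain)
  mode <- match.arg(mode)
  X <- if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
  private <- if (domain == "source") backbone$private_source else backbone$private_target
  if (ncol(X) != ncol(private$W)) {
    stop_nirshift(sprintf("%d channels do not match the %s private layer (%d)",
                          ncol(X), domain, ncol(private$W)),
                  "nirshift_argument_error")
  }
  rate <- if (mode == "train") backbone$dropout_rate else 0
  r1 <- layer_fwd(X, private)
  m1 <- dropout_mask(nrow(X), ncol(r1$out), rate)
  h1 <- if (is.null(m1)) r1$out else r1$out * m1
  r2 <- layer_fwd(h1, backbone$shared)
  m2 <- dropout_mask(nrow(X), ncol(r2$out), rate)
  g <- if (is.null(m2)) r2$out else r2$out * m2
  r3 <- layer_fwd(g, backbone$head)
  list(f = drop(r3$out), g = g,
       cache = list(domain = domain, private = r1$cache, m1 = m1,
                    shared = r2$cache, m2 = m2, head = r3$cache))
}

# Backward through the backbone given upstream gradients on the prediction f
# (vector) and, optionally, directly on the features g (matrix). Returns
# per-block weight gradients; the private block is the one the forward used.
backbone_bwd <- function(backbone, fwd, d_f, d_g = NULL) {
  cache <- fwd$cache
  n <- length(fwd$f)
  gh <- layer_bwd(backbone$head, cache$head, matrix(d_f, n, 1L))
  dG <- gh$dX
  if (!is.null(d_g)) dG <- dG + d_g
  if (!is.null(cache$m2)) dG <- dG * cache$m2
  gs <- layer_bwd(backbone$shared, cache$shared, dG)
  dH1 <- gs$dX
  if (!is.null(cache$m1)) dH1 <- dH1 * cache$m1
  private <- if (cache$domain == "source") backbone$private_source else backbone$private_target
  gp <- layer_bwd(private, cache$private, dH1)
  list(private = list(dW = gp$dW, db = gp$db),
       shared = list(dW = gs$dW, db = gs$db),
       head = list(dW = gh$dW, db = gh$db),
       domain = cache$domain)
}

# ---- Optimizers -----------------------------------------------------------
# Parameter containers are lists of dense layers (or the backbone blocks);
# optimizer state mirrors the parameter shapes. Adam follows the usual
# bias-corrected moments with L2 weight decay folded into the gradient;
# RMSProp keeps a squared-gradient average plus heavy-ball momentum.

opt_init <- function(layer) {
  list(mW = layer$W * 0, vW = layer$W * 0, mb = layer$b * 0, vb = layer$b * 0, t = 0L)
}

opt_step_layer <- function(layer, grad, state, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer == "adam") {
    b1 <- cfg$momentum; b2 <- 0.999; eps <- 1e-8
    gW <- grad$dW + cfg$weight_decay * layer$W
    gb <- grad$db
    state$t <- state$t + 1L
    state$mW <- b1 * state$mW + (1 - b1) * gW
    state$vW <- b2 * state$vW + (1 - b2) * gW^2
    state$mb <- b1 * state$mb + (1 - b1) * gb
    state$vb <- b2 * state$vb + (1 - b2) * gb^2
    c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
    layer$W <- layer$W - lr * (state$mW / c1) / (sqrt(state$vW / c2) + eps)
    layer$b <- layer$b - lr * (state$mb / c1) / (sqrt(state$vb / c2) + eps)
  } else if (cfg$optimizer == "rmsprop") {
    alpha <- 0.99; eps <- 1e-8
    state$vW <- alpha * state$vW + (1 - alpha) * grad$dW^2
    state$vb <- alpha * state$vb + (1 - alpha) * grad$db^2
    state$mW <- cfg$momentum * state$mW + grad$dW / (sqrt(state$vW) + eps)
    state$mb <- cfg$momentum * state$mb + grad$db / (sqrt(state$vb) + eps)
    layer$W <- layer$W - lr * state$mW
    layer$b <- layer$b - lr * state$mb
  } else {
    stop_nirshift(sprintf("unknown optimizer '%s'", cfg$optimizer), "nirshift_argument_error")
  }
  list(layer = layer, state = state)
}

opt_init_net <- function(layers) lapply(layers, opt_init)

opt_step_net <- function(layers, grads, states, cfg) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    r <- opt_step_layer(layers[[i]], grads[[i]], states[[i]], cfg)
    layers[[i]] <- r$layer
    states[[i]] <- r$state
  }
  list(layers = layers, states = states)
}

#' Training configuration
#'
#' Defaults follow common practice for this family of models: Adam or
#' RMSProp, learning rate 0.001, momentum 0.9, Adam weight decay 0.01, and a
#' transfer-loss weight (lambda) of 0.1 on the joint objective.
#'
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param learning_rate positive step size.
#' @param momentum first-moment coefficient (Adam beta1 / RMSProp momentum).
#' @param weight_decay L2 penalty folded into Adam gradients.
#' @param transfer_loss_weight lambda multiplying the transfer loss in the
#'   joint objective.
#' @param transfer_lr_factor learning-rate multiplier for parameter blocks
#'   whose only gradient source is the transfer objective (the target-private
#'   layer after warm-up, and adversarially driven updates). Damping these
#'   updates keeps the min-max dynamics from oscillating; 1 disables it.
#' @param batch_size minibatch size.
#' @param iterations_warmup,iterations_private,iterations_joint iteration
#'   budgets for the three training stages.
#' @param width_private,width_shared backbone hidden widths.
#' @param dropout_rate dropout probability.
#' @param seed integer seed governing initialization, dropout and batching.
#' @return A list of class `"adapt_config"`.
#' @export
adapt_config <- function(optimizer = c("adam", "rmsprop"), learning_rate = 0.001,
                         momentum = 0.9, weight_decay = 0.01,
                         transfer_loss_weight = 0.1, transfer_lr_factor = 0.1,
                         batch_size = 32L,
                         iterations_warmup = 2000L, iterations_private = 1000L,
                         iterations_joint = 2000L, width_private = 64L,
                         width_shared = 32L, dropout_rate = 0.2, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) {
    stop_nirshift("learning_rate must be positive", "nirshift_argument_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_nirshift("dropout_rate must lie in [0, 1)", "nirshift_argument_error")
  }
  if (transfer_loss_weight < 0) {
    stop_nirshift("transfer_loss_weight must be non-negative", "nirshift_argument_error")
  }
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate, momentum = momentum,
         weight_decay = weight_decay, transfer_loss_weight = transfer_loss_weight,
         transfer_lr_factor = transfer_lr_factor,
         batch_size = as.integer(batch_size),
         iterations_warmup = as.integer(iterations_warmup),
         iterations_private = as.integer(iterations_private),
         iterations_joint = as.integer(iterations_joint),
         width_private = as.integer(width_private),
         width_shared = as.integer(width_shared),
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "adapt_config"
  )
}
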