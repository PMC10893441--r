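# Transfer losses.
#
# Each loss measures a discrepancy between source-domain and target-domain
# batches in the backbone's feature/prediction space. The public functions
# return the loss value; the internal *_grad variants additionally return
# hand-derived gradients with respect to features, predictions and any
# auxiliary network, which the training loop consumes.

#' Kernel specification for (MK-)MMD
#'
#' @param family `"gaussian"` (the working kernel) or `"linear"` (a test
#'   kernel for which squared MMD has the closed form
#'   `||mean_s - mean_t||^2`).
#' @param bandwidths positive sigma values; the multi-kernel estimate
#'   averages over them. Ignored for the linear kernel.
#' @return A list of class `"kernel_spec"`.
#' @export
kernel_spec <- function(family = c("gaussian", "linear"), bandwidths = 1) {
  family <- match.arg(family)
  if (family == "gaussian" && (length(bandwidths) < 1L || any(bandwidths <= 0))) {
    stop_nirshift("bandwidths must be positive and non-empty", "nirshift_argument_error")
  }
  structure(list(family = family, bandwidths = as.numeric(bandwidths)),
            class = "kernel_spec")
}

#' Median-heuristic multi-kernel bandwidths
#'
#' The classic multi-kernel set: the median pairwise distance of the pooled
#' sample, scaled by `{0.25, 0.5, 1, 2, 4}`.
#'
#' @param features_s,features_t feature matrices (rows = samples).
#' @return A `"kernel_spec"` with five Gaussian bandwidths.
#' @export
mkmmd_kernel <- function(features_s, features_t) {
  pooled <- rbind(features_s, features_t)
  d2 <- pairwise_sqdist(pooled, pooled)
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  kernel_spec("gaussian", med * c(0.25, 0.5, 1, 2, 4))
}

pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Maximum mean discrepancy between two feature samples
#'
#' Biased V-statistic estimate of squared MMD, averaged over the kernel set:
#' `mean(K_ss) + mean(K_tt) - 2 mean(K_st)`. Non-negative by construction
#' and zero when the two samples coincide.
#'
#' @param features_s,features_t matrices with equal column count.
#' @param kernel a [kernel_spec()].
#' @return Scalar squared-MMD estimate.
#' @export
mmd <- function(features_s, features_t, kernel = mkmmd_kernel(features_s, features_t)) {
  mmd_grad(features_s, features_t, kernel, want_grad = FALSE)$value
}

mmd_grad <- function(features_s, features_t, kernel, want_grad = TRUE) {
  A <- as.matrix(features_s); B <- as.matrix(features_t)
  if (ncol(A) != ncol(B)) {
    stop_nirshift("feature dimensions differ between domains", "nirshift_argument_error")
  }
  if (nrow(A) < 1L || nrow(B) < 1L) {
    stop_nirshift("need at least one sample per domain", "nirshift_argument_error")
  }
  ns <- nrow(A); nt <- nrow(B)
  if (kernel$family == "linear") {
    Kss <- tcrossprod(A); Ktt <- tcrossprod(B); Kst <- tcrossprod(A, B)
    value <- mean(Kss) + mean(Ktt) - 2 * mean(Kst)
    if (!want_grad) return(list(value = value))
    ms <- colMeans(A); mt <- colMeans(B)
    d_gs <- matrix(2 * (ms - mt) / ns, ns, ncol(A), byrow = TRUE)
    d_gt <- matrix(-2 * (ms - mt) / nt, nt, ncol(B), byrow = TRUE)
    return(list(value = value, d_gs = d_gs, d_gt = d_gt))
  }
  Dss <- pairwise_sqdist(A, A); Dtt <- pairwise_sqdist(B, B); Dst <- pairwise_sqdist(A, B)
  value <- 0
  d_gs <- if (want_grad) A * 0 else NULL
  d_gt <- if (want_grad) B * 0 else NULL
  nk <- length(kernel$bandwidths)
  for (sg in kernel$bandwidths) {
    s2 <- sg^2
    Kss <- exp(-Dss / (2 * s2)); Ktt <- exp(-Dtt / (2 * s2)); Kst <- exp(-Dst / (2 * s2))
    value <- value + (mean(Kss) + mean(Ktt) - 2 * mean(Kst)) / nk
    if (want_grad) {
      # d k(x,y)/dx = -k * (x - y) / s2 ; V-statistic weights 1/ns^2 etc.
      cs <- -2 / (ns^2 * s2)
      d_gs <- d_gs + cs * (rowSums(Kss) * A - Kss %*% A) / nk
      ct <- -2 / (nt^2 * s2)
      d_gt <- d_gt + ct * (rowSums(Ktt) * B - Ktt %*% B) / nk
      cx <- 2 / (ns * nt * s2)
      d_gs <- d_gs + cx * (rowSums(Kst) * A - Kst %*% B) / nk
      d_gt <- d_gt + cx * (colSums(Kst) * B - t(Kst) %*% A) / nk
    }
  }
  list(value = value, d_gs = d_gs, d_gt = d_gt)
}

# ---- Label histogram weighting (conditional adversarial branch) -----------

#' Build a label histogram
#'
#' Uniformly partitions the label range `[R_n, R_m]` into `N` half-open
#' segments (the last segment closed) and records per-segment counts and
#' probabilities. This histogram drives the sample-weighting scheme of the
#' conditional adversarial loss: segments holding many labels are easier for
#' the network to pin down and their samples get larger adversarial weight.
#'
#' @param labels non-empty numeric vector.
#' @param N segment count (>= 1).
#' @param range optional length-2 override of `[R_n, R_m]` (defaults to the
#'   observed label range).
#' @return A list of class `"label_histogram"` with `R_n`, `R_m`, `N`,
#'   `counts`, `num_label`, `p`, `p_min`, `p_max`.
#' @export
build_label_histogram <- function(labels, N = 10L, range = NULL) {
  if (length(labels) == 0L) {
    stop_nirshift("labels must be non-empty", "nirshift_argument_error")
  }
  if (!.is_count(N)) stop_nirshift("N must be a positive integer", "nirshift_argument_error")
  if (is.null(range)) range <- c(min(labels), max(labels))
  R_n <- range[1]; R_m <- range[2]
  if (N > 1L && R_m <= R_n) {
    stop_nirshift("labels must be non-constant when N > 1", "nirshift_argument_error")
  }
  k <- segment_index(labels, R_n, R_m, N)
  counts <- tabulate(k, nbins = N)
  p <- counts / length(labels)
  structure(
    list(R_n = R_n, R_m = R_m, N = as.integer(N), counts = counts,
         num_label = length(labels), p = p, p_min = min(p), p_max = max(p)),
    class = "label_histogram"
  )
}

# 1-based segment index; values outside [R_n, R_m] clamp to the end segments,
# the last segment is closed.
segment_index <- function(x, R_n, R_m, N) {
  if (N == 1L) return(rep(1L, length(x)))
  k <- floor((x - R_n) / (R_m - R_n) * N) + 1L
  pmin(pmax(as.integer(k), 1L), N)
}

#' Histogram-derived adversarial weight
#'
#' Maps a value on the label axis to `(p_k - p_min) / (p_max - p_min)` for
#' its segment: 1 for the most-populated segment, 0 for the least-populated.
#' Values outside the histogram range clamp to the nearest end segment. A
#' perfectly uniform histogram carries no information about sample
#' difficulty, so the weight degenerates to 1 everywhere. An optional floor
#' `w_min` keeps the sparsest segments from being silenced entirely
#' (default 0, the literal scheme).
#'
#' @param g_value scalar or vector on the label scale (for network output,
#'   map through [unscale_predictions()] first).
#' @param hist a [build_label_histogram()] result.
#' @param w_min optional lower bound on the weight.
#' @return Weights in `[max(w_min, 0), 1]`.
#' @export
histogram_weight <- function(g_value, hist, w_min = 0) {
  stopifnot(inherits(hist, "label_histogram"))
  if (hist$p_max == hist$p_min) return(rep(1, length(g_value)))
  k <- segment_index(g_value, hist$R_n, hist$R_m, hist$N)
  w <- (hist$p[k] - hist$p_min) / (hist$p_max - hist$p_min)
  pmax(w, w_min)
}

#' Joint conditioning input for the conditional discriminator
#'
#' For regression the prediction is a scalar in (0, 1); conditioning the
#' discriminator on features and prediction uses the flattened outer product
#' with the two-bin soft assignment `(f, 1 - f)`: `[g * f, g * (1 - f)]`.
#' The map is a partition of unity in `f`, so `||joint||_1 = ||g||_1` for
#' non-negative features.
#'
#' @param f scalar prediction per sample (vector for a batch).
#' @param g feature row (matrix for a batch).
#' @return Matrix with twice the feature columns.
#' @export
cdan_joint_input <- function(f, g) {
  g <- if (is.null(dim(g))) matrix(g, nrow = 1L) else as.matrix(g)
  cbind(g * f, g * (1 - f))
}

#' Create a domain discriminator
#'
#' A two-layer dense network (ReLU hidden width 32, sigmoid output) whose
#' output is clamped to `[1e-6, 1 - 1e-6]` so the adversarial logs stay
#' finite. Initialization consumes the current RNG stream.
#'
#' @param input_dim input width (for the conditional variant,
#'   `2 * feature_dim`).
#' @param width hidden width.
#' @return A list of class `"discriminator"`.
#' @export
discriminator <- function(input_dim, width = 32L) {
  structure(list(layers = mlp(c(input_dim, width, 1L), c("relu", "sigmoid"))),
            class = "discriminator")
}

disc_clamp <- function(d) pmin(pmax(d, 1e-6), 1 - 1e-6)

#' Weighted conditional adversarial loss
#'
#' The discriminator objective of the conditional adversarial transfer
#' branch with per-sample histogram weights:
#' `E' = -mean_s[w log D(f,g)] - mean_t[w log(1 - D(f,g))]`.
#' The discriminator descends this; the feature extractor ascends it
#' (domain confusion), implemented in training by gradient reversal.
#'
#' @param f_s,f_t prediction vectors per domain.
#' @param g_s,g_t feature matrices per domain.
#' @param weights_s,weights_t per-sample weights (see [histogram_weight()]).
#' @param D a [discriminator()] taking the joint input.
#' @return Scalar loss value.
#' @export
weighted_adversarial_loss <- function(f_s, g_s, f_t, g_t, weights_s, weights_t, D) {
  adversarial_grad(f_s, g_s, f_t, g_t, weights_s, weights_t, D, want_grad = FALSE)$value
}

adversarial_grad <- function(f_s, g_s, f_t, g_t, weights_s, weights_t, D,
                             want_grad = TRUE) {
  if (length(weights_s) != length(f_s) || length(weights_t) != length(f_t)) {
    stop_nirshift("weights must align with samples", "nirshift_argument_error")
  }
  ns <- length(f_s); nt <- length(f_t)
  Js <- cdan_joint_input(f_s, g_s)
  Jt <- cdan_joint_input(f_t, g_t)
  rs <- mlp_fwd(Js, D$layers); rt <- mlp_fwd(Jt, D$layers)
  ds <- disc_clamp(drop(rs$out)); dt <- disc_clamp(drop(rt$out))
  value <- -mean(weights_s * log(ds)) - mean(weights_t * log(1 - dt))
  if (!want_grad) return(list(value = value))
  # dE'/d d_s = -w/(ns * d_s); dE'/d d_t = w/(nt * (1 - d_t))
  bs <- mlp_bwd(D$layers, rs$caches, matrix(-weights_s / (ns * ds), ns, 1L))
  bt <- mlp_bwd(D$layers, rt$caches, matrix(weights_t / (nt * (1 - dt)), nt, 1L))
  D_grads <- Map(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
                 bs$grads, bt$grads)
  p <- ncol(g_s)
  split_joint <- function(dJ, f, g) {
    d_g <- dJ[, 1:p, drop = FALSE] * f + dJ[, p + 1:p, drop = FALSE] * (1 - f)
    d_f <- rowSums(dJ[, 1:p, drop = FALSE] * g) - rowSums(dJ[, p + 1:p, drop = FALSE] * g)
    list(d_g = d_g, d_f = d_f)
  }
  ss <- split_joint(bs$dX, f_s, g_s)
  st <- split_joint(bt$dX, f_t, g_t)
  list(value = value, d_fs = ss$d_f, d_gs = ss$d_g, d_ft = st$d_f, d_gt = st$d_g,
       D_grads = D_grads)
}

# ---- Margin disparity discrepancy -----------------------------------------

#' Margin disparity discrepancy configuration
#'
#' @param gamma margin factor (>= 1).
#' @param eta tradeoff weight on the disparity term in the main objective.
#' @return A list of class `"mdd_config"`.
#' @export
mdd_config <- function(gamma = 4, eta = 1) {
  if (gamma < 1) stop_nirshift("gamma must be >= 1", "nirshift_argument_error")
  if (eta <= 0) stop_nirshift("eta must be positive", "nirshift_argument_error")
  structure(list(gamma = gamma, eta = eta), class = "mdd_config")
}

#' Margin disparity for regression
#'
#' The regression adaptation of margin disparity discrepancy: with a main
#' head `f` and an auxiliary adversarial head `f'` scoring the same
#' features, `disparity = mean_t[(f' - f)^2] - gamma * mean_s[(f' - f)^2]`.
#' The adversary maximizes the disparity; the main network minimizes source
#' MSE plus `eta` times it.
#'
#' @param main_pred_s,aux_pred_s,main_pred_t,aux_pred_t prediction vectors.
#' @param cfg an [mdd_config()].
#' @return List with `disparity` and `adversary_objective` (its negation,
#'   which the auxiliary head descends).
#' @export
mdd_loss <- function(main_pred_s, aux_pred_s, main_pred_t, aux_pred_t, cfg = mdd_config()) {
  stopifnot(inherits(cfg, "mdd_config"))
  if (length(main_pred_s) != length(aux_pred_s) ||
      length(main_pred_t) != length(aux_pred_t)) {
    stop_nirshift("per-domain prediction vectors must align", "nirshift_argument_error")
  }
  disparity <- mean((aux_pred_t - main_pred_t)^2) -
    cfg$gamma * mean((aux_pred_s - main_pred_s)^2)
  list(disparity = disparity, adversary_objective = -disparity)
}

# ---- Entropic optimal transport -------------------------------------------

#' Optimal-transport configuration
#'
#' @param epsilon entropic regularization strength (> 0).
#' @param sinkhorn_iterations Sinkhorn iteration count (>= 1).
#' @param attention optional attention network (see [make_attention()]).
#' @param potential optional Kantorovich potential network.
#' @return A list of class `"ot_config"`.
#' @export
ot_config <- function(epsilon = 0.05, sinkhorn_iterations = 200L,
                      attention = NULL, potential = NULL) {
  if (epsilon <= 0) stop_nirshift("epsilon must be positive", "nirshift_argument_error")
  if (!.is_count(sinkhorn_iterations)) {
    stop_nirshift("sinkhorn_iterations must be a positive integer", "nirshift_argument_error")
  }
  structure(list(epsilon = epsilon,
                 sinkhorn_iterations = as.integer(sinkhorn_iterations),
                 attention = attention, potential = potential),
            class = "ot_config")
}

#' Entropic-regularized transport plan between uniform marginals
#'
#' Log-domain Sinkhorn iterations (numerically stable for small `epsilon`),
#' followed by an explicit rounding of the nearly-feasible iterate onto the
#' transport polytope (row/column downscaling plus a rank-one correction),
#' so the returned plan has exact uniform marginals at any regularization
#' strength.
#'
#' @param cost non-negative finite cost matrix `n_s x n_t`.
#' @param epsilon entropic regularization.
#' @param iterations iteration count.
#' @return Transport plan matrix with row sums `1/n_s`, column sums `1/n_t`.
#' @export
sinkhorn_plan <- function(cost, epsilon = 0.05, iterations = 200L) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) {
    stop_nirshift("cost matrix must be finite", "nirshift_argument_error")
  }
  ns <- nrow(cost); nt <- ncol(cost)
  log_a <- -log(ns); log_b <- -log(nt)
  f <- numeric(ns); g <- numeric(nt)
  for (it in seq_len(iterations)) {
    g <- -epsilon * col_lse((f - cost) / epsilon + log_a)
    f <- -epsilon * row_lse(sweep(-cost, 2L, g, "+") / epsilon + log_b)
  }
  P <- exp(sweep((f - cost), 2L, g, "+") / epsilon + log_a + log_b)
  # round onto the polytope: scale overfull rows/columns down, then repair
  # the (non-negative) deficits with a rank-one correction
  a <- 1 / ns; b <- 1 / nt
  P <- P * pmin(1, a / pmax(rowSums(P), 1e-300))
  P <- sweep(P, 2L, pmin(1, b / pmax(colSums(P), 1e-300)), "*")
  ea <- a - rowSums(P); eb <- b - colSums(P)
  s <- sum(ea)
  if (s > 0) P <- P + outer(ea, eb) / s
  P
}

row_lse <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  m + log(rowSums(exp(M - m)))
}

col_lse <- function(M) row_lse(t(M))

#' Attention network for pair reweighting
#'
#' A two-layer dense network scoring each (source, target) feature pair;
#' softplus output keeps scores positive and they are normalized to mean 1
#' before multiplying the transport cost.
#'
#' @param feature_dim backbone feature width.
#' @param width hidden width.
#' @return A list of class `"attention_net"`.
#' @export
make_attention <- function(feature_dim, width = 16L) {
  structure(list(layers = mlp(c(2L * feature_dim, width, 1L), c("relu", "softplus"))),
            class = "attention_net")
}

#' Kantorovich potential network
#'
#' A small dense critic on the feature space, trained by ascent on the OT
#' dual objective `mean_s[g(x)] - mean_t[g^c(y)]` with the hard c-transform
#' `g^c(y) = min_i (c(x_i, y) - g(x_i))`.
#'
#' @param feature_dim backbone feature width.
#' @param width hidden width.
#' @return A list of class `"potential_net"`.
#' @export
make_potential <- function(feature_dim, width = 16L) {
  structure(list(layers = mlp(c(feature_dim, width, 1L), c("relu", "identity"))),
            class = "potential_net")
}

#' Enhanced transport distance
#'
#' Pairwise cost `||g_s - g_t||^2 + (f_s - f_t)^2` between the two domains,
#' multiplicatively reweighted by the attention network's mean-1-normalized
#' pair scores, transported by the entropic plan; the loss is the plan-
#' weighted total cost. The Kantorovich potential network, when present, is
#' fitted to the dual objective as a critic (its dual value is reported, not
#' added to the loss).
#'
#' @param features_s,features_t feature matrices.
#' @param preds_s,preds_t prediction vectors.
#' @param cfg an [ot_config()].
#' @return Scalar transport loss.
#' @export
etd_loss <- function(features_s, features_t, preds_s, preds_t, cfg = ot_config()) {
  etd_grad(features_s, features_t, preds_s, preds_t, cfg, want_grad = FALSE)$value
}

etd_grad <- function(features_s, features_t, preds_s, preds_t, cfg, want_grad = TRUE) {
  A <- as.matrix(features_s); B <- as.matrix(features_t)
  if (ncol(A) != ncol(B)) {
    stop_nirshift("feature dimensions differ between domains", "nirshift_argument_error")
  }
  ns <- nrow(A); nt <- nrow(B)
  C <- pairwise_sqdist(A, B) + outer(preds_s, preds_t, "-")^2
  att <- cfg$attention
  if (!is.null(att)) {
    # pair inputs: [g_s,i , g_t,j] for all ij, row-major over j within i
    pair_in <- cbind(A[rep(seq_len(ns), each = nt), , drop = FALSE],
                     B[rep(seq_len(nt), times = ns), , drop = FALSE])
    ra <- mlp_fwd(pair_in, att$layers)
    S <- matrix(drop(ra$out), ns, nt, byrow = TRUE)
    mS <- mean(S)
    Amat <- S / mS
  } else {
    Amat <- matrix(1, ns, nt)
  }
  M <- Amat * C
  P <- sinkhorn_plan(M, cfg$epsilon, cfg$sinkhorn_iterations)
  value <- sum(P * M)
  out <- list(value = value)
  if (!is.null(cfg$potential)) {
    pot <- potential_dual(A, B, C, cfg$potential)
    out$dual_value <- pot$value
    out$potential_grads <- pot$grads
  }
  if (!want_grad) return(out)
  W <- P * Amat                      # plan and attention held fixed (envelope)
  rw_s <- rowSums(W); rw_t <- colSums(W)
  out$d_gs <- 2 * (rw_s * A - W %*% B)
  out$d_gt <- 2 * (rw_t * B - t(W) %*% A)
  df <- outer(preds_s, preds_t, "-")
  out$d_fs <- 2 * rowSums(W * df)
  out$d_ft <- -2 * colSums(W * df)
  if (!is.null(att)) {
    # dL/dS with plan and cost fixed: value = sum(P * C * S) / mean(S)
    PC <- P * C
    dS <- PC / mS - sum(PC * S) / (mS^2 * ns * nt)
    ba <- mlp_bwd(att$layers, ra$caches,
                  matrix(as.vector(t(dS)), ns * nt, 1L))
    out$attention_grads <- ba$grads
  }
  out
}

# OT dual value and ascent gradients for the potential network's parameters.
# Convention: g^c(y_j) = max_i (g(x_i) - C_ij), so g(x) - g^c(y) <= c(x, y)
# and the dual value mean_s[g] - mean_t[g^c] never exceeds the primal
# transport cost (weak duality).
potential_dual <- function(A, B, C, potential) {
  ra <- mlp_fwd(A, potential$layers)
  gA <- drop(ra$out)
  Z <- gA - C
  jmax <- apply(Z, 2L, which.max)
  gc <- Z[cbind(jmax, seq_len(ncol(C)))]
  value <- mean(gA) - mean(gc)
  # d value / d g(x_i) = 1/ns - (# argmaxes hitting i)/nt
  ns <- nrow(A); nt <- ncol(C)
  up <- rep(1 / ns, ns) - tabulate(jmax, nbins = ns) / nt
  back <- mlp_bwd(potential$layers, ra$caches, matrix(up, ns, 1L))
  # ascent direction: negate for use with descent-based optimizers
  grads <- lapply(back$grads, function(g) list(dW = -g$dW, db = -g$db))
  list(value = value, grads = grads)
}

#' Global-local optimal-transport regularizer
#'
#' The global term is the entropic OT distance between the two feature
#' clouds (squared-Euclidean ground cost). The local term is a one-step
#' adversarial smoothness surrogate: each source feature is pushed a
#' distance `local_radius` along the gradient direction of the prediction
#' head, and the squared prediction change is averaged. For a linear head
#' this equals `(local_radius * ||w||)^2` exactly.
#'
#' @param features_s,features_t feature matrices.
#' @param preds_s source predictions (from `head` on `features_s`).
#' @param labels_s scaled source labels (kept for signature symmetry with
#'   the other losses; the surrogate itself is label-free).
#' @param cfg an [ot_config()].
#' @param local_radius perturbation radius (>= 0); 0 disables the local term.
#' @param head the prediction head (a [dense_layer()]); required when
#'   `local_radius > 0`.
#' @return Scalar `global + local` loss.
#' @export
glot_loss <- function(features_s, features_t, preds_s = NULL, labels_s = NULL,
                      cfg = ot_config(), local_radius = 0, head = NULL) {
  glot_grad(features_s, features_t, cfg, local_radius, head, want_grad = FALSE)$value
}

glot_grad <- function(features_s, features_t, cfg, local_radius, head,
                      want_grad = TRUE) {
  if (local_radius < 0) {
    stop_nirshift("local_radius must be non-negative", "nirshift_argument_error")
  }
  A <- as.matrix(features_s); B <- as.matrix(features_t)
  C <- pairwise_sqdist(A, B)
  P <- sinkhorn_plan(C, cfg$epsilon, cfg$sinkhorn_iterations)
  global <- sum(P * C)
  out <- list(global = global, local = 0)
  if (want_grad) {
    rw_s <- rowSums(P); rw_t <- colSums(P)
    out$d_gs <- 2 * (rw_s * A - P %*% B)
    out$d_gt <- 2 * (rw_t * B - t(P) %*% A)
  }
  if (local_radius > 0) {
    if (is.null(head)) {
      stop_nirshift("local term requires the prediction head", "nirshift_argument_error")
    }
    r1 <- layer_fwd(A, head)
    f1 <- drop(r1$out)
    # input gradient of the head at A: act'(z) * w
    gin <- act_deriv(r1$cache$Z, r1$cache$A, head$activation)
    Gdir <- (gin %*% head$W)
    nrm <- sqrt(rowSums(Gdir^2))
    dir <- Gdir / pmax(nrm, 1e-12)
    dir[nrm < 1e-12, ] <- 0
    A2 <- A + local_radius * dir
    r2 <- layer_fwd(A2, head)
    f2 <- drop(r2$out)
    n <- length(f1)
    out$local <- mean((f2 - f1)^2)
    if (want_grad) {
      d2 <- 2 * (f2 - f1) / n
      b2 <- layer_bwd(head, r2$cache, matrix(d2, n, 1L))
      b1 <- layer_bwd(head, r1$cache, matrix(-d2, n, 1L))
      out$d_gs_local <- b2$dX + b1$dX        # direction treated as constant
      out$d_gs <- out$d_gs + out$d_gs_local
      out$head_grads <- list(dW = b2$dW + b1$dW, db = b2$db + b1$db)
    }
  }
  out$value <- out$global + out$local
  out
}

#' Transfer discrepancy in the no-shift limit and beyond
#'
#' A diagnostic that reports, for each of the five transfer methods, a
#' non-negative discrepancy between two feature/prediction samples that
#' vanishes (to optimization/regularization tolerance) when the samples
#' coincide. For the distance-based losses this is the loss itself; for the
#' adversarial ones the inner player is fitted for `inner_steps` gradient
#' steps and its achievable advantage is reported.
#'
#' @param method one of `"dan"`, `"cdan"`, `"mdd"`, `"etd"`, `"glot"`.
#' @param features_s,features_t feature matrices.
#' @param preds_s,preds_t prediction vectors in (0, 1).
#' @param inner_steps gradient steps for the inner (adversarial) player.
#' @param seed seed for inner-player initialization.
#' @return Scalar discrepancy >= 0 up to optimization tolerance.
#' @export
transfer_discrepancy <- function(method, features_s, features_t, preds_s, preds_t,
                                 inner_steps = 200L, seed = 1L) {
  method <- match.arg(method, c("dan", "cdan", "mdd", "etd", "glot"))
  set.seed(derive_seed(seed, paste0("discrepancy_", method)))
  p <- ncol(features_s)
  cfg <- list(optimizer = "adam", learning_rate = 0.01, momentum = 0.9,
              weight_decay = 0)
  if (method == "dan") {
    return(mmd(features_s, features_t))
  }
  if (method == "etd") {
    oc <- ot_config(epsilon = 0.01, sinkhorn_iterations = 300L)
    return(etd_loss(features_s, features_t, preds_s, preds_t, oc))
  }
  if (method == "glot") {
    oc <- ot_config(epsilon = 0.01, sinkhorn_iterations = 300L)
    return(glot_grad(features_s, features_t, oc, 0, NULL, want_grad = FALSE)$value)
  }
  if (method == "mdd") {
    # sup over f' of the disparity; at gamma = 1 it is <= 0 for equal domains
    aux <- mlp(c(p, 1L), "sigmoid")
    st <- opt_init_net(aux)
    cfgm <- mdd_config(gamma = 1)
    best <- -Inf
    for (it in seq_len(inner_steps)) {
      rs <- mlp_fwd(features_s, aux); rt <- mlp_fwd(features_t, aux)
      as_ <- drop(rs$out); at_ <- drop(rt$out)
      disp <- mdd_loss(preds_s, as_, preds_t, at_, cfgm)$disparity
      best <- max(best, disp)
      ns <- length(preds_s); nt <- length(preds_t)
      gt <- mlp_bwd(aux, rt$caches, matrix(-2 * (at_ - preds_t) / nt, nt, 1L))
      gs <- mlp_bwd(aux, rs$caches,
                    matrix(2 * cfgm$gamma * (as_ - preds_s) / ns, ns, 1L))
      grads <- Map(function(a, b) list(dW = a$dW + b$dW, db = a$db + b$db),
                   gt$grads, gs$grads)
      r <- opt_step_net(aux, grads, st, cfg)
      aux <- r$layers; st <- r$states
    }
    return(max(0, best))
  }
  # cdan: discriminator advantage 2 log 2 * mean(w) - min_D E'
  D <- discriminator(2L * p)
  st <- opt_init_net(D$layers)
  w_s <- rep(1, length(preds_s)); w_t <- rep(1, length(preds_t))
  val <- NA_real_
  for (it in seq_len(inner_steps)) {
    g <- adversarial_grad(preds_s, features_s, preds_t, features_t, w_s, w_t, D)
    val <- g$value
    r <- opt_step_net(D$layers, g$D_grads, st, cfg)
    D$layers <- r$layers; st <- r$states
  }
  max(0, 2 * log(2) * mean(c(w_s, w_t)) - val)
}
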