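test_that("mmd is a non-negative symmetric discrepancy, zero on identical samples", {
  set.seed(30)
  for (rep in 1:20) {
    A <- matrix(rnorm(5 * 3), 5, 3)
    B <- matrix(rnorm(7 * 3, mean = rep %% 3), 7, 3)
    k <- kernel_spec("gaussian", c(0.5, 1, 2))
    expect_gte(mmd(A, B, k), 0)
    expect_equal(mmd(A, B, k), mmd(B, A, k), tolerance = 1e-12)
  }
  A <- matrix(rnorm(12), 4, 3)
  expect_lt(mmd(A, A, kernel_spec("gaussian", 1)), 1e-12)
  expect_error(mmd(matrix(0, 2, 3), matrix(0, 2, 4)),
               class = "nirshift_argument_error")
})

test_that("linear-kernel mmd equals the squared mean gap (closed form)", {
  # the 1-d spec case: s = {0, 2}, t = {1, 3} -> ||0+2)/2 - (1+3)/2||^2 = 1
  expect_equal(mmd(matrix(c(0, 2)), matrix(c(1, 3)), kernel_spec("linear")), 1)
  set.seed(31)
  for (rep in 1:25) {
    A <- matrix(rnorm(6 * 4), 6, 4)
    B <- matrix(rnorm(9 * 4, mean = 0.5), 9, 4)
    expect_equal(mmd(A, B, kernel_spec("linear")),
                 sum((colMeans(A) - colMeans(B))^2), tolerance = 1e-10)
  }
})

test_that("a very wide gaussian kernel drives mmd to zero", {
  set.seed(32)
  A <- matrix(rnorm(8), 4, 2); B <- matrix(rnorm(10, 2), 5, 2)
  expect_lt(mmd(A, B, kernel_spec("gaussian", 1e6)), 1e-8)
})

test_that("label histograms match brute-force bin counting", {
  h <- build_label_histogram(c(1, 2, 3, 4, 8, 9), N = 2, range = c(0, 10))
  expect_equal(h$counts, c(4L, 2L))
  expect_equal(h$p, c(2 / 3, 1 / 3))

  expect_equal(build_label_histogram(rnorm(10), N = 1)$p, 1)

  set.seed(33)
  for (rep in 1:50) {
    n <- sample(5:80, 1)
    N <- sample(1:12, 1)
    labels <- runif(n, -3, 7)
    h <- build_label_histogram(labels, N)
    expect_equal(sum(h$p), 1)
    expect_equal(sum(h$counts), n)
    # brute force: count by explicit interval membership
    edges <- seq(h$R_n, h$R_m, length.out = N + 1)
    brute <- sapply(seq_len(N), function(k) {
      if (k < N) sum(labels >= edges[k] & labels < edges[k + 1])
      else sum(labels >= edges[k] & labels <= edges[k + 1])
    })
    expect_equal(h$counts, as.integer(brute))
  }
  expect_error(build_label_histogram(numeric(0)), class = "nirshift_argument_error")
})

test_that("histogram weights interpolate between 0 and 1 by segment occupancy", {
  h <- build_label_histogram(c(1, 2, 3, 4, 8, 9), N = 2, range = c(0, 10))
  expect_equal(histogram_weight(1.0, h), 1)   # most-populated segment
  expect_equal(histogram_weight(8.0, h), 0)   # least-populated segment
  # clamping outside the range
  expect_equal(histogram_weight(-5, h), 1)
  expect_equal(histogram_weight(25, h), 0)
  # uniform histogram carries no information: weight 1 everywhere
  hu <- build_label_histogram(c(1, 6), N = 2, range = c(0, 10))
  expect_equal(histogram_weight(c(2, 7), hu), c(1, 1))
  # optional floor
  expect_equal(histogram_weight(8.0, h, w_min = 0.1), 0.1)
  set.seed(34)
  w <- histogram_weight(runif(200, -2, 12), h)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("the joint conditioning input is a partition of unity in f", {
  g <- c(1, 2, 3)
  expect_equal(drop(cdan_joint_input(1, g)), c(g, 0, 0, 0))
  expect_equal(drop(cdan_joint_input(0.5, g)), c(g / 2, g / 2))
  set.seed(35)
  G <- matrix(abs(rnorm(12)), 3, 4)
  f <- runif(3)
  J <- cdan_joint_input(f, G)
  expect_equal(rowSums(abs(J)), rowSums(abs(G)), tolerance = 1e-12)
})

test_that("weighted adversarial loss has the stated two-sided form", {
  set.seed(36)
  D <- discriminator(4, width = 3)
  # constant D = 0.5: both logs give log 2 regardless of input
  D$layers[[2]]$W[] <- 0; D$layers[[2]]$b <- 0
  g_s <- matrix(rnorm(6), 3, 2); g_t <- matrix(rnorm(4), 2, 2)
  f_s <- runif(3); f_t <- runif(2)
  val <- weighted_adversarial_loss(f_s, g_s, f_t, g_t, rep(1, 3), rep(1, 2), D)
  expect_equal(val, 2 * log(2), tolerance = 1e-12)
  # zero weights annihilate the loss
  expect_equal(weighted_adversarial_loss(f_s, g_s, f_t, g_t, rep(0, 3), rep(0, 2), D), 0)
  # weight-1 degeneracy: equals the unweighted value on duplicated domains
  set.seed(37)
  D2 <- discriminator(4, width = 3)
  v1 <- weighted_adversarial_loss(f_s, g_s, f_s, g_s, rep(1, 3), rep(1, 3), D2)
  manual <- {
    J <- cdan_joint_input(f_s, g_s)
    d <- drop(nirshift:::mlp_fwd(J, D2$layers)$out)
    -mean(log(d)) - mean(log(1 - d))
  }
  expect_equal(v1, manual, tolerance = 1e-10)
  expect_error(weighted_adversarial_loss(f_s, g_s, f_t, g_t, 1, rep(1, 2), D),
               class = "nirshift_argument_error")
})

test_that("margin disparity follows its hand-computed arithmetic", {
  cfg <- mdd_config(gamma = 2)
  # target gap 1, source gap 0.5: 1 - 2 * 0.25 = 0.5
  r <- mdd_loss(main_pred_s = 0.5, aux_pred_s = 1.0,
                main_pred_t = 0, aux_pred_t = 1, cfg)
  expect_equal(r$disparity, 0.5)
  expect_equal(r$adversary_objective, -0.5)
  # f' == f gives zero disparity
  expect_equal(mdd_loss(c(.1, .2), c(.1, .2), c(.3), c(.3), cfg)$disparity, 0)
  # gamma = 1 with identical domains cancels
  expect_equal(mdd_loss(c(.1, .4), c(.2, .5), c(.1, .4), c(.2, .5),
                        mdd_config(gamma = 1))$disparity, 0)
  expect_error(mdd_config(gamma = 0.5), class = "nirshift_argument_error")
})

test_that("sinkhorn plans have correct marginals and near-LP cost", {
  expect_equal(sinkhorn_plan(matrix(0, 1, 1), 0.1, 10), matrix(1, 1, 1))

  P <- sinkhorn_plan(matrix(c(0, 1, 1, 0), 2, 2), 0.05, 500)
  expect_gt(sum(diag(P)), 0.98)

  # brute-force LP oracle: with uniform marginals the optimum sits on a
  # permutation (Birkhoff), so enumerate all of them
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  all_perms <- perms(1:5)
  set.seed(38)
  for (rep in 1:5) {
    C <- matrix(runif(25), 5, 5)
    P <- sinkhorn_plan(C, 0.015, 5000)
    expect_lt(max(abs(rowSums(P) - 1 / 5)), 1e-6)
    expect_lt(max(abs(colSums(P) - 1 / 5)), 1e-6)
    lp <- min(vapply(all_perms, function(p) sum(C[cbind(1:5, p)]), 0)) / 5
    expect_lt(sum(P * C), lp * 1.05 + 1e-12)
    expect_gte(sum(P * C) + 1e-12, lp)
  }
  expect_error(sinkhorn_plan(matrix(c(0, Inf), 1, 2), 0.1, 10),
               class = "nirshift_argument_error")
})

test_that("etd transport loss vanishes on identical clouds and grows with shift", {
  set.seed(39)
  A <- matrix(rnorm(20), 10, 2)
  f <- runif(10)
  oc <- ot_config(epsilon = 0.01, sinkhorn_iterations = 400)
  expect_lt(etd_loss(A, A, f, f, oc), 0.02)

  # attention = NULL degenerates to the plain entropic transport cost
  P <- sinkhorn_plan(nirshift:::pairwise_sqdist(A, A) + outer(f, f, "-")^2,
                     oc$epsilon, oc$sinkhorn_iterations)
  C <- nirshift:::pairwise_sqdist(A, A) + outer(f, f, "-")^2
  expect_equal(etd_loss(A, A, f, f, oc), sum(P * C), tolerance = 1e-10)

  shifts <- c(0, 0.5, 1.0)
  vals <- vapply(shifts, function(s)
    etd_loss(A, A + s, f, f, oc), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("attention reweighting preserves the loss under constant scores", {
  set.seed(40)
  A <- matrix(rnorm(12), 6, 2); B <- matrix(rnorm(8), 4, 2)
  fa <- runif(6); fb <- runif(4)
  att <- make_attention(2, width = 3)
  # force constant positive output: softplus(b) with zero weights
  att$layers[[2]]$W[] <- 0
  att$layers[[2]]$b <- 1.3
  oc_att <- ot_config(epsilon = 0.05, sinkhorn_iterations = 300, attention = att)
  oc_none <- ot_config(epsilon = 0.05, sinkhorn_iterations = 300)
  # scores are constant, normalization to mean 1 makes them exactly 1
  expect_equal(etd_loss(A, B, fa, fb, oc_att),
               etd_loss(A, B, fa, fb, oc_none), tolerance = 1e-10)
})

test_that("glot local term matches the linear-head closed form", {
  head <- structure(list(W = matrix(c(0.7, -0.4), 1, 2), b = 0.1,
                         activation = "identity"), class = "dense_layer")
  A <- matrix(c(1, 2), 1, 2)
  oc <- ot_config(epsilon = 0.05, sinkhorn_iterations = 200)
  r <- nirshift:::glot_grad(A, A, oc, local_radius = 0.3, head = head)
  expect_equal(r$local, (0.3 * sqrt(0.7^2 + 0.4^2))^2, tolerance = 1e-6)
  # radius 0 reduces exactly to the global OT term
  r0 <- nirshift:::glot_grad(A, A, oc, local_radius = 0, head = NULL)
  expect_equal(r0$value, r0$global)
  expect_lt(r0$value, 1e-8)
  expect_error(glot_loss(A, A, cfg = oc, local_radius = -1),
               class = "nirshift_argument_error")
})

test_that("the kantorovich potential ascends its dual objective", {
  set.seed(41)
  A <- matrix(rnorm(16), 8, 2)
  B <- matrix(rnorm(16, 1.5), 8, 2)
  pot <- make_potential(2, width = 4)
  C <- nirshift:::pairwise_sqdist(A, B)
  st <- nirshift:::opt_init_net(pot$layers)
  cfg <- list(optimizer = "adam", learning_rate = 0.01, momentum = 0.9,
              weight_decay = 0)
  v0 <- nirshift:::potential_dual(A, B, C, pot)$value
  for (i in 1:150) {
    r <- nirshift:::potential_dual(A, B, C, pot)
    up <- nirshift:::opt_step_net(pot$layers, r$grads, st, cfg)
    pot$layers <- up$layers; st <- up$states
  }
  v1 <- nirshift:::potential_dual(A, B, C, pot)$value
  expect_gt(v1, v0)
  # weak duality: the dual value never exceeds the primal transport cost
  P <- sinkhorn_plan(C, 0.01, 1000)
  expect_lt(v1, sum(P * C) + 0.05)
})

test_that("all five transfer discrepancies vanish in the no-shift limit", {
  set.seed(42)
  G <- matrix(rnorm(40), 20, 2)
  f <- runif(20, 0.1, 0.9)
  tol <- c(dan = 1e-10, cdan = 5e-2, mdd = 1e-6, etd = 2e-2, glot = 2e-2)
  for (m in names(tol)) {
    d <- transfer_discrepancy(m, G, G, f, f, inner_steps = 150)
    expect_gte(d, 0)
    expect_lt(d, tol[[m]])
  }
})

test_that("transfer discrepancies detect a genuine domain shift", {
  set.seed(43)
  G <- matrix(rnorm(40), 20, 2)
  H <- G + 2
  f <- runif(20, 0.1, 0.9)
  for (m in c("dan", "cdan", "etd", "glot")) {
    expect_gt(transfer_discrepancy(m, G, H, f, f, inner_steps = 150), 0.3)
  }
})
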