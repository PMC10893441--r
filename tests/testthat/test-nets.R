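test_that("dense_forward matches hand-computed layer arithmetic", {
  id <- structure(list(W = diag(2), b = c(0, 0), activation = "identity"),
                  class = "dense_layer")
  expect_equal(dense_forward(c(3, -1), id), c(3, -1))

  sig <- structure(list(W = matrix(0, 1, 1), b = 0, activation = "sigmoid"),
                   class = "dense_layer")
  expect_equal(dense_forward(0, sig), 0.5)

  relu <- structure(list(W = matrix(c(1, 0, 1, 1), 2, 2), b = c(0, 1),
                         activation = "relu"), class = "dense_layer")
  # W y + b = [1*1 + 1*2, 0*1 + 1*2 + 1] = [3, 3]
  expect_equal(dense_forward(c(1, 2), relu), c(3, 3))

  expect_error(dense_forward(c(1, 2, 3), relu), class = "nirshift_argument_error")
})

test_that("forward_domain is deterministic in eval mode and routes by domain", {
  set.seed(20)
  bb <- build_backbone(6, 4, width_private = 3, width_shared = 2,
                       dropout_rate = 0.5)
  Xs <- matrix(rnorm(12), 2, 6)
  a <- forward_domain(bb, Xs, "source", "eval")
  b <- forward_domain(bb, Xs, "source", "eval")
  expect_identical(a$f, b$f)
  expect_identical(a$g, b$g)
  expect_true(all(a$f > 0 & a$f < 1))

  expect_error(forward_domain(bb, Xs, "target", "eval"),
               class = "nirshift_argument_error")

  bb0 <- build_backbone(6, 4, width_private = 3, width_shared = 2,
                        dropout_rate = 0)
  tr <- forward_domain(bb0, Xs, "source", "train")
  ev <- forward_domain(bb0, Xs, "source", "eval")
  expect_equal(tr$f, ev$f, tolerance = 1e-14)
})

test_that("eval predictions match an independent straight-line recomputation", {
  set.seed(21)
  bb <- build_backbone(5, 5, width_private = 4, width_shared = 3, dropout_rate = 0)
  x <- matrix(rnorm(10), 2, 5)
  got <- forward_domain(bb, x, "source", "eval")
  # independent composition of the per-layer formula
  sig <- function(z) 1 / (1 + exp(-z))
  manual <- t(apply(x, 1, function(row) {
    h1 <- pmax(bb$private_source$W %*% row + bb$private_source$b, 0)
    h2 <- pmax(bb$shared$W %*% h1 + bb$shared$b, 0)
    sig(bb$head$W %*% h2 + bb$head$b)
  }))
  expect_lt(max(abs(got$f - drop(manual))), 1e-10)
})

test_that("with identity activations and no dropout the backbone is affine", {
  set.seed(22)
  bb <- build_backbone(4, 4, width_private = 3, width_shared = 2, dropout_rate = 0)
  bb$private_source$activation <- "identity"
  bb$shared$activation <- "identity"
  bb$head$activation <- "identity"
  x1 <- matrix(rnorm(4), 1); x2 <- matrix(rnorm(4), 1)
  f <- function(x) forward_domain(bb, x, "source", "eval")$f
  lhs <- f(0.3 * x1 + 0.7 * x2)
  rhs <- 0.3 * f(x1) + 0.7 * f(x2)
  # affine map: superposition holds for convex weights (intercept cancels)
  expect_lt(abs(lhs - rhs), 1e-10)
})

test_that("mse_loss computes the mean of squared differences", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  expect_equal(mse_loss(c(0.2, 0.8), c(0, 1)), 0.04)
  expect_error(mse_loss(numeric(0), numeric(0)), class = "nirshift_argument_error")
})

test_that("label scaling maps the range onto [0.05, 0.95] and inverts exactly", {
  labels <- c(30, 75, 120)
  sc <- label_scaler(labels)
  scaled <- scale_labels(labels, sc)
  expect_equal(scaled[c(1, 3)], c(0.05, 0.95))
  expect_equal(scaled[2], 0.5)
  set.seed(23)
  y <- runif(50, 30, 120)
  expect_lt(max(abs(unscale_predictions(scale_labels(y, sc), sc) - y)), 1e-12)
  expect_error(label_scaler(c(5, 5)), class = "nirshift_argument_error")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(24)
  # a 5-parameter toy: one hidden unit on two inputs, sigmoid head
  bb <- build_backbone(2, 2, width_private = 1, width_shared = 1, dropout_rate = 0)
  X <- matrix(rnorm(6), 3, 2)
  y <- runif(3, 0.2, 0.8)
  loss_of <- function(bb) {
    f <- forward_domain(bb, X, "source", "eval")$f
    mse_loss(f, y)
  }
  fwd <- forward_domain(bb, X, "source", "eval")
  bwd <- nirshift:::backbone_bwd(bb, fwd, 2 * (fwd$f - y) / 3)
  params <- list(
    list(get = function(b) b$private_source$W,
         set = function(b, v) { b$private_source$W[] <- v; b },
         grad = bwd$private$dW),
    list(get = function(b) b$shared$W,
         set = function(b, v) { b$shared$W[] <- v; b },
         grad = bwd$shared$dW),
    list(get = function(b) b$head$W,
         set = function(b, v) { b$head$W[] <- v; b },
         grad = bwd$head$dW),
    list(get = function(b) b$head$b,
         set = function(b, v) { b$head$b[] <- v; b },
         grad = bwd$head$db))
  eps <- 1e-6
  for (p in params) {
    v <- p$get(bb)
    for (i in seq_along(v)) {
      vp <- v; vp[i] <- v[i] + eps
      vm <- v; vm[i] <- v[i] - eps
      num <- (loss_of(p$set(bb, vp)) - loss_of(p$set(bb, vm))) / (2 * eps)
      expect_lt(abs(p$grad[i] - num) / max(abs(num), 1e-8), 1e-4)
    }
  }
})

test_that("both optimizers reduce a convex quadratic", {
  set.seed(25)
  target <- matrix(c(1, -2, 0.5, 3), 2, 2)
  for (opt in c("adam", "rmsprop")) {
    layer <- dense_layer(2, 2, "identity")
    st <- nirshift:::opt_init(layer)
    cfg <- list(optimizer = opt, learning_rate = 0.05, momentum = 0.9,
                weight_decay = 0)
    for (i in 1:200) {
      grad <- list(dW = layer$W - target, db = layer$b)
      r <- nirshift:::opt_step_layer(layer, grad, st, cfg)
      layer <- r$layer; st <- r$state
    }
    expect_lt(max(abs(layer$W - target)), 0.05)
  }
})

test_that("backbone weights round trip through the YAML serialization", {
  set.seed(26)
  bb <- build_backbone(6, 4, width_private = 3, width_shared = 2)
  bb$label_scaler <- label_scaler(c(30, 120))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_backbone(bb, path)
  back <- read_backbone(path)
  expect_lt(max(abs(back$private_source$W - bb$private_source$W)), 1e-12)
  expect_lt(max(abs(back$head$W - bb$head$W)), 1e-12)
  expect_equal(back$label_scaler$min, 30)
  x <- matrix(rnorm(6), 1, 6)
  expect_equal(forward_domain(back, x, "source", "eval")$f,
               forward_domain(bb, x, "source", "eval")$f, tolerance = 1e-12)
})
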