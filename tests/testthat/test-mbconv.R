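test_that("softmax output is a valid distribution for arbitrary weights", {
  cfg <- tiny_model_config()
  set.seed(2)
  w <- init_weights(cfg, "xavier_normal", seed = 21)
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  p <- model_forward(w, cfg, x)$probs
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # all-zero weights: exactly uniform probabilities
  w0 <- lapply(w, function(a) a * 0)
  class(w0) <- "model_weights"
  p0 <- model_forward(w0, cfg, x)$probs
  expect_equal(as.vector(p0), rep(0.5, 10))
  expect_error(model_forward(w, cfg, array(0, c(6, 6, 2))), "input size")
})

test_that("depthwise convolution matches direct convolution oracles", {
  g <- asNamespace("glioscope")
  x <- array(0, c(5, 5, 1, 2))
  set.seed(4)
  x[, , 1, 1] <- matrix(rnorm(25), 5)
  x[, , 1, 2] <- 3 # constant image
  # delta kernel -> identity
  Wd <- array(0, c(3, 3, 2)); Wd[2, 2, ] <- 1
  y <- g$dw_fwd(x, Wd, c(0, 0), 1)$y
  expect_equal(y, x)
  # all-ones kernel on a constant image: 9v interior, smaller on the border
  W1 <- array(1, c(3, 3, 2))
  y1 <- g$dw_fwd(x, W1, c(0, 0), 1)$y
  expect_equal(y1[3, 3, 1, 2], 27) # 9 * 3 interior
  expect_equal(y1[1, 1, 1, 2], 12) # 4 taps at the corner (zero padding)
  expect_equal(y1[1, 3, 1, 2], 18) # 6 taps on an edge
  # bias-only (zero kernel) gives the constant bias
  yb <- g$dw_fwd(x, array(0, c(3, 3, 2)), c(0.7, -0.2), 1)$y
  expect_equal(unique(as.vector(yb[, , 1, 1])), 0.7)
})

test_that("expansion and squeeze-excitation follow their defining algebra", {
  g <- asNamespace("glioscope")
  set.seed(6)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  # identity 1x1 expansion (pre-activation)
  y <- g$pw_fwd(x, diag(2), c(0, 0))$y
  expect_equal(y, x)
  # zero input, bias c -> constant map c per channel
  yc <- g$pw_fwd(x * 0, matrix(rnorm(6), 2, 3), c(1, 2, 3))$y
  expect_equal(as.vector(yc[1, 1, 1, ]), c(1, 2, 3))
  # SE with W2 = 0, b2 = 0 gates at sigmoid(0) = 0.5
  se <- g$se_fwd(x, matrix(rnorm(2), 2, 1), 0, matrix(0, 1, 2), c(0, 0))
  expect_equal(se$y, 0.5 * x)
  # saturated gate is the identity
  se1 <- g$se_fwd(x, matrix(0, 2, 1), 0, matrix(0, 1, 2), c(50, 50))
  expect_equal(se1$y, x, tolerance = 1e-12)
  # hand-computed scalar gate on a single-channel 2x2 map
  xs <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  sq <- 2.5
  gate <- 1 / (1 + exp(-(0.5 * max(0.8 * sq + 0.1, 0) - 0.3)))
  se2 <- g$se_fwd(xs, matrix(0.8), 0.1, matrix(0.5), -0.3)
  expect_equal(se2$y, xs * gate, tolerance = 1e-12)
})

test_that("projection and residual addition obey the skip rules", {
  g <- asNamespace("glioscope")
  set.seed(8)
  x <- array(rnorm(4 * 4 * 3 * 1), c(4, 4, 1, 3))
  xp <- g$pw_fwd(x, matrix(0, 3, 3), numeric(3))$y
  expect_equal(xp + x, x)     # zero projection: skip passes input through
  expect_equal(x * 0 + xp, xp)
  # stride-2 block skips the residual entirely
  cfg <- model_config(input_size = 8, stem_filters = 2, stem_stride = 1,
                      blocks = list(list(e = 2, k = 3, stride = 2, out = 2,
                                         se = 2)))
  plan <- g$model_plan(cfg)
  expect_false(plan$b1$residual)
  cfg2 <- model_config(input_size = 8, stem_filters = 2, stem_stride = 1,
                       blocks = list(list(e = 2, k = 3, stride = 1, out = 2,
                                          se = 2)))
  expect_true(g$model_plan(cfg2)$b1$residual)
})

test_that("hand-built one-block instance matches scalar arithmetic to 1e-10", {
  # 1x1 input through stem (k=3, only the center tap touches the pixel),
  # one MBConv block with k=1 depthwise, SE, residual, then the classifier:
  # every operation reduces to scalar arithmetic computed independently.
  cfg <- model_config(input_size = 1, stem_filters = 1, stem_stride = 1,
                      blocks = list(list(e = 2, k = 1, stride = 1, out = 1,
                                         se = 2)),
                      classes = 2)
  w <- init_weights(cfg, "xavier_normal", 1)
  w$stem.W <- array(0, c(3, 3, 1, 1)); w$stem.W[2, 2, 1, 1] <- 0.9
  w$stem.b <- 0.1
  w$b1.exp.W <- matrix(c(1.2, -0.7), 1, 2); w$b1.exp.b <- c(0.05, 0.3)
  w$b1.dw.W <- array(c(0.6, 1.1), c(1, 1, 2)); w$b1.dw.b <- c(-0.1, 0.2)
  w$b1.se.W1 <- matrix(c(0.4, -0.5), 2, 1); w$b1.se.b1 <- 0.15
  w$b1.se.W2 <- matrix(c(0.7, 0.9), 1, 2); w$b1.se.b2 <- c(0.1, -0.2)
  w$b1.proj.W <- matrix(c(0.8, -0.3), 2, 1); w$b1.proj.b <- 0.05
  w$head.W <- matrix(c(1.5, -0.4), 1, 2); w$head.b <- c(0.2, -0.1)

  a <- 0.8
  p <- model_forward(w, cfg, matrix(a, 1, 1))$probs

  sig <- function(z) 1 / (1 + exp(-z))
  z <- max(0.9 * a + 0.1, 0)
  e1 <- max(1.2 * z + 0.05, 0); e2 <- max(-0.7 * z + 0.3, 0)
  d1 <- max(0.6 * e1 - 0.1, 0); d2 <- max(1.1 * e2 + 0.2, 0)
  h <- max(0.4 * d1 - 0.5 * d2 + 0.15, 0)
  g1 <- sig(0.7 * h + 0.1); g2 <- sig(0.9 * h - 0.2)
  pr <- 0.8 * d1 * g1 - 0.3 * d2 * g2 + 0.05
  feat <- pr + z
  l1 <- 1.5 * feat + 0.2; l2 <- -0.4 * feat - 0.1
  expected <- exp(c(l1, l2)) / sum(exp(c(l1, l2)))
  expect_equal(as.vector(p), expected, tolerance = 1e-10)
})

test_that("loss_acc matches its closed forms and is clamped", {
  expect_equal(loss_acc(matrix(c(1, 0), 2, 1), 0), 0)
  expect_equal(loss_acc(matrix(0.5, 2, 4), c(0, 1, 0, 1)), log(2))
  p <- matrix(c(1, 0, exp(-2), 1 - exp(-2)), 2)
  expect_equal(loss_acc(p, c(0, 0)), 1)
  # zero probability at the true class stays finite via the clamp
  expect_true(is.finite(loss_acc(matrix(c(0, 1), 2, 1), 0)))
  # one-hot matrix labels agree with integer labels
  expect_equal(loss_acc(p, matrix(c(1, 0, 1, 0), 2)), loss_acc(p, c(0, 0)))
})

test_that("resource proxies count parameters exactly and ignore weights", {
  g <- asNamespace("glioscope")
  # direct hand count for the desk-scale default
  cfg <- model_config()
  rc <- resource_cost(cfg)
  hand_params <- function(cfg) {
    pl <- g$model_plan(cfg)
    tot <- pl$stem$k^2 * pl$stem$cin * pl$stem$cout + pl$stem$cout
    for (nm in grep("^b[0-9]+$", names(pl), value = TRUE)) {
      p <- pl[[nm]]
      tot <- tot + p$cin * p$ec + p$ec + p$k^2 * p$ec + p$ec +
        p$ec * p$cse + p$cse + p$cse * p$ec + p$ec + p$ec * p$cout + p$cout
    }
    tot + pl$head$cin * pl$head$cout + pl$head$cout
  }
  expect_equal(rc$params, hand_params(cfg))
  # counting the actual weight arrays agrees
  w <- init_weights(cfg, "he_normal", 2)
  expect_equal(rc$params, sum(vapply(w, length, integer(1))))
  expect_equal(rc$c_size, rc$params / 1e6)
  # invariant to weight values / init seed
  expect_identical(resource_cost(cfg), resource_cost(cfg))
})

test_that("composite loss reproduces the published arithmetic", {
  cost <- structure(list(c_size = 4, c_latency = 10, params = 4e6,
                         macs = 1e7), class = "resource_cost")
  # L_CE + l1 * latency + l2 * size with the selected coefficients
  expect_equal(loss_total(0.5, cost, 8.7e-3, 4.2e-4), 0.58868)
  expect_equal(loss_eff(cost, 8.7e-3, 4.2e-4), 8.7e-3 * 4 + 4.2e-4 * 10)
  empty <- structure(list(c_size = 0, c_latency = 0), class = "resource_cost")
  expect_equal(loss_eff(empty, 1e-2, 1e-3), 0)
  expect_error(loss_total(0.5, cost, -1, 0), "non-negative")
})

test_that("analytic gradients match central differences to 1e-4", {
  cfg <- tiny_model_config()
  w <- jittered_weights(cfg)
  set.seed(31)
  xb <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  yb <- c(0, 1, 1)
  lossfn <- function(wts) loss_acc(model_forward(wts, cfg, xb)$probs, yb)
  fw <- model_forward(w, cfg, xb)
  dlog <- (fw$probs - glioscope:::one_hot(yb, 2)) / 3
  gr <- model_backward(w, cfg, fw$cache, dlog)
  eps <- 1e-5
  for (nm in names(w)) {
    idx <- seq_len(min(length(w[[nm]]), 10L))
    num <- vapply(idx, function(i) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      (lossfn(wp) - lossfn(wm)) / (2 * eps)
    }, numeric(1))
    ana <- as.vector(gr[[nm]])[idx]
    rel <- abs(num - ana) / pmax(1e-6, abs(num) + abs(ana))
    expect_lt(max(rel), 1e-4)
  }
})
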