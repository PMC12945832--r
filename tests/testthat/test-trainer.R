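test_that("init schemes have the published standard deviations", {
  cfg <- tiny_model_config()
  # stem: fan_in = 9, fan_out = 27; sample sd converges to the formula
  wx <- init_weights(model_config(stem_filters = 64L), "xavier_normal", 1)
  wh <- init_weights(model_config(stem_filters = 64L), "he_normal", 1)
  expect_equal(sd(wx$stem.W), sqrt(2 / (9 + 9 * 64)), tolerance = 0.15)
  expect_equal(sd(wh$stem.W), sqrt(2 / 9), tolerance = 0.15)
  expect_true(all(wx$stem.b == 0))
  # determinism per seed
  expect_identical(init_weights(cfg, "he_normal", 7),
                   init_weights(cfg, "he_normal", 7))
  expect_false(identical(init_weights(cfg, "he_normal", 7),
                         init_weights(cfg, "he_normal", 8)))
  expect_error(init_weights(cfg, "uniform_magic"), "arg")
})

test_that("sgd_momentum_step follows the classical recurrence", {
  s <- sgd_momentum_step(1, 0.5, 0, lr = 0.1, momentum = 0, weight_decay = 0)
  expect_equal(s$w, 0.95)
  s2 <- sgd_momentum_step(2, 0, 0, lr = 0.1, momentum = 0.9, weight_decay = 0)
  expect_equal(s2$w, 2)
  # two steps with constant gradient g, beta = 0.5, lr = 1: w2 = -2.5 g
  g <- 0.3
  a <- sgd_momentum_step(0, g, 0, lr = 1, momentum = 0.5)
  b <- sgd_momentum_step(a$w, g, a$velocity, lr = 1, momentum = 0.5)
  expect_equal(b$w, -2.5 * g)
  # weight decay folds into the gradient
  s3 <- sgd_momentum_step(10, 0, 0, lr = 0.1, momentum = 0, weight_decay = 0.01)
  expect_equal(s3$w, 10 - 0.1 * 0.1)
  expect_error(sgd_momentum_step(1, NaN, 0, 0.1), "non-finite")
})

test_that("dropout zeroes, rescales, and is the identity when disabled", {
  x <- array(1, c(10, 10))
  expect_identical(apply_dropout(x, 0, training = TRUE), x)
  expect_identical(apply_dropout(x, 0.5, training = FALSE), x)
  set.seed(12)
  y <- apply_dropout(rep(1, 1e5), 0.5, training = TRUE)
  expect_true(all(y %in% c(0, 2)))
  expect_equal(mean(y), 1, tolerance = 0.02)
})

test_that("degenerate training configurations leave weights untouched", {
  ds <- small_training_dataset()
  cfg <- tiny_model_config()
  cfg$input_size <- 32L
  t0 <- train_config(epochs = 0, seed = 3)
  m0 <- train_model(cfg, ds, t0)
  expect_equal(nrow(m0$report), 0L)
  expect_identical(m0$weights, init_weights(cfg, t0$init_scheme, t0$seed))
  tlr0 <- train_config(learning_rate = 0, epochs = 2, weight_decay = 0,
                       dropout = 0, seed = 3)
  mlr0 <- train_model(cfg, ds, tlr0)
  expect_equal(mlr0$weights, init_weights(cfg, tlr0$init_scheme, tlr0$seed),
               tolerance = 1e-14)
  expect_error(train_model(cfg, list(images = ds$images,
                                     manifest = transform(ds$manifest,
                                                          split = "test")),
                           t0),
               "empty training partition")
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- small_training_dataset()
  cfg <- tiny_model_config()
  cfg$input_size <- 32L
  tc <- desk_train_config(epochs = 2L, seed = 5L)
  m1 <- train_model(cfg, ds, tc)
  m2 <- train_model(cfg, ds, tc)
  expect_identical(m1$report, m2$report)
  expect_identical(m1$weights, m2$weights)
})

test_that("a separable two-class task is learned quickly", {
  # blob images whose class shifts the mean intensity: a logistic regression
  # on the mean pixel separates them perfectly, so the network must too
  set.seed(77)
  n <- 60
  img_sz <- 16L
  labels <- rep(0:1, n / 2)
  images <- array(rnorm(img_sz^2 * n, 0, 0.3), c(img_sz, img_sz, n))
  images <- images + rep(ifelse(labels == 1, 0.8, -0.8), each = img_sz^2)
  means <- apply(images, 3, mean)
  oracle <- glm(labels ~ means, family = binomial)
  expect_gte(mean((fitted(oracle) > 0.5) == labels), 0.95)
  man <- data.frame(patient_id = sprintf("B%03d", 1:n), label = labels,
                    split = rep(c("train", "val"), c(40, 20)))
  ds <- list(images = images, manifest = man)
  cfg <- model_config(input_size = img_sz, stem_filters = 4, stem_stride = 2,
                      blocks = list(list(e = 2, k = 3, stride = 2, out = 8,
                                         se = 2)))
  m <- train_model(cfg, ds, desk_train_config(epochs = 12L, seed = 2L))
  expect_gte(max(m$report$val_acc), 0.95)
})

test_that("training with an augmentation policy stays in contract", {
  ds <- small_training_dataset()
  cfg <- tiny_model_config()
  cfg$input_size <- 32L
  tc <- desk_train_config(epochs = 1L, seed = 5L,
                          augment = augment_policy(c("flip_h", "rotate")))
  m <- train_model(cfg, ds, tc)
  expect_equal(nrow(m$report), 1L)
  expect_true(is.finite(m$report$train_loss))
})
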