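test_that("metrics reproduce the canonical confusion-matrix cases", {
  perfect <- metrics(confusion_counts(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_true(all(unlist(perfect) == 1))
  inverted <- metrics(confusion_counts(tp = 0, tn = 0, fp = 10, fn = 10))
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$mcc, -1)
  chance <- metrics(confusion_counts(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)
  expect_error(metrics(confusion_counts(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("metrics equal independent brute-force arithmetic on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    cts <- as.list(rmultinom(1, sample(20:500, 1), rep(0.25, 4))[, 1])
    names(cts) <- c("tp", "tn", "fp", "fn")
    if (with(cts, tp + fn == 0 || tp + fp == 0 || tn + fp == 0 || tn + fn == 0))
      next
    got <- metrics(do.call(confusion_counts, cts))
    want <- do.call(brute_metrics, cts)
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  m <- metrics(confusion_counts(tp = 0, tn = 10, fp = 0, fn = 5))
  expect_true(is.nan(m$precision))
  expect_true("precision" %in% attr(m, "undefined"))
  expect_equal(m$specificity, 1)
})

test_that("MCC is symmetric under the class swap", {
  set.seed(55)
  for (i in 1:20) {
    v <- sample(1:50, 4, replace = TRUE)
    a <- metrics(confusion_counts(tp = v[1], tn = v[2], fp = v[3], fn = v[4]))
    b <- metrics(confusion_counts(tp = v[2], tn = v[1], fp = v[4], fn = v[3]))
    expect_equal(a$mcc, b$mcc, tolerance = 1e-12)
  }
})

test_that("confusion counts from label vectors match direct tallies", {
  pred <- c(1, 1, 0, 0, 1, 0)
  truth <- c(1, 0, 0, 1, 1, 0)
  cc <- confusion_counts(pred = pred, truth = truth, positive = 1)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 2, fp = 1, fn = 1))
})

test_that("stratified split reproduces the published partition sizes", {
  ids <- sprintf("P%04d", 1:533)
  labels <- rep(0:1, length.out = 533)
  s <- stratified_split(ids, labels, seed = 3)
  tab <- table(s$split)
  expect_equal(as.vector(tab[c("train", "val", "test")]), c(426L, 54L, 53L))
  # partition is disjoint and exhaustive at patient level
  expect_equal(sort(s$patient_id), sort(ids))
  # stratified: class shares within each subset near the global share
  for (sp in c("train", "val", "test")) {
    share <- mean(s$label[s$split == sp] == 1)
    expect_lt(abs(share - 0.5), 0.02)
  }
  s100 <- stratified_split(sprintf("Q%03d", 1:100), rep(0:1, 50), seed = 1)
  expect_equal(as.vector(table(s100$split)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  s10 <- stratified_split(sprintf("R%02d", 1:10), rep(0:1, 5), seed = 1)
  expect_equal(as.vector(table(s10$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
})

test_that("stratified split warns and falls back for tiny classes", {
  ids <- sprintf("T%02d", 1:20)
  labels <- c(rep(0, 18), 1, 1)
  expect_warning(s <- stratified_split(ids, labels, seed = 2),
                 "fewer than 3")
  expect_equal(sort(s$patient_id), sort(ids))
  expect_error(stratified_split(c("a", "a"), c(0, 1)), "unique")
})

test_that("splits and folds are deterministic and exhaustive over random inputs", {
  set.seed(202)
  for (i in 1:15) {
    n <- sample(30:200, 1)
    ids <- sprintf("X%04d", seq_len(n))
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (min(table(labels)) < 10) next
    s1 <- stratified_split(ids, labels, seed = i)
    s2 <- stratified_split(ids, labels, seed = i)
    expect_identical(s1, s2)
    expect_setequal(s1$patient_id, ids)
    expect_true(all(table(s1$patient_id) == 1))
    k <- sample(2:10, 1)
    f1 <- kfold(ids, labels, k = k, seed = i)
    f2 <- kfold(ids, labels, k = k, seed = i)
    expect_identical(f1, f2)
    sizes <- table(f1$fold)
    expect_lte(max(sizes) - min(sizes), 1)
    # per-class fold counts also near-equal
    for (cl in 0:1) {
      cs <- table(factor(f1$fold[f1$label == cl], levels = 1:k))
      expect_lte(max(cs) - min(cs), 1)
    }
  }
})

test_that("kfold covers the published cohort arithmetic", {
  ids <- sprintf("P%04d", 1:533)
  labels <- rep(0:1, length.out = 533)
  f <- kfold(ids, labels, k = 10, seed = 1)
  sizes <- as.vector(table(f$fold))
  expect_setequal(unique(sizes), c(53L, 54L))
  expect_equal(sum(sizes == 54L), 3L) # 533 = 7*53 + 3*54
  f100 <- kfold(sprintf("A%03d", 1:100), rep(0:1, 50), k = 10, seed = 1)
  expect_true(all(table(f100$fold) == 10))
  expect_error(kfold(c("a", "b"), c(0, 1), k = 5), "exceed")
})

test_that("evaluate applies argmax, accumulates counts, and guards leakage", {
  ds <- small_training_dataset()
  cfg <- tiny_model_config()
  cfg$input_size <- 32L
  m <- train_model(cfg, ds, desk_train_config(epochs = 1L, seed = 2L))
  ev <- evaluate(m, ds, split = "test")
  cts <- ev$counts
  expect_equal(cts$tp + cts$tn + cts$fp + cts$fn,
               sum(ds$manifest$split == "test"))
  expect_equal(ev$metrics$accuracy,
               (cts$tp + cts$tn) / sum(unlist(cts[c("tp", "tn", "fp", "fn")])))
  # evaluating a partition seen in training is a hard error
  expect_error(evaluate(m, ds, split = "train"), "leakage")
  expect_error(evaluate(m, ds, split = "nope"), "no samples")
})
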