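#' Confusion counts for a binary classifier
#'
#' @param tp,tn,fp,fn Non-negative integer counts, or leave them missing and
#'   supply `pred`/`truth` label vectors plus the `positive` label.
#' @param pred,truth Optional predicted and true label vectors.
#' @param positive The label counted as positive (default `1`).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                             pred = NULL, truth = NULL, positive = 1) {
  if (!is.null(pred)) {
    if (length(pred) != length(truth))
      stop("confusion_counts: pred and truth must have equal length")
    p <- pred == positive
    t <- truth == positive
    tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion_counts: counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_counts")
}

#' Confusion-matrix metric suite
#'
#' Computes sensitivity (recall), precision, specificity, F1, accuracy and
#' the Matthews correlation coefficient from binary confusion counts. A
#' metric whose denominator is zero is returned as `NaN` and its name is
#' recorded in the `undefined` attribute rather than being silently coerced
#' to 0. Note the MCC uses the standard numerator `TP*TN - FP*FN`.
#'
#' @param counts A [confusion_counts()].
#' @return An object of class `metric_report`: named list with fields
#'   `sensitivity`, `precision`, `specificity`, `f1`, `accuracy`, `mcc`.
#' @examples
#' metrics(confusion_counts(tp = 10, tn = 10, fp = 0, fn = 0))
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("metrics: empty confusion counts")
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  sens <- safe_div(tp, tp + fn)
  prec <- safe_div(tp, tp + fp)
  spec <- safe_div(tn, tn + fp)
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN else
    2 * prec * sens / (prec + sens)
  acc <- (tp + tn) / total
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NaN else (tp * tn - fp * fn) / mcc_den
  rep <- list(sensitivity = sens, precision = prec, specificity = spec,
              f1 = f1, accuracy = acc, mcc = mcc)
  undefined <- names(rep)[vapply(rep, is.nan, logical(1))]
  structure(rep, class = "metric_report", undefined = undefined,
            counts = counts)
}

#' @export
print.metric_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("  %-12s %.4f\n", nm, x[[nm]]))
  und <- attr(x, "undefined")
  if (length(und)) cat("  undefined (zero denominator):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

# Largest-remainder allocation of `total` across classes with real-valued
# targets; guarantees sum(result) == total and result <= cap componentwise.
largest_remainder <- function(targets, total, cap) {
  base <- pmin(floor(targets), cap)
  leftover <- total - sum(base)
  frac <- targets - floor(targets)
  ord <- order(frac, decreasing = TRUE)
  i <- 1L
  while (leftover > 0L && i <= 2L * length(base)) {
    j <- ord[((i - 1L) %% length(base)) + 1L]
    if (base[j] < cap[j]) {
      base[j] <- base[j] + 1L
      leftover <- leftover - 1L
    }
    i <- i + 1L
  }
  base
}

#' Patient-level stratified train/validation/test split
#'
#' Assigns every patient to exactly one of train/val/test, stratified by
#' label. The global sizes follow the rule: train = `floor(f_train * n)`;
#' of the remainder, validation takes the ceiling of its proportional share
#' and test the rest — for 533 patients at (0.8, 0.1, 0.1) this reproduces
#' the 426/54/53 partition. Per-label allocations match the global totals by
#' largest-remainder rounding.
#'
#' @param patient_ids Vector of unique patient identifiers.
#' @param labels Class label per patient.
#' @param fractions Numeric length-3 vector summing to 1 (train, val, test).
#' @param seed Integer seed for the within-class shuffles.
#' @return A `split_assignment` data frame with columns `patient_id`,
#'   `label`, `split`.
#' @examples
#' s <- stratified_split(sprintf("P%03d", 1:100), rep(0:1, 50), seed = 1)
#' table(s$split)
#' @export
stratified_split <- function(patient_ids, labels,
                             fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (anyDuplicated(patient_ids))
    stop("stratified_split: patient_ids must be unique")
  if (length(patient_ids) != length(labels))
    stop("stratified_split: patient_ids and labels must have equal length")
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop("stratified_split: fractions must be three values summing to 1")
  n <- length(patient_ids)
  n_train <- floor(fractions[1] * n)
  rem <- n - n_train
  n_val <- ceiling(rem * fractions[2] / (fractions[2] + fractions[3]))
  n_test <- rem - n_val

  set.seed(seed)
  split <- character(n)
  cls <- split(seq_len(n), as.character(labels))
  n_c <- lengths(cls)
  if (any(n_c < 3L)) {
    warning("stratified_split: a class has fewer than 3 patients; ",
            "falling back to global (unstratified) rounding")
    idx <- sample.int(n)
    split[idx[seq_len(n_train)]] <- "train"
    split[idx[n_train + seq_len(n_val)]] <- "val"
    split[idx[n_train + n_val + seq_len(n_test)]] <- "test"
  } else {
    tr_c <- largest_remainder(fractions[1] * n_c, n_train, n_c)
    rem_c <- n_c - tr_c
    va_c <- largest_remainder(rem_c * fractions[2] / (fractions[2] + fractions[3]),
                              n_val, rem_c)
    te_c <- rem_c - va_c
    for (k in seq_along(cls)) {
      idx <- cls[[k]][sample.int(length(cls[[k]]))]
      split[idx[seq_len(tr_c[k])]] <- "train"
      split[idx[tr_c[k] + seq_len(va_c[k])]] <- "val"
      split[idx[tr_c[k] + va_c[k] + seq_len(te_c[k])]] <- "test"
    }
  }
  out <- data.frame(patient_id = patient_ids, label = labels, split = split,
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Stratified k-fold assignment at patient level
#'
#' Shuffles patients within each class, concatenates the classes, and deals
#' fold indices cyclically: overall fold sizes differ by at most 1 and so do
#' per-class fold counts.
#'
#' @inheritParams stratified_split
#' @param k Number of folds (default 10).
#' @return A `split_assignment` data frame with columns `patient_id`,
#'   `label`, `fold`.
#' @export
kfold <- function(patient_ids, labels, k = 10L, seed = 1L) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("kfold: patient_ids must be unique")
  if (k > n) stop("kfold: k must not exceed the number of patients")
  set.seed(seed)
  cls <- split(seq_len(n), as.character(labels))
  if (k > min(lengths(cls)))
    warning("kfold: k exceeds the size of the smallest class; ",
            "some folds will miss that class")
  order_all <- unlist(lapply(cls, function(ix) ix[sample.int(length(ix))]),
                      use.names = FALSE)
  fold <- integer(n)
  fold[order_all] <- rep_len(seq_len(k), n)
  out <- data.frame(patient_id = patient_ids, label = labels, fold = fold,
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Evaluate a trained model on a held-out partition
#'
#' Predicts by per-image argmax, accumulates binary confusion counts and
#' returns the metric report. The model carries the patient ids it was
#' trained on; any overlap with the requested partition is a hard leakage
#' error, not a warning.
#'
#' @param model A `glioscope_model` from [train_model()].
#' @param data A phantom dataset (see [make_dataset()]) whose manifest has a
#'   `split` column, or any list with `images`, `manifest`.
#' @param split Which manifest partition to evaluate (default `"test"`).
#' @return List with `metrics` (a `metric_report`), `counts`, `predictions`.
#' @export
evaluate <- function(model, data, split = "test") {
  stopifnot(inherits(model, "glioscope_model"))
  sel <- which(data$manifest$split == split)
  if (!length(sel)) stop("evaluate: no samples in partition '", split, "'")
  ids <- data$manifest$patient_id[sel]
  leaked <- intersect(ids, model$train_patient_ids)
  if (length(leaked))
    stop("evaluate: data leakage - ", length(leaked),
         " patient(s) in the evaluation partition were used for training ",
         "(e.g. ", leaked[1], ")")
  probs <- predict_model(model, subset_images(data$images, sel))
  pred <- max.col(t(probs)) - 1L
  truth <- data$manifest$label[sel]
  counts <- confusion_counts(pred = pred, truth = truth, positive = 1)
  list(metrics = metrics(counts), counts = counts, predictions = pred)
}
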