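#' Training configuration
#'
#' SGD with classical momentum and L2 weight decay folded into the gradient,
#' exponential learning-rate decay applied once per epoch, inverted dropout
#' on the pooled feature vector, and Xavier/He initialization. No early
#' stopping: exactly `epochs` epochs run. The defaults are the selected
#' full-scale configuration (learning rate 0.0016, batch 256, 60 epochs,
#' weight decay 3e-4, momentum 0.92, dropout 0.25, Xavier normal); see
#' [desk_train_config()] for the fast desk-scale defaults used in tests.
#'
#' @param learning_rate Positive step size.
#' @param batch_size Positive integer; the final short batch is kept.
#' @param epochs Non-negative integer.
#' @param weight_decay Non-negative L2 coefficient (applied to weights, not
#'   biases).
#' @param momentum Momentum coefficient in \[0, 1).
#' @param dropout Dropout probability in \[0, 1).
#' @param init_scheme `"xavier_normal"` or `"he_normal"`.
#' @param lr_decay Per-epoch multiplicative decay factor (default 0.97).
#' @param warmup_epochs Linear learning-rate warmup over this many initial
#'   epochs (default 0, i.e. none). Protects the batch-norm-free network
#'   from early dead-unit lock-in at desk-scale rates.
#' @param clip_norm Global gradient-norm clip applied per step (default 5;
#'   `Inf` disables). Stabilizes the batch-norm-free network at the higher
#'   desk-scale learning rates.
#' @param lsuv_init If `TRUE`, rescale each convolution's weights after
#'   Xavier/He initialization so its output standard deviation is ~1 on a
#'   probe batch of training images (layer-sequential unit variance).
#'   Deterministic given the seed; compensates for the activation shrinkage
#'   of the batch-norm-free SE blocks. Off by default, on in
#'   [desk_train_config()].
#' @param restart_patience If positive, re-initialize from a derived seed
#'   when the training loss is still at the chance plateau
#'   (`> restart_loss`) after this many epochs; at most `max_restarts`
#'   re-initializations. Deterministic. Default 0 (off).
#' @param restart_loss Chance-plateau threshold for the restart rule
#'   (default 0.67, just under log 2).
#' @param max_restarts Maximum number of plateau restarts (default 2).
#' @param augment Optional [augment_policy()] applied to training images
#'   only.
#' @param seed Integer seed recorded in every artifact.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.0016, batch_size = 256L,
                         epochs = 60L, weight_decay = 3e-4,
                         momentum = 0.92, dropout = 0.25,
                         init_scheme = c("xavier_normal", "he_normal"),
                         lr_decay = 0.97, warmup_epochs = 0L, clip_norm = 5,
                         lsuv_init = FALSE, restart_patience = 0L,
                         restart_loss = 0.67, max_restarts = 2L,
                         augment = NULL, seed = 1L) {
  init_scheme <- match.arg(init_scheme)
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 0,
            weight_decay >= 0, momentum >= 0, momentum < 1,
            dropout >= 0, dropout < 1, lr_decay > 0, clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 momentum = momentum, dropout = dropout,
                 init_scheme = init_scheme, lr_decay = lr_decay,
                 warmup_epochs = as.integer(warmup_epochs),
                 clip_norm = clip_norm, lsuv_init = isTRUE(lsuv_init),
                 restart_patience = as.integer(restart_patience),
                 restart_loss = restart_loss,
                 max_restarts = as.integer(max_restarts),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training defaults
#'
#' A configuration sized for single-CPU minutes on the 32x32 phantom task:
#' higher learning rate and smaller batches than the full-scale defaults so
#' the small network converges in a handful of epochs.
#'
#' @param epochs Number of epochs (default 16).
#' @param seed Integer seed.
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(epochs = 10L, seed = 1L, ...) {
  train_config(learning_rate = 0.02, batch_size = 16L, epochs = epochs,
               weight_decay = 1e-4, momentum = 0.9, dropout = 0.1,
               init_scheme = "he_normal", lr_decay = 0.95, warmup_epochs = 2L,
               lsuv_init = TRUE, restart_patience = 5L, seed = seed, ...)
}

# Layer-sequential unit-variance rescaling: walk the network once on a probe
# batch, dividing each convolution's weights by its output standard
# deviation so every stage starts with O(1) activations. Biases are zero at
# init and stay untouched; the SE gate weights are left alone (the gate is
# bounded).
lsuv_rescale <- function(weights, cfg, xprobe, target = 1, floor_sd = 1e-3) {
  x <- as_input_batch(xprobe)
  plan <- model_plan(cfg)
  rescale <- function(W, y) {
    s <- stats::sd(y)
    if (!is.finite(s) || s < floor_sd) s <- floor_sd
    list(W = W / (s / target), y = y / (s / target))
  }
  st <- conv2d_fwd(x, weights$stem.W, weights$stem.b, cfg$stem_stride)
  r <- rescale(weights$stem.W, st$y)
  weights$stem.W <- r$W
  z <- r$y * (r$y > 0)
  for (nm in grep("^b[0-9]+$", names(plan), value = TRUE)) {
    p <- plan[[nm]]
    ex <- pw_fwd(z, weights[[paste0(nm, ".exp.W")]],
                 weights[[paste0(nm, ".exp.b")]])
    r <- rescale(weights[[paste0(nm, ".exp.W")]], ex$y)
    weights[[paste0(nm, ".exp.W")]] <- r$W
    a <- r$y * (r$y > 0)
    dw <- dw_fwd(a, weights[[paste0(nm, ".dw.W")]],
                 weights[[paste0(nm, ".dw.b")]], p$stride)
    r <- rescale(weights[[paste0(nm, ".dw.W")]], dw$y)
    weights[[paste0(nm, ".dw.W")]] <- r$W
    a <- r$y * (r$y > 0)
    se <- se_fwd(a, weights[[paste0(nm, ".se.W1")]],
                 weights[[paste0(nm, ".se.b1")]],
                 weights[[paste0(nm, ".se.W2")]],
                 weights[[paste0(nm, ".se.b2")]])
    pr <- pw_fwd(se$y, weights[[paste0(nm, ".proj.W")]],
                 weights[[paste0(nm, ".proj.b")]])
    r <- rescale(weights[[paste0(nm, ".proj.W")]], pr$y)
    weights[[paste0(nm, ".proj.W")]] <- r$W
    z <- if (p$residual) r$y + z else r$y
  }
  weights
}

#' One SGD-with-momentum step
#'
#' Classical momentum with L2 decay folded into the gradient:
#' `v' = momentum * v - lr * (grad + wd * w)`, `w' = w + v'`.
#'
#' @param w,grad,velocity Conformable numeric arrays.
#' @param lr,momentum,weight_decay Scalars.
#' @return List with updated `w` and `velocity`.
#' @export
sgd_momentum_step <- function(w, grad, velocity, lr, momentum = 0,
                              weight_decay = 0) {
  if (any(!is.finite(grad)))
    stop("sgd_momentum_step: non-finite gradient encountered")
  v <- momentum * velocity - lr * (grad + weight_decay * w)
  list(w = w + v, velocity = v)
}

#' Inverted dropout on an activation array
#'
#' During training each unit is zeroed with probability `p` and survivors
#' are scaled by `1/(1-p)` so the expected activation is unchanged; at
#' inference the input is returned untouched.
#'
#' @param activations Numeric array.
#' @param p Dropout probability in \[0, 1).
#' @param training Logical.
#' @return Array of the same shape.
#' @export
apply_dropout <- function(activations, p, training = TRUE) {
  stopifnot(p >= 0, p < 1)
  if (!training || p == 0) return(activations)
  keep <- array(stats::runif(length(activations)) >= p, dim(activations) %||%
                  length(activations))
  activations * keep / (1 - p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the MBConv network
#'
#' Runs exactly `config$epochs` epochs of SGD with momentum over the
#' training partition of `data` (manifest `split == "train"`), validating
#' each epoch on `split == "val"` when present. Shuffling, initialization,
#' dropout and augmentation all derive from `config$seed`, so a fixed seed
#' reproduces the report bit for bit. The learning rate is multiplied by
#' `lr_decay` after every epoch. The returned model records the training
#' patient ids for downstream leakage checks.
#'
#' @param mconfig A [model_config()].
#' @param data A `phantom_dataset` (or list with `images` H x W x N and
#'   `manifest` with `patient_id`, `label`, `split`).
#' @param config A [train_config()].
#' @param weights Optional pre-initialized weights (defaults to
#'   [init_weights()] under the configured scheme and seed).
#' @return A `glioscope_model`: `weights`, `config` (model), `train_config`,
#'   `report` (per-epoch data frame), `train_patient_ids`.
#' @export
train_model <- function(mconfig, data, config, weights = NULL) {
  stopifnot(inherits(mconfig, "model_config"), inherits(config, "train_config"))
  tr_idx <- which(data$manifest$split == "train")
  va_idx <- which(data$manifest$split == "val")
  if (!length(tr_idx)) stop("train_model: empty training partition")
  user_weights <- !is.null(weights)
  labels <- data$manifest$label
  lr_base <- config$learning_rate
  restarts <- 0L
  repeat {
  if (!user_weights) {
    init_seed <- config$seed + 7919L * restarts
    weights <- init_weights(mconfig, config$init_scheme, init_seed)
    if (isTRUE(config$lsuv_init)) {
      probe <- subset_images(data$images,
                             tr_idx[seq_len(min(64L, length(tr_idx)))])
      weights <- lsuv_rescale(weights, mconfig, probe)
    }
  }
  velocity <- lapply(weights, function(w) w * 0) # zero, same shape/attrs as w
  report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_acc = numeric(0))
  set.seed(config$seed + 1L + 31L * restarts)
  is_bias <- grepl("\\.b[0-9]*$|\\.b$", names(weights))
  do_restart <- FALSE
  for (ep in seq_len(config$epochs)) {
    wu <- config$warmup_epochs %||% 0L
    lr <- if (ep <= wu) lr_base * ep / (wu + 1L) else
      lr_base * config$lr_decay^(ep - wu - 1L)
    idx <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0
    n_seen <- 0L
    for (start in seq(1L, length(idx), by = config$batch_size)) {
      bidx <- idx[start:min(start + config$batch_size - 1L, length(idx))]
      xb <- subset_images(data$images, bidx)
      if (!is.null(config$augment)) {
        for (j in seq_along(bidx)) {
          xb[, , j] <- augment(xb[, , j], labels[bidx[j]], config$augment)$image
        }
      }
      yb <- labels[bidx]
      fw <- model_forward(weights, mconfig, xb, training = TRUE,
                          dropout_p = config$dropout)
      nb <- length(bidx)
      ep_loss <- ep_loss + loss_acc(fw$probs, yb) * nb
      n_seen <- n_seen + nb
      dlogits <- (fw$probs - one_hot(yb, mconfig$classes)) / nb
      grads <- model_backward(weights, mconfig, fw$cache, dlogits)
      if (is.finite(config$clip_norm %||% Inf)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (is.finite(gnorm) && gnorm > config$clip_norm) {
          sc <- config$clip_norm / gnorm
          grads <- lapply(grads, function(g) g * sc)
        }
      }
      for (nm in names(weights)) {
        wd <- if (is_bias[match(nm, names(weights))]) 0 else config$weight_decay
        st <- sgd_momentum_step(weights[[nm]], grads[[nm]], velocity[[nm]],
                                lr, config$momentum, wd)
        weights[[nm]] <- st$w
        velocity[[nm]] <- st$velocity
      }
    }
    val_loss <- NA_real_
    val_acc <- NA_real_
    if (length(va_idx)) {
      pv <- model_forward(weights, mconfig,
                          subset_images(data$images, va_idx))$probs
      val_loss <- loss_acc(pv, labels[va_idx])
      val_acc <- mean((max.col(t(pv)) - 1L) == labels[va_idx])
    }
    report <- rbind(report, data.frame(epoch = ep,
                                       train_loss = ep_loss / n_seen,
                                       val_loss = val_loss,
                                       val_acc = val_acc))
    # plateau restart: still at the chance plateau after the patience
    # window -> re-initialize once or twice from a derived seed
    if (!user_weights && (config$restart_patience %||% 0L) > 0L &&
        ep == config$restart_patience &&
        restarts < (config$max_restarts %||% 0L) &&
        ep_loss / n_seen > (config$restart_loss %||% 0.67)) {
      do_restart <- TRUE
      break
    }
  }
  if (do_restart) {
    restarts <- restarts + 1L
    weights <- NULL
    next
  }
  break
  } # repeat
  structure(list(weights = weights, config = mconfig,
                 train_config = config, report = report,
                 restarts = restarts,
                 train_patient_ids = data$manifest$patient_id[tr_idx]),
            class = "glioscope_model")
}

#' @export
print.glioscope_model <- function(x, ...) {
  rc <- resource_cost(x$config)
  cat("glioscope MBConv model\n")
  cat(sprintf("  parameters:    %d (%.4f M)\n", rc$params, rc$c_size))
  cat(sprintf("  latency proxy: %.3f MMAC\n", rc$c_latency))
  if (nrow(x$report))
    cat(sprintf("  final epoch:   train loss %.4f, val acc %s\n",
                x$report$train_loss[nrow(x$report)],
                format(x$report$val_acc[nrow(x$report)])))
  invisible(x)
}

#' Stratified 10-fold cross-validation of the full pipeline
#'
#' For each fold: the fold is held out, the remaining patients train the
#' model (optionally after CLAHE and train-statistics normalization), and
#' the metric suite is computed on the held-out fold. Per-fold metrics are
#' returned with their mean and standard deviation.
#'
#' @param data A `phantom_dataset`.
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()] (defaults to [desk_train_config()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param clahe_params `NULL` to skip contrast enhancement, or a list with
#'   `tile` and `clip_limit`.
#' @return List of class `cv_result`: `folds` (per-fold metric data frame),
#'   `mean`, `sd`, `assignment`.
#' @export
cross_validate <- function(data, mconfig = model_config(),
                           tconfig = desk_train_config(), k = 10L,
                           seed = 1L,
                           clahe_params = list(tile = 8L, clip_limit = 2.0)) {
  man <- data$manifest
  if (!is.null(clahe_params)) {
    for (i in seq_len(dim(data$images)[3])) {
      data$images[, , i] <- clahe(data$images[, , i],
                                  tile = clahe_params$tile,
                                  clip_limit = clahe_params$clip_limit)
    }
  }
  folds <- kfold(man$patient_id, man$label, k = k, seed = seed)
  fold_of <- folds$fold[match(man$patient_id, folds$patient_id)]
  rows <- NULL
  for (f in sort(unique(fold_of))) {
    d <- data
    d$manifest$split <- ifelse(fold_of == f, "test", "train")
    stats_tr <- channel_stats(subset_images(d$images,
                                            which(d$manifest$split == "train")),
                              partition = "train")
    d$images <- normalize(d$images, stats_tr)
    tc <- tconfig
    tc$seed <- as.integer(seed + f)
    model <- train_model(mconfig, d, tc)
    ev <- evaluate(model, d, split = "test")
    rows <- rbind(rows, data.frame(fold = f, as.list(unclass(ev$metrics))))
  }
  mcols <- setdiff(names(rows), "fold")
  structure(list(folds = rows,
                 mean = colMeans(rows[mcols], na.rm = TRUE),
                 sd = vapply(rows[mcols], stats::sd, numeric(1)),
                 assignment = folds),
            class = "cv_result")
}
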