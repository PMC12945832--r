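#' The hyperparameter search space
#'
#' Ten dimensions encoded into the unit cube: six continuous (learning rate
#' and weight decay on log scale; momentum, dropout and the two resource
#' trade-off coefficients on linear scale) and four discrete (batch size,
#' epochs, initialization scheme, augmentation policy) mapped by equal-width
#' binning of \[0,1\] with ties broken toward the lower bin.
#'
#' @return A list of dimension descriptors (class `hyper_space`).
#' @export
hyper_space <- function() {
  dims <- list(
    list(name = "learning_rate", type = "log", lo = 1e-4, hi = 1e-2),
    list(name = "weight_decay", type = "log", lo = 1e-5, hi = 1e-3),
    list(name = "momentum", type = "lin", lo = 0.85, hi = 0.99),
    list(name = "dropout", type = "lin", lo = 0.1, hi = 0.4),
    list(name = "lambda1", type = "lin", lo = 1e-4, hi = 1e-2),
    list(name = "lambda2", type = "lin", lo = 1e-5, hi = 1e-3),
    list(name = "batch_size", type = "cat", values = c(64L, 128L, 192L, 256L)),
    list(name = "epochs", type = "cat", values = 40L:60L),
    list(name = "init_scheme", type = "cat",
         values = c("xavier_normal", "he_normal")),
    list(name = "augmentation", type = "cat",
         values = c("crop_flip_h", "crop_flip_v", "rotate_jitter")))
  structure(dims, class = "hyper_space")
}

#' Encode hyperparameters into the unit cube / decode back
#'
#' `decode(encode(hp))` is the identity for grid-valued hyperparameters:
#' continuous dimensions use exact affine (or log-affine) maps, categorical
#' dimensions encode to their bin center.
#'
#' @param hp Named list of hyperparameter values.
#' @param space A [hyper_space()].
#' @return `encode_hp`: numeric vector in \[0,1\]^10; `decode_hp`: named
#'   list of hyperparameter values.
#' @export
encode_hp <- function(hp, space = hyper_space()) {
  u <- numeric(length(space))
  for (i in seq_along(space)) {
    d <- space[[i]]
    v <- hp[[d$name]]
    if (is.null(v)) stop("encode_hp: missing value for ", d$name)
    u[i] <- switch(d$type,
      lin = {
        if (v < d$lo || v > d$hi) stop("encode_hp: ", d$name, " out of range")
        (v - d$lo) / (d$hi - d$lo)
      },
      log = {
        if (v < d$lo || v > d$hi) stop("encode_hp: ", d$name, " out of range")
        (log(v) - log(d$lo)) / (log(d$hi) - log(d$lo))
      },
      cat = {
        j <- match(v, d$values)
        if (is.na(j)) stop("encode_hp: ", d$name, " value not on the grid")
        (j - 0.5) / length(d$values)
      })
  }
  u
}

#' @rdname encode_hp
#' @param u Numeric vector in \[0,1\]^10.
#' @export
decode_hp <- function(u, space = hyper_space()) {
  if (length(u) != length(space)) stop("decode_hp: wrong dimension")
  if (any(u < 0 | u > 1)) stop("decode_hp: coordinates must lie in [0,1]")
  hp <- list()
  for (i in seq_along(space)) {
    d <- space[[i]]
    hp[[d$name]] <- switch(d$type,
      lin = d$lo + u[i] * (d$hi - d$lo),
      log = exp(log(d$lo) + u[i] * (log(d$hi) - log(d$lo))),
      cat = {
        nb <- length(d$values)
        j <- max(1L, ceiling(u[i] * nb)) # boundary values fall to the lower bin
        d$values[[min(j, nb)]]
      })
  }
  hp
}

aug_policy_from_name <- function(name) {
  switch(name,
    crop_flip_h = augment_policy(c("crop", "flip_h")),
    crop_flip_v = augment_policy(c("crop", "flip_v")),
    rotate_jitter = augment_policy(c("rotate", "brightness", "contrast")),
    stop("unknown augmentation policy: ", name))
}

#' Composite-loss evaluation of one encoded candidate
#'
#' Decodes the unit vector, trains the desk-scale model with the candidate
#' hyperparameters on the training partition of `data`, and returns
#' `L_total = validation cross-entropy + lambda1 * R_latency +
#' lambda2 * R_params`. Training failures (non-finite loss) return the
#' `penalty` value instead of raising, so the optimizer continues.
#'
#' @param u Candidate in \[0,1\]^10.
#' @param data A `phantom_dataset` with `train` and `val` partitions.
#' @param mconfig A [model_config()].
#' @param eval_config List of desk-scale caps: `max_epochs` (cap on the
#'   decoded epoch count), `max_batch`, `use_augment` (logical), `seed`.
#' @param penalty Value returned when training diverges.
#' @return Scalar `L_total` with attributes `hp`, `L_CE`, `cost`.
#' @export
objective_eval <- function(u, data, mconfig = model_config(),
                           eval_config = list(max_epochs = 2L,
                                              max_batch = 64L,
                                              use_augment = FALSE,
                                              seed = 1L),
                           penalty = 1e6) {
  hp <- decode_hp(u)
  epochs <- min(hp$epochs, eval_config$max_epochs %||% hp$epochs)
  batch <- min(hp$batch_size, eval_config$max_batch %||% hp$batch_size)
  aug <- if (isTRUE(eval_config$use_augment))
    aug_policy_from_name(hp$augmentation) else NULL
  tc <- train_config(learning_rate = hp$learning_rate, batch_size = batch,
                     epochs = epochs, weight_decay = hp$weight_decay,
                     momentum = hp$momentum, dropout = hp$dropout,
                     init_scheme = hp$init_scheme, augment = aug,
                     seed = eval_config$seed %||% 1L)
  out <- tryCatch({
    model <- train_model(mconfig, data, tc)
    va_idx <- which(data$manifest$split == "val")
    pv <- model_forward(model$weights, mconfig,
                        subset_images(data$images, va_idx))$probs
    L_CE <- loss_acc(pv, data$manifest$label[va_idx])
    cost <- resource_cost(mconfig)
    lt <- loss_total(L_CE, cost, hp$lambda1, hp$lambda2)
    structure(lt, hp = hp, L_CE = L_CE, cost = cost)
  }, error = function(e) NULL)
  if (is.null(out) || !is.finite(out)) {
    return(structure(penalty, hp = hp, L_CE = NA_real_, cost = NULL))
  }
  out
}

#' Hyperparameter search with SCO or ASCO
#'
#' Runs the chosen single-candidate optimizer over the encoded
#' hyperparameter space. By default each evaluation trains the desk-scale
#' model and scores it with the composite loss; a `surrogate` function on
#' the unit cube may replace training (used for optimizer-validation and
#' fast tests). The divergence penalty adapts: a failed candidate scores
#' 10x the worst finite objective seen so far (at least 1e3).
#'
#' @param algo `"asco"` (default) or `"sco"`.
#' @param budget Total objective evaluations `T`.
#' @param data A `phantom_dataset` with train/val partitions (ignored when
#'   `surrogate` is given).
#' @param seed Integer seed.
#' @param mconfig A [model_config()].
#' @param eval_config Desk-scale caps passed to [objective_eval()].
#' @param surrogate Optional function `u -> cost` replacing training.
#' @return An `hpo_result`: `best_hp`, `best_value`, `trace` (one row per
#'   evaluation), `history`, `algo`, `seed`.
#' @export
run_hpo <- function(algo = c("asco", "sco"), budget = 60L, data = NULL,
                    seed = 1L, mconfig = model_config(),
                    eval_config = list(max_epochs = 2L, max_batch = 64L,
                                       use_augment = FALSE, seed = 1L),
                    surrogate = NULL) {
  algo <- match.arg(algo)
  if (budget < 2L) stop("run_hpo: budget must be at least 2")
  space <- search_space(rep(0, length(hyper_space())),
                        rep(1, length(hyper_space())))
  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- vector("list", budget)
  trace_env$i <- 0L
  trace_env$worst <- -Inf
  obj <- function(u) {
    val <- if (!is.null(surrogate)) {
      surrogate(u)
    } else {
      pen <- 10 * max(trace_env$worst, 1e3)
      objective_eval(u, data, mconfig, eval_config, penalty = pen)
    }
    v <- as.numeric(val)
    if (is.finite(v)) trace_env$worst <- max(trace_env$worst, v)
    trace_env$i <- trace_env$i + 1L
    trace_env$rows[[trace_env$i]] <-
      list(eval = trace_env$i, value = v,
           L_CE = attr(val, "L_CE") %||% NA_real_,
           u = u, hp = attr(val, "hp"))
    v
  }
  cfg <- sco_config(T = budget, seed = seed)
  res <- if (algo == "asco") run_asco(obj, space, cfg)
  else run_sco(obj, space, cfg)
  trace <- do.call(rbind, lapply(trace_env$rows[seq_len(trace_env$i)],
                                 function(r) data.frame(eval = r$eval,
                                                        value = r$value)))
  structure(list(best_u = res$gbest, best_hp = decode_hp(res$gbest),
                 best_value = res$f_gbest, history = res$history,
                 trace = trace, candidates = trace_env$rows,
                 algo = algo, seed = seed),
            class = "hpo_result")
}

#' Ablation comparison: default vs SCO-tuned vs ASCO-tuned
#'
#' Trains the desk-scale model under (i) the fixed default configuration,
#' (ii) the best configuration found by SCO, and (iii) the best found by
#' ASCO - all on the same train/val partitions - then evaluates each on the
#' held-out test partition, which no search step ever touched.
#'
#' @param data A `phantom_dataset` with train/val/test partitions.
#' @param budget Search budget per optimizer.
#' @param seed Integer seed.
#' @param mconfig A [model_config()].
#' @param eval_config Desk-scale caps, as [run_hpo()].
#' @return List of class `ablation_result`: `table` (one metric row per
#'   variant) and the two `hpo_result`s.
#' @export
run_ablation <- function(data, budget = 20L, seed = 1L,
                         mconfig = model_config(),
                         eval_config = list(max_epochs = 2L, max_batch = 64L,
                                            use_augment = FALSE, seed = 1L)) {
  variants <- list()
  hpos <- list()
  variants$default <- desk_train_config(epochs = eval_config$max_epochs %||% 2L,
                                        seed = seed)
  for (algo in c("sco", "asco")) {
    h <- run_hpo(algo, budget = budget, data = data, seed = seed,
                 mconfig = mconfig, eval_config = eval_config)
    hp <- h$best_hp
    variants[[algo]] <- train_config(
      learning_rate = hp$learning_rate,
      batch_size = min(hp$batch_size, eval_config$max_batch %||% hp$batch_size),
      epochs = min(hp$epochs, eval_config$max_epochs %||% hp$epochs),
      weight_decay = hp$weight_decay, momentum = hp$momentum,
      dropout = hp$dropout, init_scheme = hp$init_scheme, seed = seed)
    hpos[[algo]] <- h
  }
  rows <- NULL
  for (nm in names(variants)) {
    model <- train_model(mconfig, data, variants[[nm]])
    ev <- evaluate(model, data, split = "test")
    rows <- rbind(rows, data.frame(variant = nm,
                                   as.list(unclass(ev$metrics))))
  }
  structure(list(table = rows, hpo = hpos), class = "ablation_result")
}
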