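#' Bounded real search space
#'
#' Defines the box-constrained domain that the single-candidate optimizers
#' search. Bounds are recycled to a common dimension.
#'
#' @param lb Numeric vector of lower bounds.
#' @param ub Numeric vector of upper bounds (same length as `lb` after
#'   recycling).
#' @return An object of class `search_space` with fields `dim`, `lb`, `ub`.
#' @examples
#' sp <- search_space(rep(-5, 10), rep(5, 10))
#' sp$dim
#' @export
search_space <- function(lb, ub) {
  n <- max(length(lb), length(ub))
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("search_space: bounds must be finite")
  if (any(lb >= ub))
    stop("search_space: every lower bound must be strictly below its upper bound")
  structure(list(dim = n, lb = lb, ub = ub), class = "search_space")
}

#' Single Candidate Optimizer configuration
#'
#' @param T Total number of objective evaluations (the full budget).
#' @param alpha_budget Evaluations spent in phase 1 (global, multiplicative
#'   steps). Default: half the budget.
#' @param beta_budget Evaluations spent in phase 2 (range-scaled local steps).
#'   Must satisfy `alpha_budget + beta_budget == T`.
#' @param b Positive constant of the exponential step-weight schedule
#'   `w(t) = exp(-(b*t/T)^b)`. Default 2.
#' @param m Stagnation threshold: number of consecutive non-improving
#'   evaluations in phase 2 before a full-range escape step fires. Default 50.
#' @param seed Integer seed controlling all randomness of a run.
#' @return An object of class `sco_config`.
#' @export
sco_config <- function(T, alpha_budget = NULL, beta_budget = NULL,
                       b = 2, m = 50, seed = 1L) {
  T <- as.integer(T)
  if (T < 1L) stop("sco_config: T must be a positive integer")
  if (is.null(alpha_budget) && is.null(beta_budget)) {
    alpha_budget <- T %/% 2L
    beta_budget <- T - alpha_budget
  } else if (is.null(beta_budget)) {
    beta_budget <- T - as.integer(alpha_budget)
  } else if (is.null(alpha_budget)) {
    alpha_budget <- T - as.integer(beta_budget)
  }
  alpha_budget <- as.integer(alpha_budget)
  beta_budget <- as.integer(beta_budget)
  if (alpha_budget < 0L || beta_budget < 0L || alpha_budget + beta_budget != T)
    stop("sco_config: alpha_budget + beta_budget must equal T")
  if (b <= 0) stop("sco_config: b must be positive")
  if (m < 1) stop("sco_config: m must be a positive integer")
  structure(list(T = T, alpha_budget = alpha_budget, beta_budget = beta_budget,
                 b = as.numeric(b), m = as.integer(m), seed = as.integer(seed)),
            class = "sco_config")
}

#' Initial candidate from uniform draws
#'
#' Maps per-dimension draws `r4` in \[0,1\] into the search box:
#' `x_j = lb_j + r4_j * (ub_j - lb_j)`.
#'
#' @param space A [search_space()].
#' @param r4 Numeric vector in \[0,1\], one draw per dimension.
#' @return Numeric vector inside the box.
#' @export
init_candidate <- function(space, r4) {
  stopifnot(inherits(space, "search_space"))
  if (length(r4) != space$dim)
    stop("init_candidate: r4 must have one entry per dimension")
  if (any(r4 < 0 | r4 > 1)) stop("init_candidate: r4 entries must lie in [0,1]")
  space$lb + r4 * (space$ub - space$lb)
}

#' Exponential step-weight schedule
#'
#' `w(t) = exp(-(b*t/T)^b)`: equals 1 at `t = 0` and decays strictly with the
#' evaluation counter, shrinking both phase step sizes over the run.
#'
#' @param t Evaluation index in `0..T`.
#' @param T Total evaluation budget.
#' @param b Positive schedule constant.
#' @return Weight in (0, 1].
#' @export
weight_w <- function(t, T, b = 2) {
  exp(-(b * t / T)^b)
}

#' Phase-1 update: multiplicative perturbation of the global best
#'
#' Per dimension `j`: `gbest_j + w*|gbest_j|` when `r1_j < 0.5`, else
#' `gbest_j - w*|gbest_j|`. A fresh branch draw is used per dimension.
#'
#' @param gbest Current global best position.
#' @param w Step weight from [weight_w()].
#' @param r1 Vector of uniform draws in \[0,1), one per dimension.
#' @return Proposed candidate (not yet bound-checked).
#' @export
phase1_step <- function(gbest, w, r1) {
  step <- w * abs(gbest)
  ifelse(r1 < 0.5, gbest + step, gbest - step)
}

#' Phase-2 update: range-scaled perturbation of the global best
#'
#' Per dimension `j`: `gbest_j +- r2_j * w * (ub_j - lb_j)`, the sign chosen
#' by `r2_j < 0.5`.
#'
#' @inheritParams phase1_step
#' @param space A [search_space()].
#' @param r2 Vector of uniform draws in \[0,1), one per dimension.
#' @export
phase2_step <- function(gbest, w, space, r2) {
  step <- r2 * w * (space$ub - space$lb)
  ifelse(r2 < 0.5, gbest + step, gbest - step)
}

#' Stagnation escape: full-range perturbation
#'
#' Fires when `m` consecutive evaluations brought no cost improvement.
#' Identical branch rule to phase 2 but without the decaying weight, so the
#' kick can reach the whole box: `gbest_j +- r3_j * (ub_j - lb_j)`.
#'
#' @inheritParams phase2_step
#' @param r3 Vector of uniform draws in \[0,1), one per dimension.
#' @export
escape_step <- function(gbest, space, r3) {
  step <- r3 * (space$ub - space$lb)
  ifelse(r3 < 0.5, gbest + step, gbest - step)
}

#' Boundary rule: reset violating dimensions to the global best
#'
#' Any dimension that left the box is replaced by the corresponding global
#' best coordinate (not clamped to the violated bound).
#'
#' @param x Proposed candidate.
#' @param gbest Global best position (inside the box).
#' @param space A [search_space()].
#' @return Candidate with every dimension inside the box.
#' @export
clip_to_bounds <- function(x, gbest, space) {
  out <- x > space$ub | x < space$lb
  x[out] <- gbest[out]
  x
}

eval_objective <- function(objective, x) {
  f <- objective(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
    stop("objective returned a non-finite value at x = (",
         paste(signif(x, 6), collapse = ", "), ")")
  as.numeric(f)
}

# Shared two-phase loop. `init_state` performs initialization (plain uniform
# draw for SCO, opposition-based chaotic draw for ASCO) and reports the
# evaluations it consumed; `draw` supplies the per-dimension branch draws
# r1-r3 (pseudo-random by default, chaotic in the experimental all-chaos
# mode).
run_single_candidate <- function(objective, space, config, init_state,
                                 draw = stats::runif) {
  stopifnot(inherits(space, "search_space"), inherits(config, "sco_config"))
  d <- space$dim
  T <- config$T
  set.seed(config$seed)

  st <- init_state(objective, space)
  gbest <- st$gbest
  f_gbest <- st$f_gbest
  history <- numeric(T)
  history[seq_len(st$evals)] <- st$history
  t <- st$evals
  c_stag <- 0L

  while (t < T) {
    t <- t + 1L
    w <- weight_w(t, T, config$b)
    if (t <= config$alpha_budget) {
      x <- phase1_step(gbest, w, draw(d))
    } else if (c_stag >= config$m) {
      x <- escape_step(gbest, space, draw(d))
      c_stag <- 0L # one full-range kick, then phase-2 search resumes
    } else {
      x <- phase2_step(gbest, w, space, draw(d))
    }
    x <- clip_to_bounds(x, gbest, space)
    f <- eval_objective(objective, x)
    if (f < f_gbest) { # strict improvement only; ties do not reset the counter
      gbest <- x
      f_gbest <- f
      c_stag <- 0L
    } else {
      c_stag <- c_stag + 1L
    }
    history[t] <- f_gbest
  }
  structure(list(gbest = gbest, f_gbest = f_gbest, history = history,
                 evals = t, config = config),
            class = "optimization_result")
}

#' Run the Single Candidate Optimizer
#'
#' Two-phase single-candidate search: phase 1 perturbs the global best
#' multiplicatively with a decaying weight, phase 2 takes range-scaled local
#' steps, and a full-range escape replaces the phase-2 step after `m`
#' consecutive non-improving evaluations. Acceptance is greedy: the global
#' best is replaced only on strict cost improvement. Out-of-bound dimensions
#' are reset to the global best.
#'
#' @param objective Function mapping a numeric vector in the space to a finite
#'   scalar cost (lower is better).
#' @param space A [search_space()].
#' @param config An [sco_config()].
#' @return An `optimization_result`: `gbest`, `f_gbest`, per-evaluation
#'   `history` of the best cost (non-increasing), `evals`, `config`.
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' res <- run_sco(bench_sphere, sp, sco_config(T = 500, seed = 7))
#' res$f_gbest
#' @export
run_sco <- function(objective, space, config) {
  run_single_candidate(objective, space, config, function(obj, sp) {
    x <- init_candidate(sp, stats::runif(sp$dim))
    f <- eval_objective(obj, x)
    list(gbest = x, f_gbest = f, evals = 1L, history = f)
  })
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Single-candidate optimization result\n")
  cat(sprintf("  evaluations: %d\n", x$evals))
  cat(sprintf("  best cost:   %.6g\n", x$f_gbest))
  cat(sprintf("  best point:  %s\n",
              paste(signif(x$gbest, 5), collapse = ", ")))
  invisible(x)
}

#' Benchmark objectives
#'
#' Standard continuous test functions used to validate the optimizers:
#' sphere (minimum 0 at the origin), Rastrigin (highly multimodal, minimum 0
#' at the origin) and Rosenbrock (curved valley, minimum 0 at all-ones).
#'
#' @param x Numeric vector.
#' @return Scalar function value.
#' @export
bench_sphere <- function(x) sum(x^2)

#' @rdname bench_sphere
#' @export
bench_rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

#' @rdname bench_sphere
#' @export
bench_rosenbrock <- function(x) {
  n <- length(x)
  if (n < 2) stop("rosenbrock needs at least 2 dimensions")
  sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
}
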