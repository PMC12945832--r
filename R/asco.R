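#' Chebyshev chaotic stream
#'
#' Deterministic iterate `r <- cos(beta * acos(r))` on \[-1,1\] used in place
#' of the uniform initialization draw `r4`. With the published map parameter
#' `beta = 0.8` the map is contractive (its iterates converge to the fixed
#' point 1), so the stream carries a collapse guard: whenever two successive
#' iterates differ by less than `collapse_tol` the stream re-seeds itself
#' from the ambient pseudo-random generator. Chebyshev maps are chaotic only
#' for integer `beta >= 2`; the published value is kept, guarded, and the
#' discrepancy is documented rather than silently corrected.
#'
#' @param seed_value Initial iterate in (-1, 1). If `NULL`, derived from
#'   `seed` by a fixed affine hash so one integer controls the whole run.
#' @param beta_cheb Map parameter (default 0.8, as published).
#' @param seed Integer used to derive `seed_value` when it is not given.
#' @param collapse_tol Successive-difference threshold that triggers
#'   re-seeding (default 1e-12).
#' @return An object of class `chaos_stream` (mutable environment).
#' @export
chaos_stream <- function(seed_value = NULL, beta_cheb = 0.8, seed = 1L,
                         collapse_tol = 1e-12) {
  if (is.null(seed_value)) {
    # Knuth-style multiplicative hash of the integer seed into (-1, 1)
    u <- ((as.numeric(seed) * 2654435761 + 97531) %% 2^32) / 2^32
    seed_value <- 2 * u - 1
    if (abs(seed_value) >= 1 - 1e-6) seed_value <- seed_value * 0.5
  }
  if (abs(seed_value) >= 1)
    stop("chaos_stream: seed_value must lie strictly inside (-1, 1)")
  env <- new.env(parent = emptyenv())
  env$r <- as.numeric(seed_value)
  env$beta_cheb <- as.numeric(beta_cheb)
  env$collapse_tol <- as.numeric(collapse_tol)
  env$reseeds <- 0L
  class(env) <- "chaos_stream"
  env
}

#' Advance the Chebyshev stream by one iterate
#'
#' @param stream A [chaos_stream()].
#' @return The next iterate in \[-1, 1\]; the stream state is advanced.
#' @export
chebyshev_next <- function(stream) {
  stopifnot(inherits(stream, "chaos_stream"))
  r <- stream$r
  if (!is.finite(r) || abs(r) > 1)
    stop("chaos_stream state corrupted: |r| > 1")
  r_new <- cos(stream$beta_cheb * acos(r))
  if (abs(r_new - r) < stream$collapse_tol) {
    # contractive map has collapsed onto its fixed point: re-seed
    r_new <- stats::runif(1, -1 + 1e-9, 1 - 1e-9)
    stream$reseeds <- stream$reseeds + 1L
  }
  stream$r <- r_new
  r_new
}

#' Rescale a Chebyshev iterate to a unit-interval draw
#'
#' The initialization rule needs draws in \[0,1\] while the Chebyshev
#' iterates live in \[-1,1\]; this applies the affine map `(r + 1) / 2`.
#'
#' @param stream A [chaos_stream()].
#' @return A value in \[0, 1\].
#' @export
chaotic_uniform <- function(stream) {
  (chebyshev_next(stream) + 1) / 2
}

#' Opposition-based reflection of a candidate
#'
#' Returns the standard opposition-based-learning mirror
#' `lb_j + ub_j - x_j`, the reflection of `x` through the box midpoint.
#'
#' @param x Numeric vector inside the box.
#' @param space A [search_space()].
#' @return The opposite point (inside the box).
#' @export
opposite_point <- function(x, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(x) != space$dim)
    stop("opposite_point: x must have one entry per dimension")
  if (any(x < space$lb | x > space$ub))
    stop("opposite_point: x must lie inside the search space")
  space$lb + space$ub - x
}

#' Opposition-based initialization
#'
#' Draws the initial candidate with chaotic unit-interval draws, evaluates
#' both the candidate and its opposite point, and starts the search from the
#' better of the pair (ties keep the original draw). Consumes two objective
#' evaluations from the budget.
#'
#' @param objective Objective function (lower is better).
#' @param space A [search_space()].
#' @param stream A [chaos_stream()] supplying the r4 draws.
#' @return List with `gbest`, `f_gbest`, `evals = 2`, the running-best
#'   `history` of length 2, and the evaluated `pair`.
#' @export
obl_initialize <- function(objective, space, stream) {
  d <- space$dim
  r4 <- vapply(seq_len(d), function(i) chaotic_uniform(stream), numeric(1))
  x <- init_candidate(space, r4)
  x_opp <- opposite_point(x, space)
  f_x <- eval_objective(objective, x)
  f_opp <- eval_objective(objective, x_opp)
  if (f_opp < f_x) {
    gbest <- x_opp; f_gbest <- f_opp
  } else {
    gbest <- x; f_gbest <- f_x
  }
  list(gbest = gbest, f_gbest = f_gbest, evals = 2L,
       history = c(f_x, min(f_x, f_opp)),
       pair = list(x = x, x_opp = x_opp, f_x = f_x, f_opp = f_opp))
}

#' Run the Advanced Single Candidate Optimizer
#'
#' Identical two-phase loop to [run_sco()] with two modifications:
#' opposition-based initialization (the better of the drawn point and its
#' box reflection seeds the search, costing two evaluations) and Chebyshev
#' chaotic draws replacing the uniform initialization draws `r4`. The
#' phase/escape draws `r1`-`r3` remain pseudo-random unless
#' `chaos_all_draws = TRUE`.
#'
#' @inheritParams run_sco
#' @param beta_cheb Chebyshev map parameter (default 0.8).
#' @param chaos_all_draws If `TRUE`, the chaotic stream also supplies the
#'   phase-update draws r1-r3 (experimental; off by default).
#' @return An `optimization_result`, as [run_sco()].
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' res <- run_asco(bench_sphere, sp, sco_config(T = 500, seed = 7))
#' res$f_gbest
#' @export
run_asco <- function(objective, space, config, beta_cheb = 0.8,
                     chaos_all_draws = FALSE) {
  if (config$T < 2L)
    stop("run_asco: opposition-based initialization needs a budget T >= 2")
  stream <- NULL
  init <- function(obj, sp) {
    # set.seed has already run inside the shared loop; derive the chaos seed
    # from the same integer so one seed controls the whole run
    stream <<- chaos_stream(beta_cheb = beta_cheb, seed = config$seed)
    obl_initialize(obj, sp, stream)
  }
  draw <- if (chaos_all_draws) {
    function(n) vapply(seq_len(n), function(i) chaotic_uniform(stream), numeric(1))
  } else {
    stats::runif
  }
  run_single_candidate(objective, space, config, init, draw = draw)
}
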