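# Gray wolf optimizer (GWO) and the improved variant (IGWO) with
# fitness-based omega regeneration, over box-bounded search spaces with
# optional integer dimensions. Minimization throughout; callers negate
# maximization objectives (e.g. Kapur entropy).

#' Define a box-bounded search space
#'
#' A search space is a hyper-rectangle with optional integer-valued
#' dimensions. Integer dimensions are rounded to the nearest integer before
#' every objective evaluation and after every position update, so the
#' optimizer itself still moves through the continuous relaxation.
#'
#' @param lower Numeric vector of per-dimension lower bounds.
#' @param upper Numeric vector of per-dimension upper bounds, same length as
#'   `lower` and strictly greater element-wise.
#' @param integer Logical scalar or vector: which dimensions are integers.
#'   Integer dimensions must have integer-valued bounds.
#' @return An object of class `gwo_space` with fields `dim`, `lower`,
#'   `upper`, `integer`.
#' @examples
#' search_space(c(0, 0), c(1, 1))
#' search_space(16, 256, integer = TRUE)
#' @export
search_space <- function(lower, upper, integer = FALSE) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L) {
    stop("`lower` and `upper` must be non-empty vectors of equal length")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower >= upper)) {
    stop("each lower bound must be strictly below its upper bound")
  }
  integer <- rep_len(as.logical(integer), length(lower))
  if (any(integer & (lower != round(lower) | upper != round(upper)))) {
    stop("integer dimensions must have integer-valued bounds")
  }
  structure(
    list(dim = length(lower), lower = lower, upper = upper,
         integer = integer),
    class = "gwo_space"
  )
}

#' IGWO configuration
#'
#' Bundles the optimizer settings. The defaults follow the reference
#' protocol: 30 search agents, 200 iterations, elimination of the worst 30%
#' of agents each iteration, and a 0.7 probability that an eliminated agent
#' is replaced by an elite copy rather than a Gaussian resample around the
#' alpha wolf.
#'
#' @param pop_size Number of search agents (N >= 4).
#' @param max_iter Maximum number of iterations.
#' @param elim_fraction Fraction `r` in (0, 1] of agents eliminated per
#'   iteration (IGWO only); the number replaced is `floor(r * N)`, capped at
#'   `N - 3` so the three best agents always survive.
#' @param elite_prob Probability `p` that a replacement is a copy of one of
#'   the alpha/beta/delta elites rather than a Gaussian resample.
#' @param elite_weights Length-3 non-negative weights for drawing among
#'   alpha, beta, delta when copying an elite (rank-proportional by default).
#' @param seed Optional integer seed; when set, [gwo_optimize()] is fully
#'   reproducible and leaves the caller's RNG state untouched.
#' @param greedy_memory If `TRUE` (IGWO), an agent only keeps a move that
#'   improves its own fitness; regenerated agents always adopt their new
#'   position.
#' @return An object of class `igwo_config`.
#' @export
igwo_config <- function(pop_size = 30L, max_iter = 200L,
                        elim_fraction = 0.3, elite_prob = 0.7,
                        elite_weights = c(3, 2, 1), seed = NULL,
                        greedy_memory = TRUE) {
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  if (pop_size < 4L) stop("`pop_size` must be at least 4 (three elites plus omegas)")
  if (max_iter < 1L) stop("`max_iter` must be positive")
  if (elim_fraction <= 0 || elim_fraction > 1) stop("`elim_fraction` must lie in (0, 1]")
  if (elite_prob < 0 || elite_prob > 1) stop("`elite_prob` must lie in [0, 1]")
  if (length(elite_weights) != 3L || any(elite_weights < 0) ||
      sum(elite_weights) <= 0) {
    stop("`elite_weights` must be 3 non-negative weights with positive sum")
  }
  structure(
    list(pop_size = pop_size, max_iter = max_iter,
         elim_fraction = elim_fraction, elite_prob = elite_prob,
         elite_weights = as.numeric(elite_weights),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         greedy_memory = isTRUE(greedy_memory)),
    class = "igwo_config"
  )
}

clip_to_space <- function(x, space) {
  x <- pmin(pmax(x, rep(space$lower, each = nrow(x))),
            rep(space$upper, each = nrow(x)))
  if (any(space$integer)) {
    ii <- which(space$integer)
    x[, ii] <- round(x[, ii])
  }
  x
}

#' Initialize a wolf population
#'
#' Places `pop_size` agents uniformly at random inside the search box;
#' integer dimensions are rounded. Fitness is unset (`NA`) until the first
#' evaluation.
#'
#' @param space A [search_space()].
#' @param config An [igwo_config()].
#' @return A list of class `gwo_population` with `positions` (N x dim
#'   matrix), `fitness` (length-N, `NA`), and `iteration` (0).
#' @export
init_population <- function(space, config = igwo_config()) {
  stopifnot(inherits(space, "gwo_space"), inherits(config, "igwo_config"))
  n <- config$pop_size
  pos <- matrix(stats::runif(n * space$dim), nrow = n)
  pos <- sweep(pos, 2L, space$upper - space$lower, `*`)
  pos <- sweep(pos, 2L, space$lower, `+`)
  pos <- clip_to_space(pos, space)
  structure(
    list(positions = pos, fitness = rep(NA_real_, n), iteration = 0L),
    class = "gwo_population"
  )
}

# Cascade the three persistent elites against a population (lower = better).
# Ties are broken toward the incumbent elite, then by agent index.
update_elites <- function(positions, fitness, elites = NULL) {
  if (is.null(elites)) {
    elites <- list(alpha = NULL, beta = NULL, delta = NULL,
                   alpha_fit = Inf, beta_fit = Inf, delta_fit = Inf)
  }
  cand <- which(fitness < elites$delta_fit)
  if (!length(cand)) return(elites)
  for (i in cand[order(fitness[cand], cand)]) {
    f <- fitness[i]
    x <- positions[i, ]
    if (f < elites$alpha_fit) {
      elites$delta <- elites$beta; elites$delta_fit <- elites$beta_fit
      elites$beta <- elites$alpha; elites$beta_fit <- elites$alpha_fit
      elites$alpha <- x; elites$alpha_fit <- f
    } else if (f < elites$beta_fit) {
      elites$delta <- elites$beta; elites$delta_fit <- elites$beta_fit
      elites$beta <- x; elites$beta_fit <- f
    } else if (f < elites$delta_fit) {
      elites$delta <- x; elites$delta_fit <- f
    }
  }
  elites
}

#' One gray-wolf position update
#'
#' Moves every agent to the mean of the three candidate positions pulled
#' toward alpha, beta and delta. Each agent draws one pair of fresh uniform
#' vectors `r1`, `r2` per dimension, giving coefficients `A = 2 a r1 - a`
#' and `C = 2 r2` that are shared across the three elite pulls (the three
#' distances all use the same `C`, the three candidate positions the same
#' `A`). The control scalar decays linearly, `a = 2 (1 - t / max_iter)`.
#' Results are clipped to the box and integer dimensions re-rounded.
#'
#' @param pop A `gwo_population` (or a bare N x dim position matrix).
#' @param elites Elite list as maintained by the optimizer (fields `alpha`,
#'   `beta`, `delta`).
#' @param t Current iteration index, `0 <= t <= max_iter`.
#' @param max_iter Maximum iteration count.
#' @param space The [search_space()] used for clipping.
#' @return Object of the same shape as `pop` with updated positions.
#' @export
gwo_step <- function(pop, elites, t, max_iter, space) {
  mat_in <- is.matrix(pop)
  x <- if (mat_in) pop else pop$positions
  if (t < 0 || t > max_iter) stop("iteration index `t` must lie in [0, max_iter]")
  a <- 2 * (1 - t / max_iter)
  n <- nrow(x); d <- ncol(x)
  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  A <- 2 * a * r1 - a
  C <- 2 * r2
  acc <- matrix(0, n, d)
  for (e in list(elites$alpha, elites$beta, elites$delta)) {
    em <- matrix(e, n, d, byrow = TRUE)
    D <- abs(C * em - x)
    acc <- acc + (em - A * D)
  }
  xn <- clip_to_space(acc / 3, space)
  if (mat_in) return(xn)
  pop$positions <- xn
  pop$iteration <- as.integer(t) + 1L
  pop
}

#' Gaussian resampling scale for omega regeneration
#'
#' The noise magnitude used when an eliminated omega wolf is resampled
#' around the alpha: `sigma(t) = 1 / (t + 1)`, so exploration is widest at
#' the first iteration and decays hyperbolically.
#'
#' @param t Iteration index (0-based).
#' @return The scale `1 / (t + 1)`.
#' @export
omega_sigma <- function(t) 1 / (t + 1)

#' Fitness-based omega regeneration (the IGWO mechanism)
#'
#' Ranks agents by fitness and replaces the worst `floor(r * N)` (never more
#' than `N - 3`): each replacement is, with probability `p`, a copy of one
#' elite drawn with probability proportional to `elite_weights`, and
#' otherwise `alpha + sigma * g` with `g` standard normal and
#' `sigma = 1/(t+1)`. Replacements are clipped to the box and
#' integer-rounded.
#'
#' @inheritParams gwo_step
#' @param fitness Length-N fitness vector for the *current* positions (used
#'   only for ranking when `pop` is a bare matrix; otherwise `pop$fitness`).
#' @param config An [igwo_config()] supplying `elim_fraction`, `elite_prob`
#'   and `elite_weights`.
#' @return Same shape as `pop`, with attributes `"replaced"` (row indices
#'   regenerated) and `"resampled"` (the subset replaced by Gaussian
#'   probes rather than elite copies).
#' @export
igwo_regenerate <- function(pop, elites, config, t, space, fitness = NULL) {
  mat_in <- is.matrix(pop)
  x <- if (mat_in) pop else pop$positions
  f <- if (mat_in) fitness else pop$fitness
  if (is.null(f) || anyNA(f)) stop("fitness must be evaluated before regeneration")
  n <- nrow(x); d <- ncol(x)
  k <- min(floor(config$elim_fraction * n), n - 3L)
  if (k < 1L) {
    attr(x, "replaced") <- integer(0)
    if (mat_in) return(x)
    pop$positions <- x
    return(pop)
  }
  ord <- order(f, seq_len(n)) # best -> worst, ties by agent index
  worst <- ord[(n - k + 1L):n]
  sigma <- omega_sigma(t)
  use_elite <- stats::runif(k) < config$elite_prob
  w <- config$elite_weights / sum(config$elite_weights)
  repl <- matrix(0, k, d)
  ne <- sum(use_elite)
  if (ne) {
    epos <- rbind(elites$alpha, elites$beta, elites$delta)
    choice <- sample.int(3L, ne, replace = TRUE, prob = w)
    repl[use_elite, ] <- epos[choice, , drop = FALSE]
  }
  if (ne < k) {
    ng <- k - ne
    repl[!use_elite, ] <- matrix(elites$alpha, ng, d, byrow = TRUE) +
      sigma * matrix(stats::rnorm(ng * d), ng, d)
  }
  x[worst, ] <- clip_to_space(repl, space)
  attr(x, "replaced") <- worst
  attr(x, "resampled") <- worst[!use_elite]
  if (mat_in) return(x)
  pop$positions <- x
  pop$fitness[worst] <- NA_real_
  pop
}

eval_objective <- function(objective, x, space, vectorized) {
  xe <- x
  if (any(space$integer)) {
    ii <- which(space$integer)
    xe[, ii] <- round(xe[, ii])
  }
  f <- if (vectorized) {
    as.numeric(objective(xe))
  } else {
    vapply(seq_len(nrow(xe)), function(i) as.numeric(objective(xe[i, ]))[1L],
           numeric(1))
  }
  if (length(f) != nrow(xe)) stop("objective returned the wrong number of values")
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f))[1L]
    stop(sprintf("objective returned a non-finite value at position (%s)",
                 paste(signif(xe[bad, ], 6), collapse = ", ")))
  }
  f
}

#' Run the gray wolf optimizer
#'
#' Minimizes `objective` over `space` with either the canonical GWO or the
#' improved variant. Per iteration: evaluate all agents, update the
#' persistent alpha/beta/delta elites, — IGWO only — regenerate the worst
#' omega wolves ([igwo_regenerate()]), then move the pack ([gwo_step()]).
#' Regenerated elite copies join the move immediately (intensifying search
#' around the leaders), while Gaussian-resampled omegas stay where they
#' were placed until evaluated, so the decaying-sigma probes around alpha
#' are scored at their exact positions. With `greedy_memory` (IGWO) an
#' agent reverts a move that worsened its own best-known fitness;
#' regenerated agents always adopt their replacement. The canonical GWO
#' variant is non-greedy and never regenerates.
#'
#' @param objective Function mapping a position to a finite scalar
#'   (minimized). With `vectorized = TRUE` it must instead accept an
#'   N x dim matrix and return N values.
#' @param space A [search_space()].
#' @param config An [igwo_config()].
#' @param variant `"igwo"` (default) or `"gwo"`.
#' @param vectorized Whether `objective` is matrix-vectorized.
#' @return A list of class `gwo_result`: `best_position`, `best_fitness`,
#'   `history` (best-so-far fitness after each of the `max_iter + 1`
#'   evaluation sweeps), `n_evaluations`, `variant`.
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' res <- gwo_optimize(function(x) sum(x^2), sp,
#'                     igwo_config(pop_size = 10, max_iter = 30, seed = 1))
#' res$best_fitness
#' @export
gwo_optimize <- function(objective, space, config = igwo_config(),
                         variant = c("igwo", "gwo"), vectorized = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(space, "gwo_space"), inherits(config, "igwo_config"))
  run <- function() {
    n <- config$pop_size
    T_ <- config$max_iter
    greedy <- variant == "igwo" && config$greedy_memory
    x <- init_population(space, config)$positions
    xmem <- x
    fmem <- rep(Inf, n)
    elites <- NULL
    history <- numeric(T_ + 1L)
    n_eval <- 0L
    for (t in 0:T_) {
      f <- eval_objective(objective, x, space, vectorized)
      n_eval <- n_eval + n
      if (greedy) {
        imp <- f < fmem
        xmem[imp, ] <- x[imp, , drop = FALSE]
        fmem[imp] <- f[imp]
      } else {
        xmem <- x
        fmem <- f
      }
      elites <- update_elites(xmem, fmem, elites)
      history[t + 1L] <- elites$alpha_fit
      if (t == T_) break
      xn <- xmem
      frozen <- integer(0)
      if (variant == "igwo") {
        xn <- igwo_regenerate(xn, elites, config, t, space, fitness = fmem)
        repl <- attr(xn, "replaced")
        # Exploration first, exploitation later: in the first half of the
        # run Gaussian-resampled omegas join the pack move like any other
        # wolf; in the second half they are evaluated exactly where the
        # decaying-sigma probe placed them, refining around alpha.
        if (t >= T_ / 2) frozen <- attr(xn, "resampled")
        if (length(repl)) {
          # a regenerated agent starts fresh: its memory must not veto the
          # replacement at the next evaluation sweep
          fmem[repl] <- Inf
        }
        attr(xn, "replaced") <- NULL
        attr(xn, "resampled") <- NULL
      }
      x <- gwo_step(xn, elites, t, T_, space)
      if (length(frozen)) x[frozen, ] <- xn[frozen, , drop = FALSE]
    }
    structure(
      list(best_position = elites$alpha, best_fitness = elites$alpha_fit,
           history = history, n_evaluations = n_eval, variant = variant),
      class = "gwo_result"
    )
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf("<gwo_result> variant=%s best_fitness=%.6g evaluations=%d\n",
              x$variant, x$best_fitness, x$n_evaluations))
  cat("best_position:", paste(signif(x$best_position, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Convergence trace of an optimizer run
#'
#' @param result A `gwo_result`.
#' @param file Optional path; when given the trace is also written as CSV.
#' @return A data frame with columns `iteration` (0-based) and
#'   `best_fitness`.
#' @export
opt_trace <- function(result, file = NULL) {
  stopifnot(inherits(result, "gwo_result"))
  df <- data.frame(iteration = seq_along(result$history) - 1L,
                   best_fitness = result$history)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
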