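# IGWO-driven hyperparameter search over the 4-dimensional mixed space
# (f1, f2, f3, d): three integer filter counts in [16, 256] and a
# continuous dropout rate in [0.2, 0.8], minimizing the validation loss of
# the CNN trained under the fixed protocol on a patient-grouped stratified
# subset of the training data.

#' The CNN hyperparameter search space
#'
#' @return A [search_space()] with dimensions `(f1, f2, f3, d)`: integers
#'   in 16..256 and a continuous dropout in 0.2..0.8.
#' @export
hpo_space <- function() {
  search_space(lower = c(16, 16, 16, 0.2), upper = c(256, 256, 256, 0.8),
               integer = c(TRUE, TRUE, TRUE, FALSE))
}

decode_hyperparams <- function(x) {
  cnn_hyperparams(round(x[1L]), round(x[2L]), round(x[3L]),
                  min(0.8, max(0.2, x[4L])))
}

#' Hyperparameter-search configuration
#'
#' @param optimizer An [igwo_config()] driving the search. Desk-scale
#'   defaults (`pop_size = 30`, `max_iter = 10`) keep a full search
#'   tractable on one CPU; the reference protocol uses `max_iter = 200`.
#' @param input_size CNN input `(H, W, C)` used for candidate evaluation.
#' @param fitness_subset_fraction Fraction of training patients (grouped,
#'   stratified) fixed once per search as the candidate-training subset.
#' @param epochs_per_candidate Training epochs per candidate (reference
#'   protocol: 50; desk default 5).
#' @param learning_rate Learning rate of the candidate training runs.
#' @param seed Master seed: sub-seeds per candidate are derived from it, so
#'   identical candidates under the same search seed give identical fitness.
#' @return An object of class `hpo_config`.
#' @export
hpo_config <- function(optimizer = igwo_config(pop_size = 30L,
                                               max_iter = 10L),
                       input_size = c(32L, 32L, 3L),
                       fitness_subset_fraction = 0.15,
                       epochs_per_candidate = 5L,
                       learning_rate = 0.005,
                       seed = 1L) {
  stopifnot(fitness_subset_fraction > 0, fitness_subset_fraction <= 1,
            epochs_per_candidate >= 1)
  structure(list(optimizer = optimizer, input_size = as.integer(input_size),
                 fitness_subset_fraction = fitness_subset_fraction,
                 epochs_per_candidate = as.integer(epochs_per_candidate),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "hpo_config")
}

#' Validation loss of one hyperparameter candidate
#'
#' Builds the CNN for `h`, trains it on the data's training images under
#' the fixed protocol, and returns the best validation loss. Deterministic
#' given the same candidate and config seed.
#'
#' @param h A [cnn_hyperparams()] candidate.
#' @param data List with `x_train`, `y_train`, `x_val`, `y_val` (as for
#'   [train_cnn()]).
#' @param cfg An [hpo_config()].
#' @return Scalar validation loss.
#' @export
hpo_objective <- function(h, data, cfg) {
  stopifnot(inherits(h, "cnn_hyperparams"), inherits(cfg, "hpo_config"))
  arch <- build_cnn(h, input_size = cfg$input_size)
  cand_seed <- derive_seed(cfg$seed,
                           h$f1 * 66049 + h$f2 * 257 + h$f3 +
                             round(h$dropout * 1e6))
  tc <- train_config(learning_rate = cfg$learning_rate,
                     epochs = cfg$epochs_per_candidate,
                     patience = 10L, seed = cand_seed)
  m <- tryCatch(
    train_cnn(arch, data$x_train, data$y_train, data$x_val, data$y_val,
              config = tc),
    error = function(e) {
      stop(sprintf("training failed for candidate (%d, %d, %d, %.3f): %s",
                   h$f1, h$f2, h$f3, h$dropout, conditionMessage(e)))
    })
  min(m$history$val_loss, na.rm = TRUE)
}

#' Select the patient-grouped stratified fitness subset
#'
#' Fixes, once per search, the fraction of training patients whose images
#' are used to train each candidate (whole patients, class stratified).
#'
#' @param manifest A split manifest (column `split`).
#' @param fraction Subset fraction of the training patients.
#' @param seed Integer seed.
#' @return Logical vector over manifest rows.
#' @export
fitness_subset <- function(manifest, fraction = 0.15, seed = 1L) {
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  grp <- assign_patients(tr, c(fraction, 1 - fraction), seed)
  manifest$split == "train" & grp[manifest$patient_id] == 1L
}

#' IGWO search over CNN hyperparameters
#'
#' Runs the improved gray wolf optimizer over the 4-dimensional mixed
#' space. Fitness values are cached per decoded candidate, so elite copies
#' and revisited integer-identical candidates cost nothing.
#'
#' @param data As in [hpo_objective()]; ignored when a custom `objective`
#'   is supplied.
#' @param cfg An [hpo_config()].
#' @param objective Optional replacement objective
#'   `function(cnn_hyperparams) -> scalar` (e.g. a surrogate for testing);
#'   defaults to [hpo_objective()] on `data`.
#' @param variant Optimizer variant.
#' @return A list of class `hpo_result`: `best` ([cnn_hyperparams()]),
#'   `best_fitness`, `trace` (data frame of evaluated candidates in
#'   evaluation order: f1, f2, f3, dropout, fitness), `n_evaluations`
#'   (objective calls, cache misses only) and the optimizer result.
#' @export
search_hyperparameters <- function(data = NULL, cfg = hpo_config(),
                                   objective = NULL,
                                   variant = c("igwo", "gwo")) {
  variant <- match.arg(variant)
  stopifnot(inherits(cfg, "hpo_config"))
  if (is.null(objective)) {
    if (is.null(data)) stop("either `data` or `objective` is required")
    objective <- function(h) hpo_objective(h, data, cfg)
  }
  cache <- new.env(parent = emptyenv())
  trace <- list()
  wrapped <- function(x) {
    h <- decode_hyperparams(x)
    key <- sprintf("%d_%d_%d_%.10g", h$f1, h$f2, h$f3, h$dropout)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- objective(h)
    cache[[key]] <- f
    trace[[length(trace) + 1L]] <<- data.frame(
      f1 = h$f1, f2 = h$f2, f3 = h$f3, dropout = h$dropout, fitness = f)
    f
  }
  opt <- cfg$optimizer
  opt$seed <- opt$seed %||% cfg$seed
  res <- gwo_optimize(wrapped, hpo_space(), opt, variant = variant)
  trace <- do.call(rbind, trace)
  structure(list(best = decode_hyperparams(res$best_position),
                 best_fitness = res$best_fitness, trace = trace,
                 n_evaluations = nrow(trace), optimizer_result = res),
            class = "hpo_result")
}

#' Quadratic surrogate objective for exercising the search
#'
#' A cheap stand-in for CNN training with a known optimum:
#' `g(h) = (f1 - t1)^2 + (f2 - t2)^2 + (f3 - t3)^2 + 100 (d - td)^2`. The
#' default target is the best configuration reported for the reference
#' protocol, filters (32, 64, 128) with dropout 0.54.
#'
#' @param target Length-4 target `(f1, f2, f3, d)`.
#' @return `function(cnn_hyperparams) -> scalar`, with attribute `target`.
#' @export
hpo_surrogate <- function(target = c(32, 64, 128, 0.54)) {
  stopifnot(length(target) == 4L)
  f <- function(h) {
    (h$f1 - target[1L])^2 + (h$f2 - target[2L])^2 + (h$f3 - target[3L])^2 +
      100 * (h$dropout - target[4L])^2
  }
  attr(f, "target") <- target
  f
}
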