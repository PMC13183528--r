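test_that("search spaces validate their bounds", {
  expect_error(search_space(c(0, 1), c(1, 1)), "strictly below")
  expect_error(search_space(0, Inf), "finite")
  expect_error(search_space(0.5, 10.5, integer = TRUE), "integer-valued")
  sp <- search_space(c(0, 16), c(1, 256), integer = c(FALSE, TRUE))
  expect_equal(sp$dim, 2L)
})

test_that("initial populations are uniform in the box and reproducible", {
  sp <- search_space(c(0, 0), c(1, 1))
  cfg <- igwo_config(pop_size = 30)
  p <- withr::with_seed(1, init_population(sp, cfg))
  expect_equal(dim(p$positions), c(30L, 2L))
  expect_true(all(p$positions >= 0 & p$positions <= 1))
  expect_true(all(is.na(p$fitness)))

  spi <- search_space(16, 256, integer = TRUE)
  pi_ <- withr::with_seed(2, init_population(spi, cfg))
  expect_true(all(pi_$positions == round(pi_$positions)))
  expect_true(all(pi_$positions >= 16 & pi_$positions <= 256))

  p2 <- withr::with_seed(1, init_population(sp, cfg))
  expect_identical(p$positions, p2$positions)
})

test_that("a wolf pack sitting on a coincident optimum at zero stays put", {
  sp <- search_space(c(-1, -1), c(1, 1))
  x <- matrix(0, 5, 2)
  el <- list(alpha = c(0, 0), beta = c(0, 0), delta = c(0, 0))
  out <- withr::with_seed(1, gwo_step(x, el, t = 3, max_iter = 10, sp))
  expect_equal(out, matrix(0, 5, 2))
})

test_that("the control scalar decays linearly from 2 to 0", {
  # observable through the step: with elites at the origin and an agent at
  # x, X_k = -A * |C * 0 - x| = -A |x|; at t = max_iter, A = 0 exactly
  sp <- search_space(-5, 5)
  el <- list(alpha = 0, beta = 0, delta = 0)
  out_end <- withr::with_seed(1, gwo_step(matrix(3), el, t = 10, max_iter = 10, sp))
  expect_equal(out_end[1, 1], 0) # a = 0 kills the pull entirely
  out_start <- withr::with_seed(1, {
    r1 <- runif(1); r2 <- runif(1)
    expected <- mean(rep(-(2 * 2 * r1 - 2) * abs(2 * r2 * 0 - 3), 3))
    expected
  })
  got <- withr::with_seed(1, gwo_step(matrix(3), el, t = 0, max_iter = 10, sp))
  expect_equal(got[1, 1], max(-5, min(5, out_start)))
  expect_error(gwo_step(matrix(0), el, t = 11, max_iter = 10, sp), "iteration")
})

test_that("one gwo step matches a hand-rolled transcription of the update", {
  # single agent, dim 2: D_k = |C * e_k - x|, X_k = e_k - A * D_k,
  # x' = (X1 + X2 + X3) / 3, with one (r1, r2) pair per dimension shared
  # across the three elite pulls
  sp <- search_space(c(-5, -5), c(5, 5))
  x <- matrix(c(1.5, -2), 1, 2)
  el <- list(alpha = c(0.5, 0.2), beta = c(-1, 1), delta = c(2, -0.3))
  t <- 4; T_ <- 20
  got <- withr::with_seed(99, gwo_step(x, el, t, T_, sp))
  expected <- withr::with_seed(99, {
    a <- 2 * (1 - t / T_)
    r1 <- matrix(runif(2), 1, 2)
    r2 <- matrix(runif(2), 1, 2)
    A <- 2 * a * r1 - a
    C <- 2 * r2
    acc <- 0
    for (e in list(el$alpha, el$beta, el$delta)) {
      acc <- acc + (e - A * abs(C * e - x))
    }
    pmin(pmax(acc / 3, -5), 5)
  })
  expect_equal(got, expected)
})

test_that("omega regeneration replaces floor(r N) agents, never the elites", {
  sp <- search_space(rep(0, 5), rep(1, 5))
  cfg <- igwo_config(pop_size = 30, elim_fraction = 0.3)
  withr::with_seed(11, {
    x <- init_population(sp, cfg)$positions
    f <- runif(30)
    el <- dermwolf:::update_elites(x, f)
    out <- igwo_regenerate(x, el, cfg, t = 2, sp, fitness = f)
    repl <- attr(out, "replaced")
    expect_length(repl, 9L) # floor(0.3 * 30)
    best3 <- order(f)[1:3]
    expect_length(intersect(repl, best3), 0L)
    untouched <- setdiff(seq_len(30), repl)
    expect_identical(out[untouched, ], x[untouched, ])
  })
  # the cap: elimination never reaches the three best agents
  cfg_all <- igwo_config(pop_size = 6, elim_fraction = 1)
  withr::with_seed(12, {
    x <- init_population(sp, cfg_all)$positions
    f <- runif(6)
    el <- dermwolf:::update_elites(x, f)
    out <- igwo_regenerate(x, el, cfg_all, t = 0, sp, fitness = f)
    expect_length(attr(out, "replaced"), 3L) # capped at N - 3
  })
  expect_error(igwo_regenerate(matrix(0, 5, 2), NULL, igwo_config(pop_size = 5),
                               0, search_space(c(0, 0), c(1, 1)),
                               fitness = c(1, NA, 2, 3, 4)),
               "fitness")
})

test_that("with elite probability 1 every replacement is an exact elite copy", {
  sp <- search_space(rep(0, 4), rep(1, 4))
  cfg <- igwo_config(pop_size = 20, elite_prob = 1)
  withr::with_seed(5, {
    x <- init_population(sp, cfg)$positions
    f <- runif(20)
    el <- dermwolf:::update_elites(x, f)
    out <- igwo_regenerate(x, el, cfg, t = 1, sp, fitness = f)
    for (i in attr(out, "replaced")) {
      matches <- vapply(list(el$alpha, el$beta, el$delta),
                        function(e) all(out[i, ] == e), logical(1))
      expect_true(any(matches))
    }
    expect_length(attr(out, "resampled"), 0L)
  })
})

test_that("the resampling scale is 1/(t+1), 1 at t = 0, strictly decreasing", {
  expect_equal(omega_sigma(0), 1)
  s <- omega_sigma(0:50)
  expect_true(all(diff(s) < 0))
  expect_equal(omega_sigma(9), 0.1)
})

test_that("igwo finds the optimum of simple problems", {
  b <- benchmark_function("sphere", 5)
  sp <- search_space(b$lower, b$upper)
  for (s in 1:3) {
    res <- gwo_optimize(b$fn_mat, sp, igwo_config(seed = s), vectorized = TRUE)
    expect_lt(res$best_fitness, 1e-3)
  }
  # integer line search: f(x) = (x - 7)^2 on 0..10; optimum checked by
  # enumerating all 11 candidates
  f <- function(x) (x - 7)^2
  expect_equal(which.min(sapply(0:10, f)) - 1, 7)
  spi <- search_space(0, 10, integer = TRUE)
  ri <- gwo_optimize(f, spi, igwo_config(pop_size = 8, max_iter = 30, seed = 2))
  expect_equal(unname(ri$best_position), 7)
  expect_equal(ri$best_fitness, 0)
})

test_that("a constant objective yields a flat history at that constant", {
  sp <- search_space(c(0, 0), c(1, 1))
  res <- gwo_optimize(function(x) 4.2, sp,
                      igwo_config(pop_size = 6, max_iter = 15, seed = 1))
  expect_equal(res$best_fitness, 4.2)
  expect_true(all(res$history == 4.2))
})

test_that("positions stay inside the box throughout optimization", {
  withr::with_seed(21, {
    for (rep_ in 1:5) {
      d <- sample(1:4, 1)
      lo <- runif(d, -10, 0); hi <- lo + runif(d, 0.5, 10)
      sp <- search_space(lo, hi)
      probe_ok <- TRUE
      obj <- function(X) {
        if (any(sweep(X, 2, lo, `<`) | sweep(X, 2, hi, `>`))) probe_ok <<- FALSE
        rowSums(X^2)
      }
      gwo_optimize(obj, sp, igwo_config(pop_size = 8, max_iter = 25,
                                        seed = rep_), vectorized = TRUE)
      expect_true(probe_ok)
    }
  })
})

test_that("best-ever fitness is non-increasing and runs are reproducible", {
  b <- benchmark_function("rastrigin", 4)
  sp <- search_space(b$lower, b$upper)
  r1 <- gwo_optimize(b$fn_mat, sp, igwo_config(pop_size = 12, max_iter = 40,
                                               seed = 9), vectorized = TRUE)
  expect_true(all(diff(r1$history) <= 0))
  expect_equal(r1$best_fitness, min(r1$history))
  r2 <- gwo_optimize(b$fn_mat, sp, igwo_config(pop_size = 12, max_iter = 40,
                                               seed = 9), vectorized = TRUE)
  expect_identical(r1, r2)
  expect_equal(r1$n_evaluations, 12 * 41)
  tr <- opt_trace(r1)
  expect_equal(nrow(tr), 41L)
  expect_equal(tr$best_fitness, r1$history)
})

test_that("a non-finite objective value is reported with the position", {
  sp <- search_space(c(0, 0), c(1, 1))
  expect_error(
    gwo_optimize(function(x) if (x[1] > 0.1) NaN else 1, sp,
                 igwo_config(pop_size = 5, max_iter = 5, seed = 1)),
    "non-finite value at position")
})
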