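test_that("architecture parameter counts follow the closed form", {
  a <- build_cnn(cnn_hyperparams(32, 64, 128), input_size = c(32, 32, 3))
  expect_equal(a$conv_param_counts, c(896L, 18496L, 73856L))
  expect_equal(a$flatten_dim, 4 * 4 * 128)
  expect_equal(a$param_count, 355778)
  # odd sizes pool with floor division
  b <- build_cnn(cnn_hyperparams(16, 16, 16), input_size = c(225, 225, 3))
  expect_equal(b$shapes[[3]], c(28, 28)) # 225 -> 112 -> 56 -> 28
  expect_error(build_cnn(cnn_hyperparams(), input_size = c(4, 4, 3)),
               "too small")
  expect_error(cnn_hyperparams(8, 64, 128), "16")
  expect_error(cnn_hyperparams(32, 64, 128, dropout = 1), "dropout")
})

test_that("class weights are inversely proportional to frequency", {
  w <- class_weights(c("benign", "benign", "benign", "malignant"))
  expect_equal(unname(w), c(4 / 6, 2))
  wb <- class_weights(rep(c("benign", "malignant"), 5))
  expect_equal(unname(wb), c(1, 1))
  labs <- c(rep("benign", 7), rep("malignant", 3))
  w2 <- class_weights(labs)
  expect_equal(mean(w2[labs]), 1) # weighted mean of sample weights is 1
  expect_error(class_weights(rep("benign", 4)), "both classes")
})

test_that("softmax probabilities normalize and match closed forms", {
  p <- dermwolf:::softmax_probs(matrix(c(0, 0), 1, 2))
  expect_equal(as.vector(p), c(0.5, 0.5))
  p2 <- dermwolf:::softmax_probs(matrix(c(log(3), 0), 1, 2))
  expect_equal(as.vector(p2), c(0.75, 0.25))
  withr::with_seed(3, {
    lg <- matrix(rnorm(20, sd = 5), 10, 2)
    pp <- dermwolf:::softmax_probs(lg)
    expect_equal(rowSums(pp), rep(1, 10), tolerance = 1e-6)
  })
})

test_that("the squared-error measure matches its definition", {
  expect_equal(cnn_error(matrix(c(0, 1), 1), "malignant"), 0)
  expect_equal(cnn_error(matrix(c(0.6, 0.4), 1), "benign"), 0.32)
  withr::with_seed(5, {
    sc <- dermwolf:::softmax_probs(matrix(rnorm(12), 6, 2))
    y <- sample(c("benign", "malignant"), 6, replace = TRUE)
    expect_gte(cnn_error(sc, y), 0)
  })
  expect_error(cnn_error(matrix(0.5, 2, 2), "benign"), "mismatch")
})

test_that("analytic gradients agree with finite differences", {
  arch <- build_cnn(cnn_hyperparams(16, 16, 16, 0), input_size = c(8, 8, 1),
                    dense_units = 8)
  withr::with_seed(42, {
    params <- dermwolf:::init_cnn_params(arch)
    x <- array(runif(8 * 8 * 1 * 3), c(8, 8, 1, 3))
    y <- c(0L, 1L, 1L)
    w <- c(1.2, 0.8, 0.8)
    wp <- 0.01
    lossfn <- function(p) {
      fwd <- dermwolf:::cnn_forward(p, arch, x)
      dermwolf:::cnn_loss(dermwolf:::softmax_probs(fwd$logits), y, w, p, wp)
    }
    fwd <- dermwolf:::cnn_forward(params, arch, x)
    g <- dermwolf:::cnn_backward(params, arch, fwd, y, w, wp)
    eps <- 1e-6
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("a zero weight penalty reduces the loss to plain cross-entropy", {
  withr::with_seed(7, {
    arch <- build_cnn(cnn_hyperparams(16, 16, 16, 0), input_size = c(8, 8, 1),
                      dense_units = 8)
    params <- dermwolf:::init_cnn_params(arch)
    probs <- dermwolf:::softmax_probs(matrix(rnorm(8), 4, 2))
    y <- c(0L, 1L, 0L, 1L)
    w <- rep(1, 4)
    plain <- dermwolf:::cnn_loss(probs, y, w)
    with0 <- dermwolf:::cnn_loss(probs, y, w, params, wp = 0)
    expect_identical(plain, with0)
    wsum <- sum(vapply(params[grep("^W", names(params))],
                       function(m) sum(m^2), numeric(1)))
    expect_equal(dermwolf:::cnn_loss(probs, y, w, params, wp = 0.1),
                 plain + 0.05 * wsum)
  })
})

test_that("training learns a separable toy problem quickly", {
  toy <- toy_intensity_set(64, seed = 3, side = 16)
  arch <- build_cnn(cnn_hyperparams(16, 16, 16, 0.2), c(16, 16, 3),
                    dense_units = 16)
  m <- train_cnn(arch, toy$x, toy$y,
                 config = train_config(learning_rate = 0.01, epochs = 10,
                                       seed = 1))
  pb <- predict_cnn(m, toy$x)
  expect_equal(mean(pb$labels == toy$y), 1)
  expect_equal(rowSums(pb$scores), rep(1, 64), tolerance = 1e-6)
})

test_that("training is reproducible and early stopping respects patience", {
  toy <- toy_intensity_set(40, seed = 6, side = 16)
  val <- toy_intensity_set(20, seed = 7, side = 16)
  arch <- build_cnn(cnn_hyperparams(16, 16, 16, 0.3), c(16, 16, 3),
                    dense_units = 16)
  cfg <- train_config(learning_rate = 0.01, epochs = 30, patience = 3,
                      seed = 4)
  m1 <- train_cnn(arch, toy$x, toy$y, val$x, val$y, config = cfg)
  m2 <- train_cnn(arch, toy$x, toy$y, val$x, val$y, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  n <- nrow(m1$history)
  if (n < 30) {
    # halted: the last `patience` epochs did not improve on the best
    best <- min(m1$history$val_loss)
    expect_true(all(utils::tail(m1$history$val_loss, 3) >= best))
  }
  # restored checkpoint has the best validation loss seen
  ev <- dermwolf:::evaluate_cnn(m1$params, arch, val$x,
                                dermwolf:::as_y01(val$y))
  expect_equal(ev$loss, min(m1$history$val_loss), tolerance = 1e-10)
})

test_that("class weighting lifts minority recall on an imbalanced toy set", {
  wins <- 0
  for (s in 1:3) {
    toy <- toy_imbalanced_set(80, 0.15, seed = 100 + s)
    arch <- build_cnn(cnn_hyperparams(16, 16, 16, 0.2), c(16, 16, 3),
                      dense_units = 16)
    rec <- sapply(c(TRUE, FALSE), function(cw) {
      m <- train_cnn(arch, toy$x, toy$y,
                     config = train_config(learning_rate = 0.01, epochs = 6,
                                           class_weighted = cw, seed = s))
      pb <- predict_cnn(m, toy$x)
      cc <- confusion(pb$labels, toy$y)
      if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else 0
    })
    if (rec[1] >= rec[2]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("prediction validates input dimensions", {
  toy <- toy_intensity_set(8, seed = 9, side = 16)
  arch <- build_cnn(cnn_hyperparams(16, 16, 16, 0.2), c(16, 16, 3),
                    dense_units = 8)
  m <- train_cnn(arch, toy$x, toy$y,
                 config = train_config(epochs = 1, seed = 1))
  expect_error(predict_cnn(m, array(0, c(8, 8, 3, 2))), "input size")
  pc <- predict(m, toy$x, type = "class")
  expect_true(all(pc %in% c("benign", "malignant")))
})
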