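# A compact convolutional network for benign/malignant lesion
# classification: three {3x3 same-padding conv, ReLU, 2x2 max-pool} blocks,
# a 128-unit ReLU dense layer, dropout, and a 2-way softmax head, trained
# with class-weighted categorical cross-entropy under RMSprop with early
# stopping. Implemented directly in R: convolutions are lowered to
# BLAS-backed matrix products over im2col patch matrices, and gradients are
# verified against finite differences in the test suite.

#' CNN hyperparameters
#'
#' The four quantities exposed to the hyperparameter search: the filter
#' counts of the three convolutional layers (integers in 16..256) and the
#' dropout rate of the dense head (continuous in 0.2..0.8).
#'
#' @param f1,f2,f3 Filter counts.
#' @param dropout Dropout rate.
#' @return An object of class `cnn_hyperparams`.
#' @export
cnn_hyperparams <- function(f1 = 32L, f2 = 64L, f3 = 128L, dropout = 0.5) {
  f <- c(f1, f2, f3)
  if (any(f != round(f)) || any(f < 16) || any(f > 256)) {
    stop("filter counts must be integers in [16, 256]")
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must lie in [0, 1)")
  structure(list(f1 = as.integer(f1), f2 = as.integer(f2),
                 f3 = as.integer(f3), dropout = as.numeric(dropout)),
            class = "cnn_hyperparams")
}

#' Build the CNN architecture descriptor
#'
#' Computes layer shapes and the closed-form trainable parameter count for
#' the fixed topology: 3 conv blocks (3x3 kernels, same padding, ReLU,
#' 2x2 max-pool with floor division) followed by flatten, a dense ReLU
#' layer, dropout, and a 2-unit softmax output.
#'
#' @param hyper A [cnn_hyperparams()].
#' @param input_size Integer `(H, W, C)`; default `c(225, 225, 3)`.
#' @param dense_units Width of the penultimate dense layer (default 128).
#' @return An object of class `cnn_arch` with fields `input_size`,
#'   `filters`, `dropout`, `dense_units`, `shapes` (per-block spatial
#'   sizes), `flatten_dim`, and `param_count`.
#' @examples
#' a <- build_cnn(cnn_hyperparams(32, 64, 128), input_size = c(32, 32, 3))
#' a$param_count # 355778
#' @export
build_cnn <- function(hyper = cnn_hyperparams(),
                      input_size = c(225L, 225L, 3L), dense_units = 128L) {
  stopifnot(inherits(hyper, "cnn_hyperparams"))
  input_size <- as.integer(input_size)
  if (length(input_size) != 3L || !input_size[3L] %in% c(1L, 3L)) {
    stop("`input_size` must be (H, W, C) with C = 1 or 3")
  }
  h <- input_size[1L]; w <- input_size[2L]
  shapes <- list()
  for (i in 1:3) {
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1L || w < 1L) stop("input too small for three 2x2 poolings")
    shapes[[i]] <- c(h, w)
  }
  f <- c(hyper$f1, hyper$f2, hyper$f3)
  cin <- c(input_size[3L], f[1L], f[2L])
  conv_params <- 9L * cin * f + f
  flatten_dim <- shapes[[3L]][1L] * shapes[[3L]][2L] * f[3L]
  dense_params <- c(flatten_dim * dense_units + dense_units,
                    dense_units * 2L + 2L)
  structure(
    list(input_size = input_size, filters = f, dropout = hyper$dropout,
         dense_units = as.integer(dense_units), shapes = shapes,
         flatten_dim = as.integer(flatten_dim),
         conv_param_counts = as.integer(conv_params),
         param_count = sum(conv_params) + sum(dense_params)),
    class = "cnn_arch"
  )
}

#' @export
print.cnn_arch <- function(x, ...) {
  cat(sprintf(
    "<cnn_arch> input %dx%dx%d | conv %s (3x3, same, relu, pool 2x2) | dense %d | dropout %.2f | softmax 2\n",
    x$input_size[1L], x$input_size[2L], x$input_size[3L],
    paste(x$filters, collapse = "/"), x$dense_units, x$dropout))
  cat(sprintf("trainable parameters: %s\n",
              format(x$param_count, big.mark = ",")))
  invisible(x)
}

# He-normal initialization of all trainable tensors. Conv weights are
# stored as (9 * c_in) x f matrices, rows blocked by kernel offset
# (dy = -1..1 fastest, then dx), each block holding the c_in channels.
init_cnn_params <- function(arch) {
  f <- arch$filters
  cin <- c(arch$input_size[3L], f[1L], f[2L])
  p <- list()
  for (i in 1:3) {
    fan_in <- 9L * cin[i]
    p[[paste0("Wc", i)]] <- matrix(
      stats::rnorm(fan_in * f[i], sd = sqrt(2 / fan_in)), fan_in, f[i])
    p[[paste0("bc", i)]] <- numeric(f[i])
  }
  p$Wd1 <- matrix(stats::rnorm(arch$flatten_dim * arch$dense_units,
                               sd = sqrt(2 / arch$flatten_dim)),
                  arch$flatten_dim, arch$dense_units)
  p$bd1 <- numeric(arch$dense_units)
  p$Wd2 <- matrix(stats::rnorm(arch$dense_units * 2L,
                               sd = sqrt(2 / arch$dense_units)),
                  arch$dense_units, 2L)
  p$bd2 <- numeric(2L)
  p
}

# Activations flow through the network as (H, W, B, C) arrays: with the
# batch on the third axis, im2col patch matrices and conv outputs are plain
# reshapes (no transposition), so the convolution is two BLAS calls plus
# sub-array copies.

# Interior-pixel row indices of the zero-padded (H+2) x (W+2) plane,
# flattened column-major; shifting by an offset (dy, dx) is then integer
# arithmetic on this vector and patch extraction is fast matrix
# row-indexing.
pad_interior_idx <- function(h, w) {
  as.vector(outer(2:(h + 1L), 2:(w + 1L),
                  function(i, j) i + (j - 1L) * (h + 2L)))
}

# im2col for 3x3 same padding on an (H, W, B, C) array: returns
# (H*W*B) x (9*C) with column blocks ordered by offset (dy fastest).
im2col3 <- function(x) {
  d <- dim(x); h <- d[1L]; w <- d[2L]; b <- d[3L]; cc <- d[4L]
  idx <- pad_interior_idx(h, w)
  xp <- matrix(0, (h + 2L) * (w + 2L), b * cc)
  xp[idx, ] <- x
  cols <- matrix(0, h * w * b, 9L * cc)
  o <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    o <- o + 1L
    blk <- xp[idx + dy + dx * (h + 2L), , drop = FALSE] # (HW) x (B*C)
    dim(blk) <- NULL
    cols[, ((o - 1L) * cc + 1L):(o * cc)] <- blk
  }
  cols
}

col2im3 <- function(dcols, h, w, b, cc) {
  idx <- pad_interior_idx(h, w)
  dxp <- matrix(0, (h + 2L) * (w + 2L), b * cc)
  o <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    o <- o + 1L
    blk <- matrix(dcols[, ((o - 1L) * cc + 1L):(o * cc)], h * w, b * cc)
    sh <- idx + dy + dx * (h + 2L)
    dxp[sh, ] <- dxp[sh, , drop = FALSE] + blk
  }
  array(dxp[idx, , drop = FALSE], c(h, w, b, cc))
}

conv_fwd <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  out <- cols %*% W
  out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
  nf <- length(b)
  list(out = array(out, c(d[1L], d[2L], d[3L], nf)), cols = cols, xdim = d)
}

conv_bwd <- function(dout, cache, W) {
  d <- cache$xdim
  nf <- dim(dout)[4L]
  dM <- matrix(dout, d[1L] * d[2L] * d[3L], nf)
  dW <- crossprod(cache$cols, dM)
  db <- colSums(dM)
  dcols <- tcrossprod(dM, W)
  dx <- col2im3(dcols, d[1L], d[2L], d[3L], d[4L])
  list(dx = dx, dW = dW, db = db)
}

pool_fwd <- function(x) {
  d <- dim(x)
  ho <- d[1L] %/% 2L; wo <- d[2L] %/% 2L
  ri <- seq_len(ho) * 2L; ci <- seq_len(wo) * 2L
  a <- x[ri - 1L, ci - 1L, , , drop = FALSE]
  b <- x[ri, ci - 1L, , , drop = FALSE]
  cc <- x[ri - 1L, ci, , , drop = FALSE]
  dd <- x[ri, ci, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  list(out = m, eq = list(a == m, b == m, cc == m, dd == m), xdim = d)
}

pool_bwd <- function(dout, cache) {
  d <- cache$xdim
  ho <- dim(dout)[1L]; wo <- dim(dout)[2L]
  ri <- seq_len(ho) * 2L; ci <- seq_len(wo) * 2L
  eq <- cache$eq
  # route each gradient to the first maximal cell (deterministic ties)
  ka <- eq[[1L]]
  kb <- eq[[2L]] & !ka
  kc <- eq[[3L]] & !ka & !kb
  kd <- eq[[4L]] & !ka & !kb & !kc
  dx <- array(0, d)
  dx[ri - 1L, ci - 1L, , ] <- dout * ka
  dx[ri, ci - 1L, , ] <- dout * kb
  dx[ri - 1L, ci, , ] <- dout * kc
  dx[ri, ci, , ] <- dout * kd
  dx
}

# forward pass through the whole network
# x: H x W x C x B array scaled to [0, 1]; returns logits and caches
cnn_forward <- function(params, arch, x, dropout_mask = NULL) {
  caches <- list()
  a <- aperm(x, c(1L, 2L, 4L, 3L)) # internal (H, W, B, C) layout
  for (i in 1:3) {
    cv <- conv_fwd(a, params[[paste0("Wc", i)]], params[[paste0("bc", i)]])
    r <- cv$out
    relu_mask <- r > 0
    r[!relu_mask] <- 0
    pl <- pool_fwd(r)
    caches[[i]] <- list(conv = cv, relu = relu_mask, pool = pl)
    a <- pl$out
  }
  d <- dim(a)
  b <- d[3L]
  flat <- t(matrix(aperm(a, c(1L, 2L, 4L, 3L)),
                   d[1L] * d[2L] * d[4L], b)) # B x flatten_dim
  z1 <- flat %*% params$Wd1 +
    matrix(params$bd1, b, arch$dense_units, byrow = TRUE)
  relu1 <- z1 > 0
  h1 <- z1
  h1[!relu1] <- 0
  if (!is.null(dropout_mask)) {
    h1 <- h1 * dropout_mask / (1 - arch$dropout)
  }
  logits <- h1 %*% params$Wd2 + matrix(params$bd2, b, 2L, byrow = TRUE)
  list(logits = logits,
       cache = list(blocks = caches, flat = flat, relu1 = relu1, h1 = h1,
                    pooled_dim = d, dropout_mask = dropout_mask))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# class-weighted categorical cross-entropy (mean over the batch) plus an
# optional L2 weight penalty wp/2 * sum(W^2) over weight matrices
cnn_loss <- function(probs, y01, sample_w, params = NULL, wp = 0) {
  b <- nrow(probs)
  ll <- -log(pmax(probs[cbind(seq_len(b), y01 + 1L)], 1e-12))
  loss <- mean(sample_w * ll)
  if (wp > 0 && !is.null(params)) {
    wsum <- sum(vapply(params[grep("^W", names(params))],
                       function(w) sum(w^2), numeric(1)))
    loss <- loss + wp / 2 * wsum
  }
  loss
}

cnn_backward <- function(params, arch, fwd, y01, sample_w, wp = 0) {
  b <- nrow(fwd$logits)
  probs <- softmax_probs(fwd$logits)
  Y <- matrix(0, b, 2L)
  Y[cbind(seq_len(b), y01 + 1L)] <- 1
  dlogits <- (probs - Y) * (sample_w / b)
  cache <- fwd$cache
  g <- list()
  g$Wd2 <- crossprod(cache$h1, dlogits)
  g$bd2 <- colSums(dlogits)
  dh1 <- tcrossprod(dlogits, params$Wd2)
  if (!is.null(cache$dropout_mask)) {
    dh1 <- dh1 * cache$dropout_mask / (1 - arch$dropout)
  }
  dz1 <- dh1 * cache$relu1
  g$Wd1 <- crossprod(cache$flat, dz1)
  g$bd1 <- colSums(dz1)
  dflat <- tcrossprod(dz1, params$Wd1)
  d <- cache$pooled_dim
  da <- aperm(array(t(dflat), c(d[1L], d[2L], d[4L], d[3L])),
              c(1L, 2L, 4L, 3L))
  for (i in 3:1) {
    blk <- cache$blocks[[i]]
    dr <- pool_bwd(da, blk$pool)
    dr <- dr * blk$relu
    cb <- conv_bwd(dr, blk$conv, params[[paste0("Wc", i)]])
    g[[paste0("Wc", i)]] <- cb$dW
    g[[paste0("bc", i)]] <- cb$db
    da <- cb$dx
  }
  if (wp > 0) {
    for (nm in grep("^W", names(params), value = TRUE)) {
      g[[nm]] <- g[[nm]] + wp * params[[nm]]
    }
  }
  g
}

#' Per-class weights inversely proportional to class frequency
#'
#' `w_c = n_total / (2 n_c)`, so the weighted mean over samples is 1 and
#' the minority class is up-weighted.
#'
#' @param labels Vector of `"benign"` / `"malignant"` labels (factor or
#'   character); both classes must be present.
#' @return Named numeric vector `c(benign = ..., malignant = ...)`.
#' @examples
#' class_weights(c("benign", "benign", "benign", "malignant"))
#' @export
class_weights <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  n <- length(labels)
  nb <- sum(labels == "benign")
  nm <- n - nb
  if (nb == 0L || nm == 0L) {
    stop("both classes must be present to compute class weights")
  }
  c(benign = n / (2 * nb), malignant = n / (2 * nm))
}

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: RMSprop with learning rate
#' 0.001, rho 0.9, epsilon 1e-7, batches of 32, up to 50 epochs with early
#' stopping at patience 10 on validation loss, and class-weighted
#' cross-entropy.
#'
#' @param learning_rate,rho,epsilon RMSprop settings.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); ignored when no validation split is given.
#' @param weight_penalty L2 penalty `wp` on weight matrices (0 disables).
#' @param class_weighted Whether to weight the loss by [class_weights()].
#' @param seed Optional integer seed making training fully reproducible.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, rho = 0.9, epsilon = 1e-7,
                         batch_size = 32L, epochs = 50L, patience = 10L,
                         weight_penalty = 0, class_weighted = TRUE,
                         seed = NULL) {
  stopifnot(learning_rate > 0, rho > 0, rho < 1, epsilon > 0,
            batch_size >= 1, epochs >= 1, patience >= 0,
            weight_penalty >= 0)
  structure(list(learning_rate = learning_rate, rho = rho,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 weight_penalty = weight_penalty,
                 class_weighted = isTRUE(class_weighted),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "train_config")
}

as_y01 <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  bad <- setdiff(unique(y), c("benign", "malignant"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  as.integer(y == "malignant")
}

as_x01 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("images must be an H x W x C x N array")
  if (max(x) > 1) x <- x / 255
  x
}

#' Train the CNN
#'
#' Minimizes class-weighted categorical cross-entropy (plus an optional L2
#' weight penalty) with RMSprop mini-batch updates, early-stopping on the
#' validation loss and restoring the best-validation weights.
#'
#' @param arch A [build_cnn()] architecture.
#' @param x Training images, `H x W x C x N` array (0..255 or already in
#'   `[0, 1]`), matching `arch$input_size`.
#' @param y Training labels (`"benign"`/`"malignant"`, factor, or 0/1 with
#'   1 = malignant).
#' @param x_val,y_val Optional validation split (enables early stopping).
#' @param config A [train_config()].
#' @return An object of class `dermwolf_cnn`: trained parameters, the
#'   architecture, a per-epoch `history` data frame (train/val loss and
#'   accuracy), `best_epoch`, and the class-weight vector used.
#' @export
train_cnn <- function(arch, x, y, x_val = NULL, y_val = NULL,
                      config = train_config()) {
  stopifnot(inherits(arch, "cnn_arch"), inherits(config, "train_config"))
  run <- function() {
    x <- as_x01(x)
    y01 <- as_y01(y)
    n <- dim(x)[4L]
    if (n == 0L || length(y01) != n) stop("empty split or label length mismatch")
    has_val <- !is.null(x_val)
    if (has_val) {
      x_val <- as_x01(x_val)
      yv01 <- as_y01(y_val)
    }
    cw <- c(benign = 1, malignant = 1)
    if (config$class_weighted) {
      cw <- class_weights(ifelse(y01 == 1L, "malignant", "benign"))
    }
    sample_w_all <- unname(cw[y01 + 1L])
    params <- init_cnn_params(arch)
    vstate <- lapply(params, function(p) p * 0)
    wp <- config$weight_penalty
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    hist <- vector("list", config$epochs)
    n_epochs_run <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      nb <- ceiling(n / config$batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):
                     min(bi * config$batch_size, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y01[idx]
        wb <- sample_w_all[idx]
        dmask <- if (arch$dropout > 0) {
          matrix(stats::runif(length(idx) * arch$dense_units) >= arch$dropout,
                 length(idx), arch$dense_units)
        }
        fwd <- cnn_forward(params, arch, xb, dropout_mask = dmask)
        probs <- softmax_probs(fwd$logits)
        ep_loss <- ep_loss + cnn_loss(probs, yb, wb, params, wp) * length(idx)
        ep_correct <- ep_correct +
          sum((probs[, 2L] > probs[, 1L]) == (yb == 1L))
        grads <- cnn_backward(params, arch, fwd, yb, wb, wp)
        for (nm in names(params)) {
          g <- grads[[nm]]
          vstate[[nm]] <- config$rho * vstate[[nm]] + (1 - config$rho) * g^2
          params[[nm]] <- params[[nm]] -
            config$learning_rate * g / (sqrt(vstate[[nm]]) + config$epsilon)
        }
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                        train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        ev <- evaluate_cnn(params, arch, x_val, yv01)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
        if (ev$loss < best$loss) {
          best <- list(loss = ev$loss, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist[[ep]] <- row
      n_epochs_run <- ep
      if (has_val && wait >= config$patience && config$patience > 0L) break
    }
    if (has_val && is.finite(best$loss)) {
      params <- best$params
    } else {
      best$epoch <- n_epochs_run
    }
    structure(
      list(arch = arch, params = params,
           history = do.call(rbind, hist[seq_len(n_epochs_run)]),
           best_epoch = best$epoch, class_weights = cw, config = config,
           classes = c("benign", "malignant")),
      class = "dermwolf_cnn"
    )
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# unweighted loss and accuracy of `params` on a labelled set
evaluate_cnn <- function(params, arch, x, y01, batch_size = 128L) {
  x <- as_x01(x)
  n <- dim(x)[4L]
  loss <- 0
  correct <- 0L
  for (bi in seq_len(ceiling(n / batch_size))) {
    idx <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)
    fwd <- cnn_forward(params, arch, x[, , , idx, drop = FALSE])
    probs <- softmax_probs(fwd$logits)
    loss <- loss + cnn_loss(probs, y01[idx], rep(1, length(idx))) * length(idx)
    correct <- correct + sum((probs[, 2L] > probs[, 1L]) == (y01[idx] == 1L))
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict with a trained CNN
#'
#' Runs the network in inference mode (no dropout) and returns the softmax
#' class probabilities, the raw logits, and hard labels.
#'
#' @param model A trained [train_cnn()] model.
#' @param x Images, `H x W x C x N` array.
#' @param batch_size Inference batch size.
#' @return A list of class `prediction_batch`: `scores` (N x 2 matrix,
#'   columns `benign`, `malignant`, rows summing to 1), `logits` (N x 2),
#'   and `labels` (character vector).
#' @export
predict_cnn <- function(model, x, batch_size = 128L) {
  stopifnot(inherits(model, "dermwolf_cnn"))
  x <- as_x01(x)
  n <- dim(x)[4L]
  if (!all(dim(x)[1:3] == model$arch$input_size)) {
    stop("image dimensions do not match the architecture input size")
  }
  scores <- logits <- matrix(0, n, 2L,
                             dimnames = list(NULL, model$classes))
  for (bi in seq_len(ceiling(n / batch_size))) {
    idx <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)
    fwd <- cnn_forward(model$params, model$arch, x[, , , idx, drop = FALSE])
    logits[idx, ] <- fwd$logits
    scores[idx, ] <- softmax_probs(fwd$logits)
  }
  structure(list(scores = scores, logits = logits,
                 labels = model$classes[max.col(scores, ties.method = "first")]),
            class = "prediction_batch")
}

#' @export
predict.dermwolf_cnn <- function(object, newdata,
                                 type = c("batch", "prob", "class"), ...) {
  type <- match.arg(type)
  pb <- predict_cnn(object, newdata)
  switch(type, batch = pb, prob = pb$scores, class = pb$labels)
}

#' Mean squared prediction error
#'
#' `E = (1/T) * sum_i sum_j (f_ji - y_ji)^2` over the one-hot targets `f`
#' and predicted probabilities `y`, averaged over the `T` samples (not over
#' classes). A separate quality measure, not the training loss.
#'
#' @param pred A `prediction_batch` (or an N x 2 score matrix).
#' @param targets Labels (`"benign"`/`"malignant"` or 0/1) or an N x 2
#'   one-hot matrix.
#' @return Non-negative scalar.
#' @examples
#' cnn_error(matrix(c(0.6, 0.4), 1), "benign") # 2 * 0.4^2 = 0.32
#' @export
cnn_error <- function(pred, targets) {
  scores <- if (inherits(pred, "prediction_batch")) pred$scores else
    as.matrix(pred)
  if (is.matrix(targets)) {
    f <- targets
  } else {
    y01 <- as_y01(targets)
    f <- matrix(0, length(y01), 2L)
    f[cbind(seq_along(y01), y01 + 1L)] <- 1
  }
  if (nrow(f) != nrow(scores)) stop("prediction/target length mismatch")
  sum((f - scores)^2) / nrow(scores)
}
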