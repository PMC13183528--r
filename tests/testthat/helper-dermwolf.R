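# Shared fixtures, all generated in code.

# bimodal 8-bit test image built from two Gaussian intensity modes
bimodal_image <- function(m1 = 70, m2 = 180, s1 = 12, s2 = 12, seed = 7,
                          side = 63) {
  withr::with_seed(seed, {
    v <- c(round(stats::rnorm(2000, m1, s1)), round(stats::rnorm(2000, m2, s2)))
    v <- pmin(255, pmax(0, v))
    matrix(v[sample(length(v))][seq_len(side^2)], side, side)
  })
}

# independent queue-based flood fill from the border through FALSE cells,
# 8-connected; used as the hole-filling oracle
flood_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  visited <- matrix(FALSE, h, w)
  queue <- which(!mask & (row(mask) %in% c(1, h) | col(mask) %in% c(1, w)))
  visited[queue] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    r <- (i - 1L) %% h + 1L; cc <- (i - 1L) %/% h + 1L
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w) {
        j <- rr + (ccc - 1L) * h
        if (!mask[j] && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  mask | !visited
}

random_blob_mask <- function(seed, side = 24, p = 0.35) {
  withr::with_seed(seed, matrix(stats::runif(side^2) < p, side, side))
}

# separable toy set: class differs by mean intensity
toy_intensity_set <- function(n, seed, side = 16, means = c(180, 80),
                              sd = 15) {
  withr::with_seed(seed, {
    y <- rep(c("benign", "malignant"), length.out = n)
    x <- array(0, c(side, side, 3, n))
    for (i in seq_len(n)) {
      base <- if (y[i] == "benign") means[1] else means[2]
      x[, , , i] <- pmin(255, pmax(0, base + stats::rnorm(side^2 * 3, sd = sd)))
    }
    list(x = x, y = y)
  })
}

# imbalanced separable toy set (bright squares vs dark squares)
toy_imbalanced_set <- function(n, frac_pos, seed, side = 16) {
  withr::with_seed(seed, {
    npos <- round(n * frac_pos)
    y <- rep("benign", n)
    y[sample.int(n, npos)] <- "malignant"
    x <- array(0, c(side, side, 3, n))
    for (i in seq_len(n)) {
      base <- if (y[i] == "malignant") 70 else 170
      x[, , , i] <- pmin(255, pmax(0, base + stats::rnorm(side^2 * 3, sd = 25)))
    }
    list(x = x, y = y)
  })
}
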