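# Seeded generators: dermoscopy-like lesion images with exact ground-truth
# masks, hair artifacts, dataset manifests with patient grouping, and the
# standard optimizer benchmark functions. These emulate the salient
# structure of dermoscopic melanoma datasets -- two-class lesions with
# strong class imbalance, hair artifacts, low contrast and patient grouping
# -- so the rest of the package is testable without any external download.

derive_seed <- function(seed, index) {
  as.integer(((as.numeric(seed) %% 1000003) * 8191 +
                as.numeric(index) * 97003) %% 2147483646 + 1)
}

#' Parameters of the synthetic lesion generator
#'
#' Describes one class of lesion image: a radially perturbed, rotated
#' ellipse (the lesion) composited over noisy skin-toned background. Border
#' irregularity is a low-order Fourier perturbation of the ellipse radius
#' (harmonics 3..8); asymmetry adds low-order (1st/2nd harmonic) lobes.
#' Malignant-like lesions are encoded by high irregularity and asymmetry,
#' higher intra-lesion intensity variance, and dark pigment blotches -- not
#' by mean intensity alone -- so a classifier must learn shape and texture.
#'
#' @param size Image side length in pixels (square images).
#' @param bg_mean Background mean intensity per RGB channel (length 3) or a
#'   single gray level.
#' @param bg_sd Background Gaussian noise sd.
#' @param lesion_mean Lesion mean intensity per channel (length 3) or gray.
#' @param lesion_sd Intra-lesion Gaussian noise sd (texture strength).
#' @param axes_frac Range (min, max) of ellipse semi-axes as a fraction of
#'   `size`.
#' @param irregularity Border irregularity amplitude in [0, 0.5]: maximal
#'   radial perturbation as a fraction of the local radius.
#' @param asymmetry Asymmetry amplitude in [0, 0.5] (1st/2nd-harmonic
#'   radial lobes).
#' @param n_harmonics Integer vector of Fourier harmonics used for the
#'   irregular border.
#' @param blotch_count Number of dark pigment blotches inside the lesion.
#' @param blotch_contrast Peak darkening of a blotch (intensity levels).
#' @param contrast_compress Factor in (0, 1]: 1 leaves intensities alone,
#'   smaller values compress them towards mid-gray to emulate low-contrast
#'   acquisition.
#' @return An object of class `lesion_params`.
#' @export
lesion_params <- function(size = 64L,
                          bg_mean = c(200, 165, 150), bg_sd = 6,
                          lesion_mean = c(115, 85, 70), lesion_sd = 10,
                          axes_frac = c(0.22, 0.34),
                          irregularity = 0.05, asymmetry = 0.04,
                          n_harmonics = 3:8,
                          blotch_count = 0L, blotch_contrast = 0,
                          contrast_compress = 1) {
  if (irregularity < 0 || irregularity > 0.5) {
    stop("`irregularity` must lie in [0, 0.5]")
  }
  if (asymmetry < 0 || asymmetry > 0.5) stop("`asymmetry` must lie in [0, 0.5]")
  if (contrast_compress <= 0 || contrast_compress > 1) {
    stop("`contrast_compress` must lie in (0, 1]")
  }
  if (mean(lesion_mean) >= mean(bg_mean)) {
    stop("the lesion must be darker than the background")
  }
  structure(
    list(size = as.integer(size), bg_mean = bg_mean, bg_sd = bg_sd,
         lesion_mean = lesion_mean, lesion_sd = lesion_sd,
         axes_frac = axes_frac, irregularity = irregularity,
         asymmetry = asymmetry, n_harmonics = as.integer(n_harmonics),
         blotch_count = as.integer(blotch_count),
         blotch_contrast = blotch_contrast,
         contrast_compress = contrast_compress),
    class = "lesion_params"
  )
}

#' @rdname lesion_params
#' @param ... Overrides passed on to [lesion_params()].
#' @export
benign_lesion_params <- function(size = 64L, ...) {
  args <- utils::modifyList(
    list(size = size, irregularity = 0.04, asymmetry = 0.03,
         lesion_sd = 9, blotch_count = 0L, blotch_contrast = 0),
    list(...))
  do.call(lesion_params, args)
}

#' @rdname lesion_params
#' @export
malignant_lesion_params <- function(size = 64L, ...) {
  args <- utils::modifyList(
    list(size = size, irregularity = 0.30, asymmetry = 0.25,
         axes_frac = c(0.18, 0.28), lesion_sd = 22,
         blotch_count = 4L, blotch_contrast = 60),
    list(...))
  do.call(lesion_params, args)
}

#' Generate one synthetic lesion image with its ground-truth mask
#'
#' Rasterizes a radially perturbed ellipse with a ~1.5-pixel anti-aliased
#' edge, composites lesion texture (Gaussian noise plus optional dark
#' blotches) over noisy background, and returns the exact foreground mask
#' (pixels with lesion coverage >= 0.5).
#'
#' @param params A [lesion_params()].
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return A list with `image` (H x W x 3 array, 0..255), `mask` (logical
#'   H x W), and `meta` (drawn axes `a`, `b`, rotation, center).
#' @export
make_lesion_image <- function(params = lesion_params(), seed = NULL) {
  stopifnot(inherits(params, "lesion_params"))
  gen <- function() {
    n <- params$size
    a <- stats::runif(1, params$axes_frac[1], params$axes_frac[2]) * n
    b <- stats::runif(1, params$axes_frac[1], params$axes_frac[2]) * n
    max_r <- max(a, b) * (1 + params$irregularity + params$asymmetry)
    if (max_r >= n / 2 - 1) stop("lesion does not fit inside the image")
    theta <- stats::runif(1, 0, pi)
    cx <- n / 2 + stats::runif(1, -0.04, 0.04) * n
    cy <- n / 2 + stats::runif(1, -0.04, 0.04) * n
    X <- matrix(rep(seq_len(n), each = n), n) # column index
    Y <- matrix(rep(seq_len(n), times = n), n) # row index
    xr <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
    yr <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    phi <- atan2(yr / b, xr / a)

    pert <- 0
    if (params$irregularity > 0 && length(params$n_harmonics)) {
      amp <- stats::runif(length(params$n_harmonics))
      amp <- amp / sum(amp)
      psi <- stats::runif(length(params$n_harmonics), 0, 2 * pi)
      for (j in seq_along(params$n_harmonics)) {
        pert <- pert + params$irregularity * amp[j] *
          cos(params$n_harmonics[j] * phi + psi[j])
      }
    }
    if (params$asymmetry > 0) {
      psi0 <- stats::runif(2, 0, 2 * pi)
      pert <- pert + params$asymmetry *
        (0.6 * cos(phi + psi0[1]) + 0.4 * cos(2 * phi + psi0[2]))
    }
    edge <- 1.5 / sqrt(a * b) # ~1.5 px anti-aliased edge, normalized units
    alpha <- clamp01((1 + pert - rho) / edge + 0.5)
    mask <- alpha >= 0.5

    lesion_rgb <- rep_len(params$lesion_mean, 3L)
    bg_rgb <- rep_len(params$bg_mean, 3L)
    blotch <- 0
    if (params$blotch_count > 0L && params$blotch_contrast > 0) {
      blotch <- matrix(0, n, n)
      for (i in seq_len(params$blotch_count)) {
        u <- stats::runif(1, 0, 2 * pi)
        rr <- sqrt(stats::runif(1)) * 0.55
        bx <- cx + (a * rr * cos(u)) * cos(theta) - (b * rr * sin(u)) * sin(theta)
        by <- cy + (a * rr * cos(u)) * sin(theta) + (b * rr * sin(u)) * cos(theta)
        w <- stats::runif(1, 0.10, 0.22) * sqrt(a * b)
        blotch <- blotch + params$blotch_contrast *
          exp(-((X - bx)^2 + (Y - by)^2) / (2 * w^2))
      }
    }
    img <- array(0, c(n, n, 3L))
    for (k in 1:3) {
      bgf <- bg_rgb[k] + stats::rnorm(n * n, sd = params$bg_sd)
      lef <- lesion_rgb[k] + stats::rnorm(n * n, sd = params$lesion_sd) - blotch
      v <- (1 - alpha) * bgf + alpha * lef
      if (params$contrast_compress < 1) {
        v <- 128 + (v - 128) * params$contrast_compress
      }
      img[, , k] <- quant8(v)
    }
    list(image = img, mask = mask,
         meta = list(a = a, b = b, theta = theta, cx = cx, cy = cy))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Composite dark hair-like strokes onto an image
#'
#' Draws `count` anti-aliased quadratic-Bezier arcs of the given width in a
#' dark hair tone, and returns the exact stroke mask (coverage >= 0.5).
#' Exercises the DullRazor removal step.
#'
#' @param img 8-bit image (matrix or H x W x 3).
#' @param count Number of strokes (>= 0).
#' @param width Stroke width in pixels.
#' @param color Hair intensity per channel (dark).
#' @param seed Optional integer seed.
#' @return List with `image` (same shape as input), `mask` (logical H x W
#'   stroke mask) and `coverage_fraction`.
#' @export
add_hair <- function(img, count, width = 2, color = c(45, 32, 28),
                     seed = NULL) {
  assert_image8(img)
  if (count < 0) stop("`count` must be non-negative")
  h <- nrow(img); w <- ncol(img)
  gen <- function() {
    if (count == 0) {
      return(list(image = img, mask = matrix(FALSE, h, w),
                  coverage_fraction = 0))
    }
    D <- matrix(Inf, h, w)
    rw <- ceiling(width / 2 + 1.5)
    for (s in seq_len(count)) {
      # endpoints on opposite border bands, bowed control point in between
      side <- sample.int(2L, 1L)
      if (side == 1L) {
        p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, 0.15 * w))
        p2 <- c(stats::runif(1, 1, h), stats::runif(1, 0.85 * w, w))
      } else {
        p0 <- c(stats::runif(1, 1, 0.15 * h), stats::runif(1, 1, w))
        p2 <- c(stats::runif(1, 0.85 * h, h), stats::runif(1, 1, w))
      }
      mid <- (p0 + p2) / 2
      dir <- p2 - p0
      len <- sqrt(sum(dir^2))
      perp <- c(-dir[2], dir[1]) / max(len, 1)
      p1 <- mid + perp * stats::runif(1, -0.35, 0.35) * len
      tt <- seq(0, 1, length.out = max(16L, ceiling(2.5 * len)))
      py <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
      px <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
      for (q in seq_along(tt)) {
        r0 <- max(1L, floor(py[q] - rw)); r1 <- min(h, ceiling(py[q] + rw))
        c0 <- max(1L, floor(px[q] - rw)); c1 <- min(w, ceiling(px[q] + rw))
        if (r0 > r1 || c0 > c1) next
        rr <- r0:r1; cc <- c0:c1
        d2 <- outer((rr - py[q])^2, (cc - px[q])^2, `+`)
        D[rr, cc] <- pmin(D[rr, cc], d2)
      }
    }
    alpha <- clamp01(width / 2 + 0.5 - sqrt(D))
    mask <- alpha >= 0.5
    out <- img
    col <- rep_len(color, 3L)
    for (k in seq_len(n_channels(img))) {
      ch <- get_channel(img, k)
      ck <- if (n_channels(img) == 1L) mean(col) else col[k]
      out <- set_channel(out, k, quant8((1 - alpha) * ch + alpha * ck))
    }
    list(image = out, mask = mask, coverage_fraction = mean(mask))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}

#' Generate a synthetic dermoscopy dataset on disk
#'
#' Writes `n_images` lesion images (and their exact ground-truth masks) as
#' PNGs plus a manifest CSV with columns `image_path`, `mask_path`, `label`
#' and `patient_id`. The malignant fraction equals `round(n_images *
#' imbalance)` images; labels are assigned to image slots at random so a
#' patient may hold both classes, as in real screening data. Each record is
#' generated under its own sub-seed derived from (`seed`, record index), so
#' regeneration with the same seed is byte-identical.
#'
#' @param n_images Number of images.
#' @param imbalance Malignant fraction in (0, 1).
#' @param n_patients Number of distinct patients (>= 2); images are spread
#'   evenly at random across them.
#' @param out_dir Output directory (created if missing).
#' @param image_size Side length of the generated images.
#' @param p_benign,p_malignant [lesion_params()] for the two classes.
#' @param hair_prob Probability that an image receives hair strokes.
#' @param hair_count,hair_width Stroke count and width when hair is added.
#' @param seed Integer seed for the whole manifest.
#' @return The manifest data frame (paths relative to `out_dir`), invisibly,
#'   with attributes `base_dir` and `seed`. Also written to
#'   `out_dir/manifest.csv`.
#' @export
make_dataset <- function(n_images, imbalance, n_patients, out_dir,
                         image_size = 32L,
                         p_benign = benign_lesion_params(image_size),
                         p_malignant = malignant_lesion_params(image_size),
                         hair_prob = 0.25, hair_count = 2L, hair_width = 1,
                         seed = 1L) {
  if (n_patients < 2L) stop("`n_patients` must be at least 2")
  if (imbalance <= 0 || imbalance >= 1) stop("`imbalance` must lie in (0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_mal <- round(n_images * imbalance)
  labels <- withr::with_seed(derive_seed(seed, 0L), {
    lab <- rep("benign", n_images)
    lab[sample.int(n_images, n_mal)] <- "malignant"
    pid <- sample(rep_len(seq_len(n_patients), n_images))
    list(label = lab, patient = sprintf("P%04d", pid))
  })
  rec <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- derive_seed(seed, i)
    lab <- labels$label[i]
    p <- if (lab == "malignant") p_malignant else p_benign
    out <- withr::with_seed(si, {
      les <- make_lesion_image(p)
      if (stats::runif(1) < hair_prob) {
        hb <- add_hair(les$image, count = hair_count, width = hair_width)
        les$image <- hb$image
      }
      les
    })
    img_rel <- sprintf("img_%05d.png", i)
    msk_rel <- sprintf("mask_%05d.png", i)
    write_image(out$image, file.path(out_dir, img_rel))
    write_image(out$mask, file.path(out_dir, msk_rel))
    rec[[i]] <- data.frame(image_path = img_rel, mask_path = msk_rel,
                           label = lab, patient_id = labels$patient[i],
                           stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rec)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "base_dir") <- out_dir
  attr(manifest, "seed") <- as.integer(seed)
  invisible(manifest)
}

#' Standard optimizer benchmark functions
#'
#' Returns one of the classic box-bounded test functions together with its
#' known global minimum, a matrix-vectorized form, and default bounds.
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"ackley"`.
#' @param dim Dimensionality (>= 1).
#' @return A list with `name`, `dim`, `fn` (vector -> scalar), `fn_mat`
#'   (N x dim matrix -> N values), `lower`, `upper`, `x_opt`, `f_opt`.
#' @examples
#' b <- benchmark_function("rastrigin", 2)
#' b$fn(c(1, 0)) # 1
#' @export
benchmark_function <- function(name = c("sphere", "rastrigin", "ackley"),
                               dim = 2L) {
  name <- match.arg(name)
  dim <- as.integer(dim)
  if (dim < 1L) stop("`dim` must be at least 1")
  out <- switch(
    name,
    sphere = list(
      fn = function(x) sum(x^2),
      fn_mat = function(X) rowSums(X^2),
      lower = rep(-5, dim), upper = rep(5, dim)),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      fn_mat = function(X) 10 * ncol(X) + rowSums(X^2 - 10 * cos(2 * pi * X)),
      lower = rep(-5.12, dim), upper = rep(5.12, dim)),
    ackley = list(
      fn = function(x) {
        -20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))) +
          20 + exp(1)
      },
      fn_mat = function(X) {
        -20 * exp(-0.2 * sqrt(rowMeans(X^2))) -
          exp(rowMeans(cos(2 * pi * X))) + 20 + exp(1)
      },
      lower = rep(-32, dim), upper = rep(32, dim))
  )
  c(list(name = name, dim = dim), out,
    list(x_opt = rep(0, dim), f_opt = 0))
}
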