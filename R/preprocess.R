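# Image conditioning ahead of segmentation and classification: Gaussian
# denoising, DullRazor-style hair/artifact removal, and lookup-table
# min-max contrast stretching.

#' Gaussian low-pass denoising
#'
#' Convolves each channel with a normalized Gaussian kernel (truncated at
#' ~3 sigma, replicated borders) and re-quantizes to 8 bits. `sigma = 0` is
#' the identity.
#'
#' @param img 8-bit image.
#' @param sigma Kernel standard deviation in pixels (>= 0).
#' @return 8-bit image of the same shape.
#' @export
gaussian_denoise <- function(img, sigma = 1) {
  assert_image8(img)
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(img)
  out <- img
  kern <- EBImage::makeBrush(2L * ceiling(3 * sigma) + 1L,
                             shape = "gaussian", sigma = sigma)
  for (k in seq_len(n_channels(img))) {
    ch <- get_channel(img, k) / 255
    sm <- EBImage::filter2(ch, kern, boundary = "replicate")
    out <- set_channel(out, k, quant8(255 * clamp01(sm)))
  }
  out
}

gray_close <- function(ch, e_size) {
  br <- EBImage::makeBrush(e_size, shape = "box")
  EBImage::erode(EBImage::dilate(ch, br), br)
}

#' DullRazor hair and artifact removal
#'
#' Detects thin dark structures (hairs, ruler edges) by grayscale
#' morphological closing: the image is dilated then eroded with a square
#' element, the absolute difference against the original is thresholded
#' into a boolean artifact mask, the mask is cleaned by a 3 x 3 opening and
#' grown by one 3 x 3 dilation to cover stroke borders, and masked pixels
#' are replaced — either by the closed image's values (`mode = "closing"`)
#' or by the median of unmasked pixels in a neighborhood
#' (`mode = "median"`, the statistical-averaging variant). Pixels outside
#' the returned mask are never modified; an image without detectable
#' artifacts is returned bit-identical. Works best after light Gaussian
#' denoising (the [preprocess_image()] order), which keeps sensor noise and
#' the lesion rim below the detection threshold.
#'
#' @param img 8-bit image.
#' @param element_size Odd side length of the square closing element
#'   (default 7); must exceed the hair width to be removed.
#' @param threshold Minimum closing difference (intensity levels, default
#'   10) for a pixel to count as artifact.
#' @param mode Replacement mode, `"closing"` (default) or `"median"`.
#' @param median_radius Neighborhood radius for `mode = "median"`.
#' @param min_area Connected components of the cleaned mask smaller than
#'   this (default 15 px) are discarded: hair strokes are long, noise
#'   clusters are tiny.
#' @param mask_dilate Number of 3 x 3 dilations applied to the cleaned mask
#'   (default 2) so anti-aliased stroke borders are covered.
#' @return List with `image` (hair-free 8-bit image), `mask` (logical
#'   artifact mask) and `coverage_fraction`.
#' @export
remove_hair <- function(img, element_size = 7L, threshold = 10,
                        mode = c("closing", "median"), median_radius = 5L,
                        min_area = 15L, mask_dilate = 2L) {
  assert_image8(img)
  mode <- match.arg(mode)
  element_size <- as.integer(element_size)
  if (element_size < 3L || element_size %% 2L == 0L) {
    stop("`element_size` must be an odd integer >= 3")
  }
  g <- rgb_to_gray(img)
  closed_g <- quant8(255 * gray_close(g / 255, element_size))
  diffm <- abs(closed_g - g)
  raw <- diffm >= threshold
  mask <- open_mask(raw, struct_elem(3L))
  if (min_area > 1L && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    mask[mask] <- sizes[lab[lab > 0L]] >= min_area
  }
  for (i in seq_len(mask_dilate)) mask <- dilate_mask(mask, struct_elem(3L))
  cov <- mean(mask)
  out <- img
  if (any(mask)) {
    if (mode == "closing") {
      for (k in seq_len(n_channels(img))) {
        ch <- get_channel(img, k)
        closed_k <- if (n_channels(img) == 1L) closed_g else {
          quant8(255 * gray_close(ch / 255, element_size))
        }
        ch[mask] <- closed_k[mask]
        out <- set_channel(out, k, ch)
      }
    } else {
      idx <- which(mask, arr.ind = TRUE)
      h <- nrow(g); w <- ncol(g)
      r <- as.integer(median_radius)
      for (k in seq_len(n_channels(img))) {
        ch <- get_channel(img, k)
        repl <- numeric(nrow(idx))
        for (i in seq_len(nrow(idx))) {
          ys <- max(1L, idx[i, 1L] - r):min(h, idx[i, 1L] + r)
          xs <- max(1L, idx[i, 2L] - r):min(w, idx[i, 2L] + r)
          nb <- ch[ys, xs][!mask[ys, xs]]
          repl[i] <- if (length(nb)) stats::median(nb) else closed_g[idx[i, 1L], idx[i, 2L]]
        }
        ch[mask] <- quant8(repl)
        out <- set_channel(out, k, ch)
      }
    }
  }
  list(image = out, mask = mask, coverage_fraction = cov)
}

#' Min-max contrast lookup table for one channel
#'
#' @param channel 8-bit matrix.
#' @return Integer vector of 256 output levels (`table[v + 1]` maps input
#'   `v`), monotonically non-decreasing, with attributes `in_min`,
#'   `in_max`. A constant channel maps to itself.
#' @export
contrast_lut <- function(channel) {
  v <- range(channel)
  lut <- 0:255
  if (v[1L] < v[2L]) {
    lut <- quant8(255 * (0:255 - v[1L]) / (v[2L] - v[1L]))
  }
  structure(as.integer(lut), in_min = as.integer(v[1L]),
            in_max = as.integer(v[2L]))
}

#' Linear contrast stretching
#'
#' Stretches each channel so its observed minimum maps to 0 and its maximum
#' to 255, `out = round(255 (v - min) / (max - min))` (round half-up),
#' applied through a 256-entry lookup table. Constant channels pass through
#' unchanged. Idempotent: a channel already spanning 0..255 is untouched.
#'
#' @param img 8-bit image.
#' @return 8-bit image of the same shape.
#' @export
enhance_contrast <- function(img) {
  assert_image8(img)
  out <- img
  for (k in seq_len(n_channels(img))) {
    ch <- get_channel(img, k)
    lut <- contrast_lut(ch)
    out <- set_channel(out, k,
                       matrix(as.numeric(lut[ch + 1L]), nrow(ch), ncol(ch)))
  }
  out
}

#' Full preprocessing chain
#'
#' Denoise, remove hair, then stretch contrast — the conditioning applied
#' before segmentation or classification.
#'
#' @param img 8-bit image.
#' @param denoise_sigma Gaussian sigma (0 disables denoising).
#' @param hair_element,hair_threshold DullRazor parameters; `hair_element =
#'   0` disables hair removal.
#' @param contrast Whether to apply [enhance_contrast()].
#' @return 8-bit image, with the hair mask as attribute `hair_mask` when
#'   hair removal ran.
#' @export
preprocess_image <- function(img, denoise_sigma = 0.5, hair_element = 7L,
                             hair_threshold = 10, contrast = TRUE) {
  out <- gaussian_denoise(img, denoise_sigma)
  hm <- NULL
  if (hair_element >= 3L) {
    hr <- remove_hair(out, element_size = hair_element,
                      threshold = hair_threshold)
    out <- hr$image
    hm <- hr$mask
  }
  if (contrast) out <- enhance_contrast(out)
  if (!is.null(hm)) attr(out, "hair_mask") <- hm
  out
}
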