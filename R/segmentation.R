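# Kapur-entropy multilevel thresholding with the gray wolf optimizer in the
# loop, plus the morphological post-processing that turns a thresholded
# dermoscopy image into a single lesion mask.

#' 256-bin intensity histogram
#'
#' @param img 8-bit image; RGB input is converted to luminance with
#'   [rgb_to_gray()].
#' @return A list of class `gray_histogram` with `counts` (256 integers),
#'   `ph` (probabilities summing to 1) and `L = 256`.
#' @export
gray_histogram <- function(img) {
  assert_image8(img)
  v <- as.vector(rgb_to_gray(img))
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(counts = counts, ph = counts / sum(counts), L = 256L),
            class = "gray_histogram")
}

as_ph <- function(hist) {
  if (inherits(hist, "gray_histogram")) return(hist$ph)
  ph <- as.numeric(hist)
  if (length(ph) != 256L || any(ph < 0)) {
    stop("`hist` must be a gray_histogram or a 256-bin probability vector")
  }
  s <- sum(ph)
  if (s <= 0) stop("histogram has no mass")
  ph / s
}

# Cumulative mass and entropy-sum tables for a 256-bin histogram:
# P0[b + 1] = sum of ph over bins < b, likewise Q0 for ph * log(ph).
kapur_tables <- function(ph) {
  logph <- numeric(256L)
  pos <- ph > 0
  logph[pos] <- log(ph[pos])
  list(P0 = c(0, cumsum(ph)), Q0 = c(0, cumsum(ph * logph)))
}

# Kapur objective for a matrix of candidate threshold vectors (rows),
# using cumulative sums so each evaluation is O(m). Thresholds are rounded
# and sorted per row; classes are [th_{j-1}, th_j - 1] with th_0 = 0,
# th_m = 256. Empty bins and empty classes contribute 0.
kapur_objective_mat <- function(ph, TH, tables = NULL) {
  TH <- round(TH)
  TH[TH < 0] <- 0
  TH[TH > 255] <- 255
  nc <- ncol(TH)
  if (nc == 2L) {
    lo <- pmin(TH[, 1L], TH[, 2L])
    TH <- cbind(lo, TH[, 1L] + TH[, 2L] - lo)
  } else if (nc > 2L) {
    TH <- t(apply(TH, 1L, sort))
  }
  if (is.null(tables)) tables <- kapur_tables(ph)
  P0 <- tables$P0; Q0 <- tables$Q0
  n <- nrow(TH)
  J <- numeric(n)
  prev <- rep.int(1L, n)
  for (j in seq_len(nc + 1L)) {
    b <- if (j <= nc) TH[, j] + 1L else rep.int(257L, n)
    w <- P0[b] - P0[prev]
    S <- Q0[b] - Q0[prev]
    pos <- w > 0
    J[pos] <- J[pos] + log(w[pos]) - S[pos] / w[pos]
    prev <- b
  }
  J
}

#' Kapur entropy of a thresholding
#'
#' The sum over classes of the Shannon entropy of the within-class
#' intensity distribution: for class `j` with probability mass `w_j`,
#' `H_j = -sum_i (ph_i / w_j) ln(ph_i / w_j)` over the class's bins, with
#' `0 ln 0 := 0` and empty classes contributing 0. Multilevel thresholds
#' are chosen to maximize this objective. Thresholds are sorted internally,
#' so the value is permutation-invariant; pixel `v` belongs to class `j`
#' when `th_{j-1} <= v < th_j` (`th_0 = 0`, `th_m = 256`).
#'
#' @param hist A [gray_histogram()] (or 256-bin probability vector).
#' @param th Integer thresholds in (0, 255); need not be sorted.
#' @return The scalar entropy `J >= 0`.
#' @examples
#' ph <- c(rep(0.25, 4), rep(0, 252))
#' kapur_objective(ph, 2) # 2 * log(2)
#' @export
kapur_objective <- function(hist, th) {
  ph <- as_ph(hist)
  kapur_objective_mat(ph, matrix(as.numeric(th), nrow = 1L))
}

#' Find multilevel thresholds by maximizing Kapur entropy with IGWO
#'
#' Runs the optimizer `repeats` times under distinct sub-seeds (minimizing
#' the negated entropy over integer thresholds in 1..254), sorts each run's
#' thresholds, and reports the per-position mean across runs rounded to the
#' nearest integer. Duplicate thresholds after rounding are resolved by
#' incrementing (with a message).
#'
#' @param img 8-bit image (or a [gray_histogram()]).
#' @param m Number of classes (>= 2), i.e. `m - 1` thresholds.
#' @param opt An [igwo_config()]; its `seed` drives the per-run sub-seeds.
#' @param repeats Number of independent optimizer runs averaged (default 25).
#' @param variant `"igwo"` or `"gwo"`.
#' @return Integer vector of class `threshold_vector` (sorted, strictly
#'   increasing, in 1..254) with attributes `J` (entropy at the reported
#'   thresholds), `m`, and `runs` (per-run threshold matrix).
#' @export
find_thresholds <- function(img, m = 2L, opt = igwo_config(),
                            repeats = 25L, variant = c("igwo", "gwo")) {
  variant <- match.arg(variant)
  m <- as.integer(m)
  if (m < 2L) stop("`m` must be at least 2")
  if (m - 1L > 254L) stop("cannot place more than 254 distinct thresholds")
  ph <- if (inherits(img, "gray_histogram")) img$ph else gray_histogram(img)$ph
  space <- search_space(rep(1, m - 1L), rep(254, m - 1L), integer = TRUE)
  tables <- kapur_tables(ph)
  obj <- function(X) -kapur_objective_mat(ph, X, tables)
  base_seed <- if (is.null(opt$seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    opt$seed
  }
  runs <- matrix(0, repeats, m - 1L)
  for (r in seq_len(repeats)) {
    cfg <- opt
    cfg$seed <- derive_seed(base_seed, r)
    res <- gwo_optimize(obj, space, cfg, variant = variant,
                        vectorized = TRUE)
    runs[r, ] <- sort(round(res$best_position))
  }
  th <- round(colMeans(runs))
  th <- sort(th)
  while (anyDuplicated(th)) {
    i <- which(duplicated(th))[1L]
    message("duplicate threshold after averaging; incrementing ", th[i])
    th[i] <- th[i] + 1L
    th <- sort(pmin(th, 254L))
    if (anyDuplicated(th) && all(th == 254L)) stop("cannot deduplicate thresholds")
  }
  structure(as.integer(th), class = "threshold_vector",
            J = kapur_objective(ph, th), m = m, runs = runs)
}

#' Exhaustive Kapur threshold search
#'
#' Brute-force maximization over all threshold combinations; practical for
#' `m = 2` (254 candidates) and `m = 3` (~32k pairs). Used as an
#' optimality reference for the optimizer-driven search.
#'
#' @inheritParams find_thresholds
#' @return As [find_thresholds()] (without `runs`).
#' @export
exhaustive_thresholds <- function(img, m = 2L) {
  m <- as.integer(m)
  if (!m %in% c(2L, 3L)) stop("exhaustive search supports m = 2 or 3")
  ph <- if (inherits(img, "gray_histogram")) img$ph else gray_histogram(img)$ph
  if (m == 2L) {
    TH <- matrix(1:254, ncol = 1L)
  } else {
    TH <- as.matrix(expand.grid(th1 = 1:253, th2 = 2:254))
    TH <- TH[TH[, 1L] < TH[, 2L], , drop = FALSE]
  }
  J <- kapur_objective_mat(ph, TH)
  best <- which.max(J)
  structure(as.integer(TH[best, ]), class = "threshold_vector",
            J = J[best], m = m)
}

#' Apply a threshold vector to an image
#'
#' Pixel `v` is assigned class `j` such that `th_{j-1} <= v < th_j`
#' (`th_0 = 0`, `th_m = 256`); a pixel equal to a threshold goes to the
#' upper class.
#'
#' @param img 8-bit image (RGB converted to luminance).
#' @param th Sorted thresholds (a `threshold_vector` or integer vector).
#' @return Integer H x W matrix of class labels 1..m.
#' @export
apply_thresholds <- function(img, th) {
  g <- rgb_to_gray(img)
  th <- sort(as.numeric(th))
  matrix(findInterval(g, th) + 1L, nrow(g), ncol(g))
}

#' Segment the lesion in a dermoscopic image
#'
#' Thresholds the image by Kapur entropy (optimizer in the loop), takes the
#' darkest class as lesion foreground (melanocytic lesions are darker than
#' surrounding skin), then cleans the mask morphologically: fill holes,
#' open, close (3 x 3 element), and keep the largest 8-connected component.
#' With `foreground = "bright"` the image is intensity-inverted and the
#' same dark-lesion pipeline is applied, so results mirror exactly.
#'
#' @param img 8-bit image (ideally preprocessed; see [preprocess_image()]).
#' @param m Number of threshold classes (default 2).
#' @param opt An [igwo_config()] for the threshold search.
#' @param repeats Optimizer repeats passed to [find_thresholds()].
#' @param variant Optimizer variant.
#' @param foreground `"dark"` (default) or `"bright"`.
#' @param e Structuring element for the morphology (default 3 x 3 box).
#' @return Logical lesion mask with attributes `thresholds` and `J`. If the
#'   foreground is empty after morphology, an empty mask is returned with a
#'   warning.
#' @export
segment_lesion <- function(img, m = 2L, opt = igwo_config(), repeats = 25L,
                           variant = c("igwo", "gwo"),
                           foreground = c("dark", "bright"),
                           e = struct_elem(3L)) {
  variant <- match.arg(variant)
  foreground <- match.arg(foreground)
  g <- rgb_to_gray(img)
  if (foreground == "bright") g <- 255 - g
  th <- find_thresholds(g, m = m, opt = opt, repeats = repeats,
                        variant = variant)
  cls <- apply_thresholds(g, th)
  mask <- cls == 1L # darkest class
  mask <- fill_holes(mask, e)
  mask <- open_mask(mask, e)
  mask <- close_mask(mask, e)
  if (!any(mask)) {
    warning("empty foreground after morphology; returning empty mask")
  } else {
    mask <- largest_component(mask)
  }
  attr(mask, "thresholds") <- as.integer(th)
  attr(mask, "J") <- attr(th, "J")
  mask
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Logical matrices of equal shape.
#' @return IoU in [0, 1]; 1 if both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
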