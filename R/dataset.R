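# Dataset manifests and leakage-free patient-grouped splitting. A manifest
# is a data frame with columns image_path, label (benign/malignant) and
# patient_id (plus optional mask_path); all images of one patient always
# end up in the same subset.

#' Read / write a dataset manifest CSV
#'
#' @param path Path to a CSV with columns `image_path`, `label`,
#'   `patient_id` (and optionally `mask_path`, `split`).
#' @return A data frame with attribute `base_dir` set to the manifest's
#'   directory, against which relative image paths are resolved.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_path", "label", "patient_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$label), c("benign", "malignant"))
  if (length(bad)) stop("unknown labels in manifest: ", paste(bad, collapse = ", "))
  attr(df, "base_dir") <- dirname(normalizePath(path))
  df
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

# Greedy patient assignment balancing, for every group, both the total
# image count and the per-class counts against targets proportional to
# `ratios`. Patients carrying minority-class images are placed first
# (largest first), so the rare class is spread as evenly as granularity
# allows; ties are broken deterministically after a seeded shuffle.
assign_patients <- function(manifest, ratios, seed = NULL) {
  pats <- unique(manifest$patient_id)
  k <- length(ratios)
  if (length(pats) < k) stop("fewer patients than splits requested")
  tab <- table(manifest$patient_id, manifest$label)
  cls <- colnames(tab)
  counts <- matrix(tab, nrow(tab), dimnames = dimnames(tab))
  minority <- cls[which.min(colSums(counts))]
  ord <- withr::with_seed(if (is.null(seed)) 0L else as.integer(seed),
                          sample(rownames(counts)))
  counts <- counts[ord, , drop = FALSE]
  has_min <- counts[, minority] > 0
  tot <- rowSums(counts)
  ord2 <- c(which(has_min)[order(-counts[has_min, minority])],
            which(!has_min)[order(-tot[!has_min])])
  counts <- counts[ord2, , drop = FALSE]
  target <- outer(ratios, colSums(counts))
  colnames(target) <- cls
  assigned <- matrix(0, k, length(cls), dimnames = list(NULL, cls))
  wcls <- sum(counts) / pmax(colSums(counts), 1) # rarity weight per class
  grp <- integer(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    carry <- counts[i, ] > 0
    cost <- vapply(seq_len(k), function(s) {
      after <- assigned[s, ] + counts[i, ]
      # fill ratio of the classes this patient carries: proportional
      # filling stratifies every class and thereby the totals
      sum(wcls[carry] * (after[carry] / pmax(target[s, carry], 1e-9))^2)
    }, numeric(1))
    s <- which.min(cost)
    assigned[s, ] <- assigned[s, ] + counts[i, ]
    grp[i] <- s
  }
  stats::setNames(grp, rownames(counts))
}

#' Patient-grouped stratified train/validation/test split
#'
#' Assigns whole patients (never single images) to splits, greedily
#' balancing split sizes and class ratios, so no patient identifier
#' straddles two subsets.
#'
#' @param manifest Manifest data frame ([read_manifest()] /
#'   [make_dataset()]).
#' @param ratios Named split fractions summing to 1
#'   (default `c(train = 0.70, val = 0.15, test = 0.15)`).
#' @param seed Integer seed for tie-shuffling.
#' @return The manifest with a `split` factor column added.
#' @export
split_dataset <- function(manifest,
                          ratios = c(train = 0.70, val = 0.15, test = 0.15),
                          seed = NULL) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("`ratios` must sum to 1")
  if (is.null(names(ratios))) {
    names(ratios) <- paste0("split", seq_along(ratios))
  }
  grp <- assign_patients(manifest, ratios, seed)
  manifest$split <- factor(names(ratios)[grp[manifest$patient_id]],
                           levels = names(ratios))
  manifest
}

#' Patient-grouped stratified k-fold partition
#'
#' Each patient lands in exactly one holdout fold; folds are class
#' stratified as far as patient granularity allows.
#'
#' @inheritParams split_dataset
#' @param k Number of folds (>= 2, default 5).
#' @return A list of `k` logical vectors over manifest rows (`TRUE` =
#'   holdout fold member); also attached to the manifest as attribute
#'   `fold` by [kfold_assignments()].
#' @export
kfold_patient <- function(manifest, k = 5L, seed = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  if (length(unique(manifest$patient_id)) < k) {
    stop("fewer patients than folds requested")
  }
  grp <- assign_patients(manifest, rep(1 / k, k), seed)
  fold <- unname(grp[manifest$patient_id])
  lapply(seq_len(k), function(i) fold == i)
}

#' @rdname kfold_patient
#' @export
kfold_assignments <- function(manifest, k = 5L, seed = NULL) {
  folds <- kfold_patient(manifest, k, seed)
  manifest$fold <- 0L
  for (i in seq_along(folds)) manifest$fold[folds[[i]]] <- i
  manifest
}

#' Load manifest images into an array
#'
#' Reads every image of a manifest (paths resolved against its `base_dir`
#' attribute, or `base_dir` argument) and stacks them as an
#' `H x W x C x N` array, bilinearly resized when a target size is given.
#'
#' @param manifest Manifest data frame.
#' @param size Optional target `(H, W)`; images are resized with bilinear
#'   interpolation when their size differs.
#' @param base_dir Directory for relative paths (defaults to the
#'   manifest's `base_dir` attribute).
#' @return List with `x` (`H x W x 3 x N` array, 0..255), `y` (labels),
#'   `patient_id`, and `split`/`fold` columns when present.
#' @export
load_images <- function(manifest, size = NULL, base_dir = NULL) {
  base_dir <- base_dir %||% attr(manifest, "base_dir") %||% "."
  n <- nrow(manifest)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- manifest$image_path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$image_path[i])
    img <- read_image(p)
    if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (!is.null(size) && !all(dim(img)[1:2] == size[1:2])) {
      img <- quant8(EBImage::resize(img, w = size[1L], h = size[2L]))
    }
    imgs[[i]] <- img
  }
  d <- dim(imgs[[1L]])
  x <- array(0, c(d, n))
  for (i in seq_len(n)) x[, , , i] <- imgs[[i]]
  out <- list(x = x, y = manifest$label, patient_id = manifest$patient_id)
  if (!is.null(manifest$split)) out$split <- manifest$split
  if (!is.null(manifest$fold)) out$fold <- manifest$fold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
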