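# Binary mathematical morphology on logical masks, with an explicit
# structuring element. Conventions: the element's origin is its center
# (odd side lengths enforced); dilation treats pixels outside the image as
# background and erosion treats them as foreground, so closing and opening
# are exact duals under complementation everywhere, including borders.

#' Create a structuring element
#'
#' @param size Side length(s), odd, default a 3 x 3 square.
#' @param shape `"box"` (all true) or `"disk"` (Euclidean ball).
#' @return A logical matrix of class `struct_elem` with odd dimensions and
#'   at least one `TRUE` cell.
#' @export
struct_elem <- function(size = 3L, shape = c("box", "disk")) {
  shape <- match.arg(shape)
  size <- rep_len(as.integer(size), 2L)
  if (any(size < 1L) || any(size %% 2L == 0L)) {
    stop("structuring element sides must be odd and positive")
  }
  e <- matrix(TRUE, size[1L], size[2L])
  if (shape == "disk") {
    r <- (size - 1L) / 2
    dy <- matrix(rep(-r[1]:r[1], times = size[2L]), size[1L])
    dx <- matrix(rep(-r[2]:r[2], each = size[1L]), size[1L])
    e <- (dy / max(r[1L], 1))^2 + (dx / max(r[2L], 1))^2 <= 1
  }
  structure(e, class = c("struct_elem", "matrix"))
}

as_struct_elem <- function(e) {
  if (is.numeric(e) && length(e) == 1L) return(struct_elem(e))
  e <- as.matrix(e)
  if (any(dim(e) %% 2L == 0L)) stop("structuring element sides must be odd")
  e <- e != 0
  if (!any(e)) stop("structuring element must have at least one true cell")
  e
}

# shift a logical matrix by (dy, dx), padding with `fill`
shift_mask <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  if (length(ys) && length(xs)) out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

elem_offsets <- function(e) {
  ry <- (nrow(e) - 1L) / 2L
  rx <- (ncol(e) - 1L) / 2L
  idx <- which(e, arr.ind = TRUE)
  cbind(dy = idx[, 1L] - ry - 1L, dx = idx[, 2L] - rx - 1L)
}

#' Binary dilation and erosion
#'
#' @param mask Logical H x W matrix.
#' @param e Structuring element ([struct_elem()], any odd-sized 0/1 matrix,
#'   or a single odd integer meaning a square box).
#' @return Logical H x W matrix.
#' @export
dilate_mask <- function(mask, e = struct_elem(3L)) {
  e <- as_struct_elem(e)
  off <- elem_offsets(e)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off[i, 1L], off[i, 2L], FALSE)
  }
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, e = struct_elem(3L)) {
  e <- as_struct_elem(e)
  # erosion by e = complement of dilation of the complement by reflected e
  off <- elem_offsets(e)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mask(mask, -off[i, 1L], -off[i, 2L], TRUE)
  }
  out
}

#' Morphological opening and closing
#'
#' Opening (erode then dilate) removes details smaller than the element
#' without altering the remaining shape; closing (dilate then erode)
#' bridges narrow gaps. Both are idempotent.
#'
#' @inheritParams dilate_mask
#' @return Logical H x W matrix.
#' @export
open_mask <- function(mask, e = struct_elem(3L)) {
  e <- as_struct_elem(e)
  dilate_mask(erode_mask(mask, e), e)
}

#' @rdname open_mask
#' @export
close_mask <- function(mask, e = struct_elem(3L)) {
  e <- as_struct_elem(e)
  erode_mask(dilate_mask(mask, e), e)
}

#' Fill holes in a binary mask
#'
#' Iterates the geodesic dilation `X_k = dilate(X_{k-1}, e) & !A` from a
#' border-seeded background marker until a fixed point; the filled mask is
#' everything the border-connected background cannot reach. Background
#' regions touching the image border are never filled. With the default
#' 3 x 3 box element the background is traversed with 8-connectivity.
#'
#' @inheritParams dilate_mask
#' @return Logical H x W matrix, a superset of `mask`.
#' @export
fill_holes <- function(mask, e = struct_elem(3L)) {
  e <- as_struct_elem(e)
  h <- nrow(mask); w <- ncol(mask)
  notA <- !mask
  marker <- matrix(FALSE, h, w)
  marker[1L, ] <- notA[1L, ]; marker[h, ] <- notA[h, ]
  marker[, 1L] <- marker[, 1L] | notA[, 1L]
  marker[, w] <- marker[, w] | notA[, w]
  repeat {
    grown <- dilate_mask(marker, e) & notA
    grown <- grown | marker
    if (identical(grown, marker)) break
    marker <- grown
  }
  !marker
}

# union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical H x W matrix.
#' @return Integer H x W matrix: 0 for background, 1..k for components.
#' @export
label_components <- function(mask) {
  lab4 <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  n <- max(lab4)
  if (n <= 1L) return(matrix(as.integer(lab4), nrow(mask)))
  # merge 4-connected labels that touch diagonally
  parent <- seq_len(n)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab4[seq_len(nrow(lab4) - 1L), , drop = FALSE]
    b <- lab4[-1L, , drop = FALSE]
    if (sh[2L] == 1L) {
      a <- a[, seq_len(ncol(a) - 1L), drop = FALSE]
      b <- b[, -1L, drop = FALSE]
    } else {
      a <- a[, -1L, drop = FALSE]
      b <- b[, seq_len(ncol(b) - 1L), drop = FALSE]
    }
    keep <- a > 0 & b > 0 & a != b
    if (any(keep)) {
      pairs <- unique(cbind(a[keep], b[keep]))
      for (i in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[i, 1L])
        rb <- uf_find(parent, pairs[i, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nrow(mask), ncol(mask))
  nz <- lab4 > 0
  out[nz] <- relab[lab4[nz]]
  out
}

#' Keep only the largest 8-connected component
#'
#' @param mask Logical H x W matrix.
#' @return Logical H x W matrix with at most one component. An all-false
#'   input is returned unchanged.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  k <- max(lab)
  if (k <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  lab == which.max(sizes)
}
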