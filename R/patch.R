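# Tiled patch extraction and whole-image reassembly. Windows are square,
# 0-based, (row, col), half-open [row0, row0 + size); edge windows overhang
# into padding.

#' Plan a regular grid of square patch windows
#'
#' Lattice starts at 0 with the given stride; the number of starts per axis is
#' `ceiling((dim - size) / stride) + 1` (at least 1), so the union of windows
#' covers the image, the last window possibly overhanging into padding. When a
#' `region_mask` is supplied, only windows whose mask coverage (padding counts
#' as 0) is at least `min_mask_fraction` are kept.
#'
#' @param image_shape integer (H, W).
#' @param size window side in pixels.
#' @param stride lattice stride, `0 < stride <= size`.
#' @param region_mask optional H x W binary mask restricting the grid.
#' @param min_mask_fraction minimum fraction of mask pixels per kept window.
#' @param pad_mode `"reflect"` (default) or `"zero"` padding for overhangs.
#' @return a `patch_grid` list: tibble of `windows` (row0, col0, size),
#'   `stride`, `image_shape`, `pad_mode`.
#' @export
plan_grid <- function(image_shape, size, stride = size, region_mask = NULL,
                      min_mask_fraction = 0, pad_mode = c("reflect", "zero")) {
  pad_mode <- match.arg(pad_mode)
  H <- image_shape[1]; W <- image_shape[2]
  if (stride <= 0 || stride > size)
    stop("need 0 < stride <= size", call. = FALSE)
  if (min_mask_fraction < 0 || min_mask_fraction > 1)
    stop("min_mask_fraction must lie in [0, 1]", call. = FALSE)
  if (size > 2 * max(H, W))
    stop("patch size larger than the padded image", call. = FALSE)
  starts <- function(n) {
    k <- max(0L, as.integer(ceiling((n - size) / stride))) + 1L
    (seq_len(k) - 1L) * stride
  }
  r0 <- starts(H); c0 <- starts(W)
  win <- expand.grid(row0 = r0, col0 = c0, KEEP.OUT.ATTRS = FALSE)
  win <- win[order(win$row0, win$col0), , drop = FALSE]
  win$size <- size
  if (!is.null(region_mask)) {
    cov <- vapply(seq_len(nrow(win)), function(i) {
      rs <- (win$row0[i] + 1):(win$row0[i] + size)
      cs <- (win$col0[i] + 1):(win$col0[i] + size)
      sub <- region_mask[rs[rs <= H], cs[cs <= W], drop = FALSE]
      sum(sub) / (size * size)   # overhang counts as uncovered
    }, numeric(1))
    win <- win[cov >= min_mask_fraction, , drop = FALSE]
  }
  rownames(win) <- NULL
  structure(list(windows = tibble::as_tibble(win), stride = stride,
                 image_shape = c(H, W), pad_mode = pad_mode),
            class = "patch_grid")
}

pad_image <- function(image, pad, mode) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (pad == 0) return(image)
  ri <- c(seq_len(H), if (mode == "reflect") rev(seq_len(H))[seq_len(pad)] else rep(NA, pad))
  ci <- c(seq_len(W), if (mode == "reflect") rev(seq_len(W))[seq_len(pad)] else rep(NA, pad))
  if (length(d) == 2) {
    out <- matrix(0, H + pad, W + pad)
    sel <- image[ri[!is.na(ri)], ci[!is.na(ci)], drop = FALSE]
    out[seq_along(ri)[!is.na(ri)], seq_along(ci)[!is.na(ci)]] <- sel
  } else {
    out <- array(0, c(H + pad, W + pad, d[3]))
    out[seq_along(ri)[!is.na(ri)], seq_along(ci)[!is.na(ci)], ] <-
      image[ri[!is.na(ri)], ci[!is.na(ci)], , drop = FALSE]
  }
  out
}

#' Extract the patches of a planned grid
#'
#' @param image matrix or H x W x C array matching `grid$image_shape`.
#' @param grid a [plan_grid()] result.
#' @return list of patch arrays in window order.
#' @export
extract_patches <- function(image, grid) {
  d <- dim(image)
  if (d[1] != grid$image_shape[1] || d[2] != grid$image_shape[2])
    stop("image shape does not match the grid", call. = FALSE)
  w <- grid$windows
  size <- if (nrow(w)) w$size[1] else 0L
  over <- if (nrow(w)) max(0L, max(w$row0 + size - d[1], w$col0 + size - d[2])) else 0L
  padded <- pad_image(image, over, grid$pad_mode)
  lapply(seq_len(nrow(w)), function(i) {
    rs <- (w$row0[i] + 1):(w$row0[i] + size)
    cs <- (w$col0[i] + 1):(w$col0[i] + size)
    if (length(d) == 2) padded[rs, cs, drop = FALSE] else padded[rs, cs, , drop = FALSE]
  })
}

#' Reassemble an image from grid patches
#'
#' Overlapping pixels are averaged with uniform weights; pixels covered by no
#' window take `fill`. On a disjoint grid `assemble_patches(extract_patches(x))`
#' reproduces `x` exactly on the covered, unpadded pixels.
#'
#' @param patches list of patch arrays, one per grid window.
#' @param grid the [plan_grid()] used for extraction.
#' @param fill value (or H x W matrix) for uncovered pixels.
#' @return matrix or array of `grid$image_shape`.
#' @export
assemble_patches <- function(patches, grid, fill = 0) {
  w <- grid$windows
  if (length(patches) != nrow(w))
    stop("patch count does not match the grid", call. = FALSE)
  H <- grid$image_shape[1]; W <- grid$image_shape[2]
  nc <- if (length(patches) && length(dim(patches[[1]])) == 3) dim(patches[[1]])[3] else 1L
  acc <- array(0, c(H, W, nc))
  cnt <- matrix(0, H, W)
  for (i in seq_len(nrow(w))) {
    size <- w$size[i]
    rs <- (w$row0[i] + 1):(w$row0[i] + size)
    cs <- (w$col0[i] + 1):(w$col0[i] + size)
    vr <- rs <= H; vc <- cs <= W
    p <- patches[[i]]
    if (length(dim(p)) == 2) dim(p) <- c(dim(p), 1L)
    if (!all(dim(p)[1:2] == size))
      stop("patch size does not match the grid window", call. = FALSE)
    acc[rs[vr], cs[vc], ] <- acc[rs[vr], cs[vc], , drop = FALSE] +
      p[which(vr), which(vc), , drop = FALSE]
    cnt[rs[vr], cs[vc]] <- cnt[rs[vr], cs[vc]] + 1
  }
  covered <- cnt > 0
  fillm <- if (is.matrix(fill)) fill else matrix(fill, H, W)
  out <- acc
  for (ch in seq_len(nc)) {
    plane <- acc[, , ch]
    plane[covered] <- plane[covered] / cnt[covered]
    plane[!covered] <- fillm[!covered]
    out[, , ch] <- plane
  }
  if (nc == 1L) out[, , 1] else out
}

#' Serialize / restore a patch grid as JSON
#' @param grid a `patch_grid`.
#' @param path file path.
#' @return `read_grid` returns a `patch_grid`.
#' @export
write_grid <- function(grid, path) {
  jsonlite::write_json(list(windows = grid$windows, stride = grid$stride,
                            image_shape = grid$image_shape,
                            pad_mode = grid$pad_mode),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(windows = tibble::as_tibble(x$windows), stride = x$stride,
                 image_shape = x$image_shape, pad_mode = x$pad_mode),
            class = "patch_grid")
}
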