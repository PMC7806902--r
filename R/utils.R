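# shared internal helpers: intensity bookkeeping, warps, seeds

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Translate an image by an integer displacement
#'
#' Moves image content by `(dy, dx)`: the output at pixel `(r, c)` is the
#' input at `(r - dy, c - dx)`. Out-of-range samples are filled with `fill`
#' or, when `fill = "edge"`, with the nearest edge pixel.
#'
#' @param img matrix or H x W x C array.
#' @param dy,dx integer displacement in pixels (rows, columns).
#' @param fill numeric fill value, or `"edge"` for clamped edge replication.
#' @return array of the same shape as `img`.
#' @export
translate_image <- function(img, dy, dx, fill = 0) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  ri <- seq_len(H) - dy
  ci <- seq_len(W) - dx
  if (identical(fill, "edge")) {
    ri <- pmin(pmax(ri, 1L), H)
    ci <- pmin(pmax(ci, 1L), W)
    if (length(d) == 2) return(img[ri, ci, drop = FALSE])
    return(img[ri, ci, , drop = FALSE])
  }
  okr <- ri >= 1 & ri <= H
  okc <- ci >= 1 & ci <= W
  if (length(d) == 2) {
    out <- matrix(fill, H, W)
    out[okr, okc] <- img[ri[okr], ci[okc], drop = FALSE]
  } else {
    out <- array(fill, d)
    out[okr, okc, ] <- img[ri[okr], ci[okc], , drop = FALSE]
  }
  out
}

# derive a stream of reproducible sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth positive random field via separable gaussian blur of white noise,
# rescaled to mean 0 / sd 1 (uses the caller's RNG stream)
smooth_field <- function(H, W, scale) {
  z <- matrix(rnorm(H * W), H, W)
  k <- gaussian_kernel(scale)
  z <- blur_sep(z, k)
  (z - mean(z)) / max(sd(z), 1e-12)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable blur with edge replication
blur_sep <- function(z, k) {
  r <- (length(k) - 1L) / 2L
  H <- nrow(z); W <- ncol(z)
  zp <- z[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  z1 <- apply(zp, 2, function(col) stats::filter(col, k, sides = 2))[(r + 1):(r + H), , drop = FALSE]
  zp <- z1[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  z2 <- t(apply(zp, 1, function(row) stats::filter(row, k, sides = 2)))[, (r + 1):(r + W), drop = FALSE]
  z2
}

# block-mean downsample of a matrix to target size (used by the toy embedder)
resize_mean <- function(z, ho, wo) {
  H <- nrow(z); W <- ncol(z)
  ri <- findInterval(seq_len(H), seq(1, H + 1, length.out = ho + 1),
                     rightmost.closed = TRUE)
  ci <- findInterval(seq_len(W), seq(1, W + 1, length.out = wo + 1),
                     rightmost.closed = TRUE)
  rs <- rowsum(z, ri)
  rs <- t(rowsum(t(rs), ci))
  cnt <- outer(tabulate(ri, ho), tabulate(ci, wo))
  rs / cnt
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
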