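# Minimal convolutional-network core: conv layers (via compiled im2col
# kernels), activations, nearest-neighbour up/down sampling, inverted dropout
# and an Adam optimizer. Parameters live in flat named lists of arrays;
# gradients mirror that layout. Everything is deterministic given the R RNG
# state.

conv_fwd <- function(x, w, b, stride = 1L, pad = 1L, want_cache = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  dw <- dim(w)                     # (kh, kw, Cin, F)
  wmat <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  out <- conv2d_fwd_cpp(x, wmat, b, dw[1], dw[2], as.integer(stride),
                        as.integer(pad))
  if (want_cache) list(out = out, x = x) else out
}

# x may be the cache list from conv_fwd(want_cache = TRUE) or the raw input
conv_bwd <- function(x, w, dy, stride = 1L, pad = 1L, want_dw = TRUE,
                     want_dx = TRUE) {
  if (is.list(x)) x <- x$x
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  dw <- dim(w)
  wmat <- matrix(w, dw[1] * dw[2] * dw[3], dw[4])
  g <- conv2d_bwd_cpp(x, wmat, dy, dw[1], dw[2], as.integer(stride),
                      as.integer(pad), want_dw, want_dx)
  if (want_dw) {
    g$dw <- array(g$dw, dw)
    g$db <- as.numeric(g$db)
  }
  g
}

lrelu <- function(x, a = 0.2) { x[x < 0] <- a * x[x < 0]; x }
dlrelu <- function(pre, a = 0.2) { d <- array(a, dim(pre)); d[pre > 0] <- 1; d }
relu <- function(x) { x[x < 0] <- 0; x }
drelu <- function(pre) (pre > 0) * 1
sigmoid <- function(x) 1 / (1 + exp(-x))

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  o <- c(TRUE, FALSE); e <- c(FALSE, TRUE)
  dy[o, o, , drop = FALSE] + dy[e, o, , drop = FALSE] +
    dy[o, e, , drop = FALSE] + dy[e, e, , drop = FALSE]
}

concat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# glorot-uniform init for a conv weight (kh, kw, Cin, F); consumes R RNG
init_conv <- function(kh, kw, cin, f) {
  fan <- kh * kw * (cin + f) / 2
  lim <- sqrt(3 / fan)
  list(w = array(runif(kh * kw * cin * f, -lim, lim), c(kh, kw, cin, f)),
       b = rep(0, f))
}

# moment buffers mirror the exact structure (dims included) of each parameter
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(a, b) {
  for (k in names(b)) a[[k]] <- a[[k]] + b[[k]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

# random flip / 90-degree-rotation augmentation applied jointly to a
# color patch (H,W,3) and target map (H,W); consumes 3 RNG draws
augment_pair <- function(x, y) {
  if (runif(1) < 0.5) { x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]; y <- y[rev(seq_len(nrow(y))), , drop = FALSE] }
  if (runif(1) < 0.5) { x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]; y <- y[, rev(seq_len(ncol(y))), drop = FALSE] }
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) {
    x <- aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
    y <- t(y)[rev(seq_len(ncol(y))), , drop = FALSE]
  }
  list(x = x, y = y)
}
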