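# U-net generator and pair discriminator for color -> UV translation, with
# the conditional-adversarial objective
#   min_G max_D  mean_i [ meanpix|Y_i - G(X_i)| + lambda log(1 - D(X_i,G(X_i))) ]
#                + lambda mean_j log D(X_j, Y_j)
# Log terms are evaluated on probabilities clamped to (1e-6, 1 - 1e-6);
# gradients are taken in logit space for stability.

DISC_EPS <- 1e-6

#' Generator (U-net) configuration
#'
#' The encoder halves the spatial size per level with 4x4 stride-2
#' convolutions (leaky ReLU); the decoder upsamples (nearest neighbour),
#' concatenates the matching encoder feature (skip connection) and applies a
#' 3x3 convolution (ReLU). Inverted dropout is applied at the decoder levels
#' in `dropout_levels` during training (innermost two by default). A final 3x3
#' convolution with sigmoid squashing yields the UV output on [0, 1].
#'
#' @param depth number of down/up levels; `input_size` must be divisible by
#'   `2^depth`.
#' @param base_channels channels of the first encoder level (doubled per level).
#' @param input_size square patch side in pixels.
#' @param out_channels output channels (1 = monochrome UV).
#' @param dropout_rate dropout probability in [0, 1).
#' @param dropout_levels decoder levels (counted from the innermost = depth)
#'   that receive dropout.
#' @return a `generator_config` list.
#' @export
generator_config <- function(depth = 3, base_channels = 8, input_size = 64,
                             out_channels = 1, dropout_rate = 0.5,
                             dropout_levels = c(depth, depth - 1)) {
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(depth = depth, base_channels = base_channels,
                 input_size = input_size, out_channels = out_channels,
                 dropout_rate = dropout_rate,
                 dropout_levels = dropout_levels[dropout_levels >= 1],
                 in_channels = 3L),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Stride-2 convolution stack over the channel-concatenated (color, candidate
#' UV) pair followed by a dense head over the flattened conv features; the
#' scalar output is a probability squashed strictly inside (0, 1).
#'
#' @param depth number of stride-2 levels.
#' @param base_channels first-level channel count.
#' @param input_size square patch side in pixels.
#' @param uv_channels channels of the candidate UV input.
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(depth = 3, base_channels = 16,
                                 input_size = 64, uv_channels = 1) {
  structure(list(depth = depth, base_channels = base_channels,
                 input_size = input_size, uv_channels = uv_channels,
                 in_channels = 3L + uv_channels),
            class = "discriminator_config")
}

gen_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1)

init_generator <- function(cfg) {
  ch <- gen_channels(cfg)
  p <- list()
  cin <- cfg$in_channels
  for (k in seq_len(cfg$depth)) {
    l <- init_conv(4, 4, cin, ch[k])
    p[[paste0("enc", k, ".w")]] <- l$w
    p[[paste0("enc", k, ".b")]] <- l$b
    cin <- ch[k]
  }
  for (k in rev(seq_len(cfg$depth))) {
    skip <- if (k > 1) ch[k - 1] else cfg$in_channels
    cout <- if (k > 1) ch[k - 1] else cfg$base_channels
    l <- init_conv(3, 3, cin + skip, cout)
    p[[paste0("dec", k, ".w")]] <- l$w
    p[[paste0("dec", k, ".b")]] <- l$b
    cin <- cout
  }
  l <- init_conv(3, 3, cin, cfg$out_channels)
  p[["out.w"]] <- l$w
  p[["out.b"]] <- l$b
  p
}

#' Run the generator on one color patch
#'
#' @param params generator parameter list from a trained state (or
#'   [init_generator] internals).
#' @param x color patch, `S x S x 3` on [0, 1], `S = config$input_size`.
#' @param config the [generator_config()].
#' @param train logical; enables dropout (training mode). Inference is
#'   deterministic.
#' @param want_cache keep intermediates for backpropagation (internal).
#' @return `S x S x out_channels` array on [0, 1] (with `want_cache = TRUE`, a
#'   list `(out, cache)`).
#' @export
generator_forward <- function(params, x, config, train = FALSE,
                              want_cache = FALSE) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != config$input_size || dim(x)[2] != config$input_size)
    stop("patch size does not match config$input_size", call. = FALSE)
  d <- config$depth
  enc <- vector("list", d)
  pre_e <- vector("list", d)
  ce <- vector("list", d)   # conv caches (patch matrices) for backprop
  h <- x
  for (k in seq_len(d)) {
    r <- conv_fwd(h, params[[paste0("enc", k, ".w")]],
                  params[[paste0("enc", k, ".b")]], stride = 2, pad = 1,
                  want_cache = want_cache)
    pre_e[[k]] <- if (want_cache) r$out else r
    if (want_cache) ce[[k]] <- r["x"]
    h <- lrelu(pre_e[[k]])
    enc[[k]] <- h
  }
  pre_d <- vector("list", d)
  cd <- vector("list", d)
  drop_mask <- vector("list", d)
  for (k in rev(seq_len(d))) {
    u <- upsample2(h)
    skip <- if (k > 1) enc[[k - 1]] else x
    cc <- concat_ch(u, skip)
    r <- conv_fwd(cc, params[[paste0("dec", k, ".w")]],
                  params[[paste0("dec", k, ".b")]], stride = 1, pad = 1,
                  want_cache = want_cache)
    pre_d[[k]] <- if (want_cache) r$out else r
    if (want_cache) cd[[k]] <- r["x"]
    h <- relu(pre_d[[k]])
    if (train && config$dropout_rate > 0 && k %in% config$dropout_levels) {
      keep <- 1 - config$dropout_rate
      m <- array((runif(length(h)) < keep) / keep, dim(h))
      drop_mask[[k]] <- m
      h <- h * m
    }
  }
  r <- conv_fwd(h, params[["out.w"]], params[["out.b"]], stride = 1, pad = 1,
                want_cache = want_cache)
  pre_o <- if (want_cache) r$out else r
  co <- if (want_cache) r["x"] else NULL
  out <- if (identical(config$head, "softmax")) {
    m <- pmax(pre_o[, , 1], pre_o[, , 2])
    e1 <- exp(pre_o[, , 1] - m); e2 <- exp(pre_o[, , 2] - m)
    array(c(e1 / (e1 + e2), e2 / (e1 + e2)), dim(pre_o))
  } else sigmoid(pre_o)
  if (!want_cache) {
    if (config$out_channels == 1L) return(out[, , 1]) else return(out)
  }
  list(out = out, cache = list(x = x, enc = enc, pre_e = pre_e, pre_d = pre_d,
                               ce = ce, cd = cd, co = co,
                               drop_mask = drop_mask))
}

# full forward+backward for one (x, y_target) with optional adversarial term.
# Returns list(out, grads, l1) where grads are wrt all generator params.
# adv_fn: NULL or function(g_out) -> list(value, d_gout) adding extra loss.
generator_grads <- function(params, config, x, y, lambda = 0, disc = NULL,
                            disc_config = NULL, train = TRUE) {
  fw <- generator_forward(params, x, config, train = train, want_cache = TRUE)
  out <- fw$out
  ytgt <- y
  if (is.matrix(ytgt)) dim(ytgt) <- c(dim(ytgt), 1L)
  npix <- prod(dim(out)[1:2])
  l1 <- mean(abs(ytgt - out))
  d_out <- sign(out - ytgt) / length(out)  # d mean|Y-G| / dG
  adv <- 0
  if (lambda > 0 && !is.null(disc)) {
    dfw <- disc_forward_cache(disc, x, out, disc_config)
    p <- clamp_prob(dfw$p)
    adv <- log(1 - p)
    # d/dz log(1-sigmoid(z)) = -p ; propagate lambda * (-p) through D to uv input
    dz <- -lambda * dfw$p
    duv <- disc_backward(disc, disc_config, dfw, dz, wrt = "input")$d_uv
    # clip the adversarial gradient to the reconstruction gradient's norm:
    # Adam normalizes step sizes per-parameter, so without a bound the
    # adversarial direction can dominate regardless of lambda and collapse
    # the generator onto a discriminator exploit
    l1n <- sqrt(sum(d_out^2))
    an <- sqrt(sum(duv^2))
    if (an > l1n && an > 0) duv <- duv * (l1n / an)
    d_out <- d_out + duv
  }
  grads <- unet_backprop(params, config, fw, d_out)
  list(out = out, grads = grads, l1 = l1, adv = adv)
}

# Backward pass through the U-net given the gradient wrt its sigmoid output.
# Decoder levels were computed in order d, d-1, ..., 1 (level 1 feeds the
# output conv); gradients therefore walk levels 1..d, routing the upsample
# branch to the next-deeper decoder activation (enc[[d]] at level d) and the
# skip branch to the matching encoder activation.
unet_backprop <- function(params, config, fw, d_out) {
  ca <- fw$cache
  d <- config$depth
  ch <- gen_channels(config)
  g <- list()
  dz <- if (identical(config$head, "softmax")) {
    s <- d_out[, , 1] * fw$out[, , 1] + d_out[, , 2] * fw$out[, , 2]
    array(c(fw$out[, , 1] * (d_out[, , 1] - s),
            fw$out[, , 2] * (d_out[, , 2] - s)), dim(d_out))
  } else d_out * fw$out * (1 - fw$out)
  bo <- conv_bwd(ca$co, params[["out.w"]], dz, stride = 1, pad = 1)
  g[["out.w"]] <- bo$dw; g[["out.b"]] <- bo$db

  d_enc <- vector("list", d)   # accumulated gradient wrt enc[[k]] activations
  dh <- bo$dx                  # gradient wrt decoder level-1 activation
  for (k in seq_len(d)) {
    if (!is.null(ca$drop_mask[[k]])) dh <- dh * ca$drop_mask[[k]]
    dpre <- dh * drelu(ca$pre_d[[k]])
    bk <- conv_bwd(ca$cd[[k]], params[[paste0("dec", k, ".w")]], dpre,
                   stride = 1, pad = 1)
    g[[paste0("dec", k, ".w")]] <- bk$dw
    g[[paste0("dec", k, ".b")]] <- bk$db
    nskip <- if (k > 1) ch[k - 1] else config$in_channels
    nup <- dim(bk$dx)[3] - nskip
    du <- bk$dx[, , seq_len(nup), drop = FALSE]
    dskip <- bk$dx[, , nup + seq_len(nskip), drop = FALSE]
    if (k > 1) {
      d_enc[[k - 1]] <- if (is.null(d_enc[[k - 1]])) dskip else d_enc[[k - 1]] + dskip
    }
    dh_up <- upsample2_bwd(du)
    if (k == d) {
      d_enc[[d]] <- if (is.null(d_enc[[d]])) dh_up else d_enc[[d]] + dh_up
    } else {
      dh <- dh_up   # gradient wrt decoder activation at level k + 1
    }
  }
  dcur <- d_enc[[d]]
  for (k in rev(seq_len(d))) {
    if (k < d && !is.null(d_enc[[k]])) dcur <- dcur + d_enc[[k]]
    dpre <- dcur * dlrelu(ca$pre_e[[k]])
    bk <- conv_bwd(ca$ce[[k]], params[[paste0("enc", k, ".w")]], dpre,
                   stride = 2, pad = 1, want_dx = k > 1)
    g[[paste0("enc", k, ".w")]] <- bk$dw
    g[[paste0("enc", k, ".b")]] <- bk$db
    if (k > 1) dcur <- bk$dx
  }
  g
}

clamp_prob <- function(p) pmin(pmax(p, DISC_EPS), 1 - DISC_EPS)

init_discriminator <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  p <- list()
  cin <- cfg$in_channels
  for (k in seq_len(cfg$depth)) {
    l <- init_conv(4, 4, cin, ch[k])
    p[[paste0("c", k, ".w")]] <- l$w
    p[[paste0("c", k, ".b")]] <- l$b
    cin <- ch[k]
  }
  # dense head over the flattened conv features: spatial layout is kept, so
  # the head can react to texture/sharpness, not just channel averages
  nfeat <- cin * (cfg$input_size / 2^cfg$depth)^2
  lim <- sqrt(3 / nfeat)
  p[["fc.w"]] <- matrix(runif(nfeat, -lim, lim), 1, nfeat)
  p[["fc.b"]] <- 0
  p
}

disc_forward_cache <- function(params, x, uv, cfg) {
  if (is.matrix(uv)) dim(uv) <- c(dim(uv), 1L)
  if (!all(dim(x)[1:2] == cfg$input_size) || !all(dim(uv)[1:2] == cfg$input_size))
    stop("discriminator input size mismatch", call. = FALSE)
  h <- concat_ch(x, uv)
  pre <- vector("list", cfg$depth)
  act <- vector("list", cfg$depth)
  cc <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    r <- conv_fwd(h, params[[paste0("c", k, ".w")]],
                  params[[paste0("c", k, ".b")]], stride = 2, pad = 1,
                  want_cache = TRUE)
    pre[[k]] <- r$out
    cc[[k]] <- r["x"]
    h <- lrelu(pre[[k]])
    act[[k]] <- h
  }
  feat <- as.numeric(h)
  z <- as.numeric(params[["fc.w"]] %*% feat + params[["fc.b"]])
  list(p = sigmoid(z), z = z, feat = feat, act = act, pre = pre, cc = cc,
       x = x, uv = uv)
}

# dz: scalar gradient wrt the logit z. wrt: "params", "input" or both.
disc_backward <- function(params, cfg, fw, dz, wrt = "params") {
  g <- list()
  need_p <- "params" %in% wrt
  need_i <- "input" %in% wrt
  if (need_p) {
    g[["fc.w"]] <- matrix(dz * fw$feat, 1)
    g[["fc.b"]] <- dz
  }
  hdim <- dim(fw$act[[cfg$depth]])
  dh <- array(as.numeric(params[["fc.w"]]) * dz, hdim)
  for (k in rev(seq_len(cfg$depth))) {
    dpre <- dh * dlrelu(fw$pre[[k]])
    bk <- conv_bwd(fw$cc[[k]], params[[paste0("c", k, ".w")]], dpre,
                   stride = 2, pad = 1, want_dw = need_p,
                   want_dx = need_i || k > 1)
    if (need_p) {
      g[[paste0("c", k, ".w")]] <- bk$dw
      g[[paste0("c", k, ".b")]] <- bk$db
    }
    if (need_i || k > 1) dh <- bk$dx
  }
  out <- list(grads = g)
  if ("input" %in% wrt) {
    nuv <- cfg$uv_channels
    out$d_uv <- dh[, , 3 + seq_len(nuv), drop = FALSE]
    out$d_color <- dh[, , 1:3, drop = FALSE]
  }
  out
}

#' Run the discriminator on a (color, candidate UV) pair
#'
#' @param params discriminator parameter list.
#' @param x color patch `S x S x 3`.
#' @param uv candidate UV patch (`S x S` or `S x S x uv_channels`).
#' @param config the [discriminator_config()].
#' @return scalar probability, clamped strictly inside (0, 1).
#' @export
discriminator_forward <- function(params, x, uv, config) {
  clamp_prob(disc_forward_cache(params, x, uv, config)$p)
}

#' Generator objective on a batch
#'
#' `mean_i [ meanpix |Y_i - G(X_i)| + lambda * log(1 - D(X_i, G(X_i))) ]`.
#' With `lambda = 0` this is the pure per-pixel L1 objective (the
#' "no discriminator" ablation). `disc_fn` may be any function
#' `(x, uv) -> probability`, e.g. a stub for testing.
#'
#' @param batch list of pairs, each `list(x = SxSx3, y = SxS)`.
#' @param gen_params,config generator parameters and config.
#' @param lambda adversarial weight (>= 0, default 0.005).
#' @param disc_fn probability function of `(x, uv)`; required when
#'   `lambda > 0`.
#' @return list: `loss` (scalar) and `terms` (per-batch mean `l1_term`,
#'   `adv_gen_term`, `lambda`).
#' @export
generator_loss <- function(batch, gen_params, config, lambda = 0.005,
                           disc_fn = NULL) {
  if (length(batch) == 0) stop("empty batch", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  l1s <- advs <- numeric(length(batch))
  for (i in seq_along(batch)) {
    gx <- generator_forward(gen_params, batch[[i]]$x, config, train = FALSE)
    y <- batch[[i]]$y
    l1s[i] <- mean(abs(y - gx))
    if (lambda > 0) {
      p <- clamp_prob(disc_fn(batch[[i]]$x, gx))
      advs[i] <- log(1 - p)
    }
  }
  terms <- list(l1_term = mean(l1s), adv_gen_term = lambda * mean(advs),
                lambda = lambda)
  list(loss = terms$l1_term + terms$adv_gen_term, terms = terms)
}

#' Discriminator objective on disjoint fake/real batches
#'
#' `-mean_I log(1 - D(X_i, G(X_i))) - mean_J log D(X_j, Y_j)`, with fake
#' candidates `fake_uv[[i]]` (generator outputs) and real pairs from
#' `real_batch`. The index sets behind the two batches must be disjoint; the
#' training sampler enforces this and the function refuses overlapping
#' explicit indices.
#'
#' @param fake_batch list of `list(x, uv)` fake pairs (uv = generator output).
#' @param real_batch list of `list(x, y)` real pairs.
#' @param disc_fn probability function of `(x, uv)`.
#' @param fake_idx,real_idx optional integer indices used to assert
#'   disjointness.
#' @return scalar loss (>= 0 given clamping).
#' @export
discriminator_loss <- function(fake_batch, real_batch, disc_fn,
                               fake_idx = NULL, real_idx = NULL) {
  if (!is.null(fake_idx) && !is.null(real_idx) &&
      length(intersect(fake_idx, real_idx)) > 0)
    stop("fake and real index sets must be disjoint", call. = FALSE)
  lf <- vapply(fake_batch, function(b)
    log(1 - clamp_prob(disc_fn(b$x, b$uv))), numeric(1))
  lr <- vapply(real_batch, function(b)
    log(clamp_prob(disc_fn(b$x, b$y))), numeric(1))
  -mean(lf) - mean(lr)
}
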