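# Face-region detection: a patch-level binary face/non-face CNN classifier
# and region-map assembly by painting per-window votes. On phantoms the
# training labels come from mask coverage; a hook accepts externally produced
# landmark-derived masks for real photographs.

#' Label grid windows as face / non-face from a region mask
#'
#' A window is `face` when its mask coverage is at least `face_threshold`,
#' `non_face` when its coverage is exactly zero; windows with intermediate
#' coverage are dropped from training.
#'
#' @param mask H x W binary mask (1 = face).
#' @param grid a [plan_grid()] over the same image.
#' @param face_threshold coverage fraction in (0, 1].
#' @return tibble `(row0, col0, size, coverage, label)`, dropped windows
#'   removed.
#' @export
label_patches_from_mask <- function(mask, grid, face_threshold = 0.9) {
  if (face_threshold <= 0 || face_threshold > 1)
    stop("face_threshold must lie in (0, 1]", call. = FALSE)
  w <- grid$windows
  H <- nrow(mask); W <- ncol(mask)
  cov <- vapply(seq_len(nrow(w)), function(i) {
    rs <- (w$row0[i] + 1):(w$row0[i] + w$size[i])
    cs <- (w$col0[i] + 1):(w$col0[i] + w$size[i])
    sum(mask[rs[rs <= H], cs[cs <= W], drop = FALSE]) / (w$size[i]^2)
  }, numeric(1))
  w$coverage <- cov
  w$label <- ifelse(cov >= face_threshold, "face",
                    ifelse(cov == 0, "non_face", NA))
  w[!is.na(w$label), , drop = FALSE]
}

clf_config <- function(depth = 2, base_channels = 8, input_size = 24) {
  list(depth = depth, base_channels = base_channels, input_size = input_size,
       in_channels = 3L)
}

init_clf <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  p <- list()
  cin <- cfg$in_channels
  for (k in seq_len(cfg$depth)) {
    l <- init_conv(4, 4, cin, ch[k])
    p[[paste0("c", k, ".w")]] <- l$w
    p[[paste0("c", k, ".b")]] <- l$b
    cin <- ch[k]
  }
  lim <- sqrt(3 / cin)
  p[["fc.w"]] <- matrix(runif(cin, -lim, lim), 1, cin)
  p[["fc.b"]] <- 0
  p
}

clf_forward <- function(params, x, cfg) {
  h <- x
  pre <- act <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    pre[[k]] <- conv_fwd(h, params[[paste0("c", k, ".w")]],
                         params[[paste0("c", k, ".b")]], stride = 2, pad = 1)
    h <- lrelu(pre[[k]])
    act[[k]] <- h
  }
  gap <- apply(h, 3, mean)
  z <- as.numeric(params[["fc.w"]] %*% gap + params[["fc.b"]])
  list(p = sigmoid(z), z = z, gap = gap, act = act, pre = pre, x = x)
}

clf_backward <- function(params, cfg, fw, dz) {
  g <- list()
  g[["fc.w"]] <- matrix(dz * fw$gap, 1)
  g[["fc.b"]] <- dz
  hdim <- dim(fw$act[[cfg$depth]])
  dgap <- as.numeric(params[["fc.w"]]) * dz
  dh <- array(rep(dgap, each = hdim[1] * hdim[2]) / (hdim[1] * hdim[2]), hdim)
  for (k in rev(seq_len(cfg$depth))) {
    dpre <- dh * dlrelu(fw$pre[[k]])
    xin <- if (k == 1) fw$x else fw$act[[k - 1]]
    bk <- conv_bwd(xin, params[[paste0("c", k, ".w")]], dpre, stride = 2,
                   pad = 1)
    g[[paste0("c", k, ".w")]] <- bk$dw
    g[[paste0("c", k, ".b")]] <- bk$db
    dh <- bk$dx
  }
  g
}

#' Train the patch-level face/non-face classifier
#'
#' A small configurable CNN (stride-2 convolution blocks, global average
#' pooling, dense head) trained with binary cross-entropy and Adam on labelled
#' square patches. Fully seeded; the training-loss trace is returned.
#'
#' @param patches list of `S x S x 3` color patches.
#' @param labels character or factor, `"face"` / `"non_face"` per patch (both
#'   classes must be present).
#' @param config list: `depth`, `base_channels`, `input_size` (see
#'   `clf_config`).
#' @param steps training steps.
#' @param batch_size,lr,seed optimizer settings.
#' @return `face_classifier` list with `params`, `config`, `loss_trace`,
#'   `seed`.
#' @export
train_face_classifier <- function(patches, labels, config = clf_config(),
                                  steps = 2000, batch_size = 16, lr = 1e-3,
                                  seed = 1) {
  y <- as.integer(labels == "face")
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training labels", call. = FALSE)
  with_seed(seed, {
    p <- init_clf(config)
    ad <- adam_init(p)
    trace <- numeric(0)
    n <- length(patches)
    for (s in seq_len(max(0L, steps))) {
      idx <- sample.int(n, min(batch_size, n))
      gacc <- NULL; loss <- 0
      for (i in idx) {
        fw <- clf_forward(p, patches[[i]], config)
        pr <- clamp_prob(fw$p)
        loss <- loss - (y[i] * log(pr) + (1 - y[i]) * log(1 - pr))
        dz <- (fw$p - y[i]) / length(idx)
        g <- clf_backward(p, config, fw, dz)
        gacc <- if (is.null(gacc)) g else acc_grads(gacc, g)
      }
      st <- adam_step(p, gacc, ad, lr)
      p <- st$params; ad <- st$state
      trace[s] <- loss / length(idx)
    }
    structure(list(params = p, config = config, loss_trace = trace,
                   seed = seed),
              class = "face_classifier")
  })
}

#' Predict face probability for patches
#' @param clf a [train_face_classifier()] result.
#' @param patches list of patches.
#' @return numeric vector of probabilities.
#' @export
predict_face <- function(clf, patches) {
  vapply(patches, function(x) clf_forward(clf$params, x, clf$config)$p,
         numeric(1))
}

#' Assemble a face-region map from per-window classifier labels
#'
#' Windows tile the whole image; each window paints its predicted label onto
#' the canvas and overlapping votes are resolved by majority, ties counting
#' as face.
#'
#' @param image H x W x 3 color image.
#' @param clf trained [train_face_classifier()] state.
#' @param patch_size window side (the classifier's input size).
#' @param stride window stride.
#' @return H x W binary matrix (1 = face).
#' @export
assemble_region_map <- function(image, clf, patch_size = clf$config$input_size,
                                stride = patch_size) {
  grid <- plan_grid(dim(image)[1:2], patch_size, stride)
  patches <- extract_patches(image, grid)
  pr <- predict_face(clf, patches)
  H <- dim(image)[1]; W <- dim(image)[2]
  face_votes <- matrix(0, H, W)
  tot_votes <- matrix(0, H, W)
  w <- grid$windows
  for (i in seq_len(nrow(w))) {
    rs <- (w$row0[i] + 1):min(w$row0[i] + w$size[i], H)
    cs <- (w$col0[i] + 1):min(w$col0[i] + w$size[i], W)
    face_votes[rs, cs] <- face_votes[rs, cs] + (pr[i] >= 0.5)
    tot_votes[rs, cs] <- tot_votes[rs, cs] + 1
  }
  out <- matrix(0, H, W)
  out[face_votes >= tot_votes / 2] <- 1  # ties -> face
  out[tot_votes == 0] <- 0
  out
}
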