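# Melanin-emphasis baselines: grayscale, blue channel, and a two-chromophore
# ICA decomposition of log-RGB skin color (melanin / hemoglobin components)
# with weighted re-synthesis and a constrained weight grid search.

#' Luminance grayscale of an RGB image
#' @param color H x W x 3 array on [0, 1].
#' @return H x W matrix, `0.299 R + 0.587 G + 0.114 B`.
#' @export
grayscale <- function(color) {
  0.299 * color[, , 1] + 0.587 * color[, , 2] + 0.114 * color[, , 3]
}

#' Blue channel of an RGB image
#' @param color H x W x 3 array.
#' @return H x W matrix (the B plane, unchanged).
#' @export
blue_channel <- function(color) color[, , 3]

# FastICA-style 2-source separation by deflation: whiten, then symmetric
# fixed-point iterations with the tanh nonlinearity from a fixed
# deterministic start; tolerance 1e-6.
fastica2 <- function(z, tol = 1e-6, maxit = 500) {
  # z: 2 x n whitened data (identity covariance)
  wmat <- matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)
  for (comp in 1:2) {
    w <- wmat[, comp]
    if (comp == 2) {
      w <- w - sum(w * wmat[, 1]) * wmat[, 1]
      w <- w / sqrt(sum(w^2))
    }
    for (it in seq_len(maxit)) {
      wx <- drop(w %*% z)
      gw <- tanh(wx)
      gp <- 1 - gw^2
      w1 <- z %*% gw / ncol(z) - mean(gp) * w
      w1 <- drop(w1)
      if (comp == 2) w1 <- w1 - sum(w1 * wmat[, 1]) * wmat[, 1]
      w1 <- w1 / sqrt(sum(w1^2))
      conv <- abs(abs(sum(w1 * w)) - 1)
      w <- w1
      if (conv < tol) break
    }
    wmat[, comp] <- w
  }
  t(wmat)   # unmixing: s = wmat_t %*% z
}

#' Decompose a color skin image into melanin and hemoglobin components
#'
#' Pixels are mapped to absorbance (`-log RGB`), the shading direction
#' `(1,1,1)/sqrt(3)` is projected out (multiplicative shading is common to
#' all channels in log space), and a 2-source ICA is run on the masked
#' pixels' plane coordinates. The component whose log-RGB mixing vector
#' absorbs most strongly in the blue channel is labelled melanin. Component
#' maps cover the whole image; re-synthesis with unit weights reconstructs
#' the input exactly.
#'
#' @param color H x W x 3 image on (0, 1].
#' @param skin_mask optional binary mask of skin pixels used to fit the ICA
#'   (at least 100 pixels); defaults to all pixels.
#' @return `ica_decomposition`: `melanin_map`, `hemoglobin_map` (H x W source
#'   images), `mixing` (3 x 2, component -> log-RGB absorbance),
#'   `mean_absorbance`, `shading_map`, `basis`, `shading_removed = TRUE`.
#' @export
ica_decompose <- function(color, skin_mask = NULL) {
  H <- dim(color)[1]; W <- dim(color)[2]
  if (is.null(skin_mask)) skin_mask <- matrix(1, H, W)
  sel <- which(skin_mask > 0)
  if (length(sel) < 100)
    stop("need at least 100 masked skin pixels", call. = FALSE)
  px <- cbind(as.vector(color[, , 1]), as.vector(color[, , 2]),
              as.vector(color[, , 3]))
  a <- -log(pmax(px, 1e-4))                       # absorbance, all pixels
  mu <- colMeans(a[sel, , drop = FALSE])
  ac <- sweep(a, 2, mu)
  u1 <- rep(1, 3) / sqrt(3)
  shade <- drop(ac %*% u1)                        # shading coordinate
  # orthonormal basis of the chromophore plane
  B <- qr.Q(qr(cbind(u1, diag(3))))[, 2:3]
  p2 <- ac %*% B                                  # n x 2 plane coordinates
  p2m <- t(p2[sel, , drop = FALSE])
  cv <- cov(t(p2m))
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] <= max(1e-10 * ev$values[1], 1e-14))
    stop("degenerate pixel cloud: rank < 2", call. = FALSE)
  wh <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  unmix_w <- fastica2(wh %*% p2m)                 # s = unmix_w %*% wh %*% p2
  unmix <- unmix_w %*% wh
  mix2 <- solve(unmix)                            # p2 = mix2 %*% s
  s_all <- t(unmix %*% t(p2))                     # n x 2 sources
  mixing <- B %*% mix2                            # 3 x 2, log-RGB per component
  # orient each component so its absorbance vector points positive overall
  for (k in 1:2) {
    if (sum(mixing[, k]) < 0) {
      mixing[, k] <- -mixing[, k]
      s_all[, k] <- -s_all[, k]
    }
  }
  # melanin = stronger relative blue absorbance
  nb <- abs(mixing[3, ]) / sqrt(colSums(mixing^2))
  mel <- which.max(nb)
  ord <- c(mel, setdiff(1:2, mel))
  s_all <- s_all[, ord, drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  structure(list(melanin_map = matrix(s_all[, 1], H, W),
                 hemoglobin_map = matrix(s_all[, 2], H, W),
                 mixing = mixing, mean_absorbance = mu,
                 shading_map = matrix(shade, H, W), basis = B,
                 shading_removed = TRUE, dims = c(H, W)),
            class = "ica_decomposition")
}

#' Re-synthesize a melanin-emphasized image from an ICA decomposition
#'
#' Rebuilds log-RGB absorbance as
#' `mean + mixing %*% (w * sources) + shading`, exponentiates back to RGB and
#' renders per `render`. Unit weights reproduce the rendered original.
#'
#' @param decomp an [ica_decompose()] result.
#' @param w_melanin,w_hemoglobin non-negative component weights.
#' @param render `"blue"` or `"grayscale"` output rendering.
#' @return H x W single-channel image (clipped to [0, 1]).
#' @export
ica_emphasize <- function(decomp, w_melanin, w_hemoglobin,
                          render = c("blue", "grayscale")) {
  render <- match.arg(render)
  if (w_melanin < 0 || w_hemoglobin < 0)
    stop("weights must be >= 0", call. = FALSE)
  s <- cbind(w_melanin * as.vector(decomp$melanin_map),
             w_hemoglobin * as.vector(decomp$hemoglobin_map))
  amat <- s %*% t(decomp$mixing)
  amat <- sweep(amat, 2, decomp$mean_absorbance, `+`) +
    as.vector(decomp$shading_map) %*% t(rep(1, 3) / sqrt(3))
  rgb <- exp(-amat)
  img <- array(rgb, c(decomp$dims, 3))
  out <- if (render == "blue") blue_channel(img) else grayscale(img)
  clip01(out)
}

#' Constrained grid search for the component weights
#'
#' Scans `w_melanin` over `seq(0, weight_sum, by = step)` with
#' `w_hemoglobin = weight_sum - w_melanin` and picks the pair minimizing the
#' pooled median per-pixel L1 (0-255 scale) between the rendered emphasis
#' images and the UV references; ties take the smaller melanin weight.
#'
#' @param decomps list of [ica_decompose()] results.
#' @param uv_refs list of matching H x W UV reference images.
#' @param masks optional list of evaluation masks.
#' @param step grid step (must divide `weight_sum`).
#' @param weight_sum fixed sum of the two weights.
#' @param render rendering passed to [ica_emphasize()].
#' @return list `(w_melanin, w_hemoglobin, objective)` where `objective` is a
#'   tibble over the full grid.
#' @export
weight_grid_search <- function(decomps, uv_refs, masks = NULL, step = 0.1,
                               weight_sum = 2.0, render = "blue") {
  if (length(uv_refs) == 0) stop("empty reference set", call. = FALSE)
  k <- weight_sum / step
  if (abs(k - round(k)) > 1e-9)
    stop("step must divide weight_sum", call. = FALSE)
  wm <- round(seq(0, weight_sum, by = step), 10)
  obj <- vapply(wm, function(w) {
    dists <- unlist(lapply(seq_along(decomps), function(i) {
      img <- ica_emphasize(decomps[[i]], w, weight_sum - w, render)
      d <- 255 * abs(img - uv_refs[[i]])
      if (!is.null(masks)) d[masks[[i]] > 0] else as.vector(d)
    }))
    median(dists)
  }, numeric(1))
  best <- which.min(obj)   # first minimum = smallest w_melanin on ties
  list(w_melanin = wm[best], w_hemoglobin = weight_sum - wm[best],
       objective = tibble::tibble(w_melanin = wm, median_l1 = obj))
}
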