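# Quantitative evaluation: median/mean per-pixel L1 on the 0-255 scale,
# Frechet distance between feature distributions with a pluggable embedder,
# segmentation overlap metrics, correlation/no-intercept regression, L1
# heatmaps and the ablation report table.

#' Per-pixel L1 loss between two images
#'
#' Absolute per-pixel difference scaled to 0-255 within the mask, aggregated
#' by the median (default; robust to outliers) or the mean.
#'
#' @param img_a,img_b equally shaped intensity images on [0, 1].
#' @param mask optional binary mask (default: all pixels); must be non-empty.
#' @param aggregate `"median"` or `"mean"`.
#' @return scalar loss on the 0-255 scale.
#' @export
per_pixel_l1 <- function(img_a, img_b, mask = NULL,
                         aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!all(dim(img_a) == dim(img_b))) stop("shape mismatch", call. = FALSE)
  d <- 255 * abs(img_a - img_b)
  v <- if (is.null(mask)) as.vector(d) else d[mask > 0]
  if (length(v) == 0) stop("empty mask", call. = FALSE)
  if (aggregate == "median") median(v) else mean(v)
}

#' Frechet distance between two feature distributions
#'
#' `|mu1 - mu2|^2 + tr(S1 + S2 - 2 (S1 S2)^(1/2))` with sample means and
#' covariances of the two feature sets. The matrix square root uses an
#' eigendecomposition of the symmetrized product with negative eigenvalues
#' clipped at 0; the result is clipped to be non-negative.
#'
#' @param features_a,features_b matrices (rows = observations, >= 2 per set,
#'   equal dimensionality).
#' @return non-negative distance.
#' @export
fid <- function(features_a, features_b) {
  features_a <- as.matrix(features_a); features_b <- as.matrix(features_b)
  if (ncol(features_a) != ncol(features_b))
    stop("feature dimensionality mismatch", call. = FALSE)
  if (nrow(features_a) < 2 || nrow(features_b) < 2)
    stop("need at least 2 feature vectors per set", call. = FALSE)
  mu1 <- colMeans(features_a); mu2 <- colMeans(features_b)
  s1 <- cov(features_a); s2 <- cov(features_b)
  prod_sym <- (s1 %*% s2 + t(s1 %*% s2)) / 2
  ev <- eigen(prod_sym, symmetric = TRUE)
  sqrt_tr <- sum(sqrt(pmax(ev$values, 0)))
  val <- sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sqrt_tr
  max(val, 0)
}

#' Deterministic toy feature embedder for Frechet evaluation
#'
#' Features per patch: the patch block-averaged to 16 x 16, plus 8 x 8 pools
#' of the horizontal and vertical gradient magnitudes (so blur and sharpness
#' move the embedding), projected to `out_dim` dimensions with a fixed-seed
#' random linear map. Deterministic given `seed`.
#'
#' @param out_dim embedding dimensionality.
#' @param seed seed of the projection matrix.
#' @return function mapping an `S x S` patch to a numeric vector; carries an
#'   `id` attribute.
#' @export
make_toy_embedder <- function(out_dim = 64, seed = 7) {
  in_dim <- 16 * 16 + 8 * 8 + 8 * 8
  proj <- with_seed(seed, matrix(rnorm(in_dim * out_dim) / sqrt(in_dim),
                                 out_dim, in_dim))
  f <- function(patch) {
    if (length(dim(patch)) == 3) patch <- patch[, , 1]
    gx <- abs(patch[, -1, drop = FALSE] - patch[, -ncol(patch), drop = FALSE])
    gy <- abs(patch[-1, , drop = FALSE] - patch[-nrow(patch), , drop = FALSE])
    v <- c(as.vector(resize_mean(patch, 16, 16)),
           as.vector(resize_mean(gx, 8, 8)), as.vector(resize_mean(gy, 8, 8)))
    drop(proj %*% v)
  }
  attr(f, "id") <- sprintf("toy-proj-%d-seed-%d", out_dim, seed)
  f
}

#' Embed face-region patches of an image set
#'
#' Tiles the region of each image and returns one feature vector per patch.
#'
#' @param images list of H x W intensity images.
#' @param region_masks optional list of binary region masks.
#' @param patch_size,stride tiling geometry.
#' @param embedder patch-embedding function, e.g. [make_toy_embedder()]; a
#'   pretrained deep embedder can be plugged in through the same interface.
#' @param min_mask_fraction minimum region coverage per patch.
#' @return matrix of features (rows = patches).
#' @export
embed_patches <- function(images, region_masks = NULL, patch_size = 32,
                          stride = patch_size,
                          embedder = make_toy_embedder(),
                          min_mask_fraction = 0.5) {
  feats <- list()
  for (i in seq_along(images)) {
    mask <- if (is.null(region_masks)) NULL else region_masks[[i]]
    grid <- plan_grid(dim(images[[i]]), patch_size, stride, region_mask = mask,
                      min_mask_fraction = if (is.null(mask)) 0 else min_mask_fraction)
    ps <- extract_patches(images[[i]], grid)
    feats <- c(feats, lapply(ps, embedder))
  }
  if (length(feats) == 0) stop("no region-covering patches", call. = FALSE)
  do.call(rbind, feats)
}

#' Pixel overlap metrics between predicted and true masks
#'
#' IoU, recall, precision and F-measure inside the evaluation region.
#' Conventions: both masks empty gives all metrics 1; empty truth with
#' non-empty prediction gives recall `NA`, IoU and precision 0, F `NA`.
#'
#' @param pred,truth binary masks of equal shape.
#' @param region optional binary evaluation region.
#' @return list `(iou, recall, precision, f)` plus the pixel confusion counts
#'   `(tp, fp, fn, tn)`.
#' @export
mask_metrics <- function(pred, truth, region = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch", call. = FALSE)
  if (is.null(region)) region <- array(1, dim(pred))
  p <- pred[region > 0] > 0
  t <- truth[region > 0] > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  if (tp + fn == 0 && tp + fp == 0)
    return(list(iou = 1, recall = 1, precision = 1, f = 1,
                tp = tp, fp = fp, fn = fn, tn = tn))
  if (tp + fn == 0)
    return(list(iou = 0, recall = NA_real_, precision = 0, f = NA_real_,
                tp = tp, fp = fp, fn = fn, tn = tn))
  iou <- tp / (tp + fp + fn)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(iou = iou, recall = recall, precision = precision, f = f,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Pearson product-moment correlation
#' @param x,y numeric vectors (length >= 3, non-zero variance).
#' @return correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need vectors of equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance", call. = FALSE)
  cor(x, y)
}

#' Slope of the least-squares regression through the origin
#' @param x,y numeric vectors; `sum(x^2)` must be positive.
#' @return slope `sum(x * y) / sum(x^2)`.
#' @export
regress_no_intercept <- function(x, y) {
  if (sum(x^2) == 0) stop("all-zero x", call. = FALSE)
  unname(coef(lm(y ~ x + 0))[1])
}

#' Pixel-wise L1 heatmap with a rendered overlay
#'
#' @param img_a,img_b equally shaped images on [0, 1].
#' @param mask optional binary mask; the map is 0 outside it.
#' @return list: `map` (H x W, 0-255 scale) and `overlay` (H x W x 3 viridis
#'   rendering blended over `img_a`).
#' @export
l1_heatmap <- function(img_a, img_b, mask = NULL) {
  if (!all(dim(img_a) == dim(img_b))) stop("shape mismatch", call. = FALSE)
  map <- 255 * abs(img_a - img_b)
  if (!is.null(mask)) map <- map * (mask > 0)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))) / 255
  idx <- pmin(pmax(floor(map / 255 * 255) + 1, 1), 256)
  H <- nrow(map); W <- ncol(map)
  heat <- array(pal[idx, ], c(H, W, 3))
  base <- if (length(dim(img_a)) == 3) img_a else array(rep(img_a, 3), c(H, W, 3))
  alpha <- 0.6
  list(map = map, overlay = clip01((1 - alpha) * base + alpha * heat))
}

#' Ablation report over translation variants and baselines
#'
#' Evaluates the four training variants (discriminator x alignment) and the
#' grayscale / blue-channel / ICA baselines on a held-out cohort against the
#' clean registered UV ground truth: pooled median per-pixel L1 within face
#' masks and Frechet distance of face-patch features.
#'
#' @param test_pairs held-out `image_pair` list.
#' @param models named list of `uv_train_state` objects; recognized names
#'   `"disc+align+"`, `"disc-align+"`, `"disc+align-"`, `"disc-align-"`
#'   (missing entries yield NA rows).
#' @param ica_weights `(w_melanin, w_hemoglobin)` used for the ICA rows.
#' @param embedder,patch_size Frechet evaluation settings.
#' @param fid_reference `"observed"` (default) compares feature
#'   distributions against the observed UV captures — the realistic target,
#'   noise and texture included, and registration does not matter for a
#'   distributional distance; `"oracle"` uses the clean registered ground
#'   truth. Median L1 always uses the registered oracle so that aligned
#'   models are not penalized for the test pairs' own misalignment.
#' @return tibble with columns method, discriminator, alignment, median_l1,
#'   fid.
#' @export
ablation_report <- function(test_pairs, models, ica_weights = c(1.3, 0.7),
                            embedder = make_toy_embedder(), patch_size = 32,
                            fid_reference = c("observed", "oracle")) {
  fid_reference <- match.arg(fid_reference)
  refs <- lapply(test_pairs, true_uv_oracle)
  fid_refs <- if (fid_reference == "observed")
    lapply(test_pairs, `[[`, "uv") else refs
  masks <- lapply(test_pairs, `[[`, "face_mask")
  ref_feat <- embed_patches(fid_refs, masks, patch_size, embedder = embedder)
  eval_images <- function(imgs) {
    pooled <- unlist(lapply(seq_along(imgs), function(i)
      (255 * abs(imgs[[i]] - refs[[i]]))[masks[[i]] > 0]))
    c(median_l1 = median(pooled),
      fid = fid(embed_patches(imgs, masks, patch_size, embedder = embedder),
                ref_feat))
  }
  variants <- list(`disc+align+` = c("(+)", "(+)"),
                   `disc-align+` = c("(-)", "(+)"),
                   `disc+align-` = c("(+)", "(-)"),
                   `disc-align-` = c("(-)", "(-)"))
  rows <- list()
  for (nm in names(variants)) {
    if (!is.null(models[[nm]])) {
      imgs <- lapply(test_pairs, function(p)
        convert_image(models[[nm]], p$color, p$face_mask))
      m <- eval_images(imgs)
    } else m <- c(median_l1 = NA_real_, fid = NA_real_)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      method = "uv-net", discriminator = variants[[nm]][1],
      alignment = variants[[nm]][2], median_l1 = m[["median_l1"]],
      fid = m[["fid"]])
  }
  base_fns <- list(
    `ica-blue` = function(p) ica_emphasize(
      ica_decompose(p$color, p$face_mask), ica_weights[1], ica_weights[2],
      "blue"),
    `ica-grayscale` = function(p) ica_emphasize(
      ica_decompose(p$color, p$face_mask), ica_weights[1], ica_weights[2],
      "grayscale"),
    `blue-channel` = function(p) blue_channel(p$color),
    grayscale = function(p) grayscale(p$color))
  for (nm in names(base_fns)) {
    imgs <- lapply(test_pairs, base_fns[[nm]])
    m <- eval_images(imgs)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      method = nm, discriminator = "(-)", alignment = "(-)",
      median_l1 = m[["median_l1"]], fid = m[["fid"]])
  }
  do.call(rbind, rows)
}

#' Write an ablation report as TSV
#' @param report tibble from [ablation_report()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
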