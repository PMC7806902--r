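# Pigment-spot segmentation: the translation U-net with a two-class softmax
# head, trained on cross-entropy plus soft-DICE, with spot-area percentage
# reporting over a cheek/face evaluation region.

#' Soft-DICE loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1`;
#' bounded in [0, 1), 0 iff the probability map equals a non-degenerate
#' binary truth.
#'
#' @param prob_map H x W probabilities on [0, 1].
#' @param truth_mask H x W binary ground truth.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
dice_loss <- function(prob_map, truth_mask, eps = 1) {
  if (!all(dim(prob_map) == dim(truth_mask)))
    stop("shape mismatch", call. = FALSE)
  1 - (2 * sum(prob_map * truth_mask) + eps) /
    (sum(prob_map) + sum(truth_mask) + eps)
}

# gradient of dice_loss wrt prob_map
dice_loss_grad <- function(prob_map, truth_mask, eps = 1) {
  num <- 2 * sum(prob_map * truth_mask) + eps
  den <- sum(prob_map) + sum(truth_mask) + eps
  -(2 * truth_mask * den - num) / den^2
}

#' Spot-segmentation training configuration
#'
#' @param unet a [generator_config()]; the final layer is replaced by a
#'   two-class softmax head.
#' @param ce_weight,dice_weight loss mixture weights (>= 0, not both 0).
#' @param brightness_jitter multiplicative brightness augmentation amplitude.
#' @param iterations,batch_size,lr,val_every,seed optimizer settings.
#' @return a `spot_train_config` list.
#' @export
spot_train_config <- function(unet = generator_config(input_size = 32,
                                                      out_channels = 2),
                              ce_weight = 1, dice_weight = 1,
                              brightness_jitter = 0.1, iterations = 600,
                              batch_size = 4, lr = 1e-3, val_every = 100,
                              seed = 1) {
  if (ce_weight < 0 || dice_weight < 0 || (ce_weight == 0 && dice_weight == 0))
    stop("ce_weight and dice_weight must be >= 0 and not both 0",
         call. = FALSE)
  unet$out_channels <- 2L
  unet$head <- "softmax"
  unet$in_channels <- 1L
  list(unet = unet, ce_weight = ce_weight, dice_weight = dice_weight,
       brightness_jitter = brightness_jitter, iterations = iterations,
       batch_size = batch_size, lr = lr, val_every = val_every, seed = seed)
}

spot_loss_and_grads <- function(params, cfg, x, t) {
  fw <- generator_forward(params, x, cfg$unet, train = TRUE, want_cache = TRUE)
  p1 <- pmax(fw$out[, , 1], 1e-8)   # background prob
  p2 <- pmax(fw$out[, , 2], 1e-8)   # spot prob
  npix <- length(t)
  ce <- -sum(t * log(p2) + (1 - t) * log(p1)) / npix
  dl <- dice_loss(fw$out[, , 2], t)
  d_out <- array(0, dim(fw$out))
  d_out[, , 1] <- cfg$ce_weight * (-(1 - t) / p1) / npix
  d_out[, , 2] <- cfg$ce_weight * (-t / p2) / npix +
    cfg$dice_weight * dice_loss_grad(fw$out[, , 2], t)
  grads <- unet_backprop(params, cfg$unet, fw, d_out)
  list(loss = cfg$ce_weight * ce + cfg$dice_weight * dl, ce = ce, dice = dl,
       grads = grads)
}

#' Train the pigment-spot segmentation network
#'
#' Inputs are single-channel UV (or synthetic-UV) patches with binary
#' ground-truth spot masks. Minimizes
#' `ce_weight * cross_entropy + dice_weight * dice_loss` with Adam; random
#' flips/rotations plus multiplicative brightness jitter as augmentation;
#' early stopping on the validation cost.
#'
#' @param patches list of `S x S` input patches.
#' @param masks list of matching binary spot masks (at least one positive
#'   pixel over the whole set).
#' @param config a [spot_train_config()].
#' @param val_patches,val_masks optional validation set.
#' @return `spot_net` state: `params`, `config`, `val_trace`,
#'   `best_val_cost`.
#' @export
train_spot_net <- function(patches, masks, config = spot_train_config(),
                           val_patches = list(), val_masks = list()) {
  if (sum(vapply(masks, sum, numeric(1))) == 0)
    stop("training masks contain no positive pixel", call. = FALSE)
  n <- length(patches)
  has_val <- length(val_patches) > 0
  with_seed(config$seed, {
    p <- init_generator(config$unet)
    ad <- adam_init(p)
    best <- Inf; best_p <- p
    vt <- list()
    val_cost <- function() {
      mean(vapply(seq_along(val_patches), function(i) {
        o <- generator_forward(p, val_patches[[i]], config$unet)
        pr2 <- pmax(o[, , 2], 1e-8); pr1 <- pmax(o[, , 1], 1e-8)
        t <- val_masks[[i]]
        ce <- -sum(t * log(pr2) + (1 - t) * log(pr1)) / length(t)
        config$ce_weight * ce + config$dice_weight * dice_loss(o[, , 2], t)
      }, numeric(1)))
    }
    for (iter in seq_len(config$iterations)) {
      idx <- sample.int(n, min(config$batch_size, n))
      gacc <- NULL; lo <- 0
      for (i in idx) {
        a <- augment_pair(patches[[i]] |> (\(m) array(m, c(dim(m), 1)))(),
                          masks[[i]])
        x <- a$x
        if (config$brightness_jitter > 0)
          x <- clip01(x * (1 + runif(1, -config$brightness_jitter,
                                     config$brightness_jitter)))
        r <- spot_loss_and_grads(p, config, x, a$y)
        lo <- lo + r$loss
        gacc <- if (is.null(gacc)) r$grads else acc_grads(gacc, r$grads)
      }
      st <- adam_step(p, scale_grads(gacc, 1 / length(idx)), ad, config$lr)
      p <- st$params; ad <- st$state
      if (has_val && (iter %% config$val_every == 0 ||
                      iter == config$iterations)) {
        v <- val_cost()
        vt[[length(vt) + 1L]] <- tibble::tibble(iteration = iter, val_cost = v)
        if (v < best) { best <- v; best_p <- p }
      }
    }
    if (!has_val) best_p <- p
    structure(list(params = best_p, config = config,
                   val_trace = if (length(vt)) do.call(rbind, vt) else NULL,
                   best_val_cost = best),
              class = "spot_net")
  })
}

#' Detect pigment spots in a UV (or synthetic UV) image
#'
#' Patch-wise inference with whole-image probability-map assembly, binarized
#' at 0.5 and intersected with the evaluation region.
#'
#' @param state a [train_spot_net()] result.
#' @param image H x W intensity image on [0, 1].
#' @param region_mask H x W binary evaluation region (cheek/face).
#' @param stride inference grid stride (defaults to the patch size).
#' @return `spot_prediction` list: `prob_map`, binary `mask` (subset of
#'   `region`), `region`.
#' @export
detect_spots <- function(state, image, region_mask,
                         stride = state$config$unet$input_size) {
  size <- state$config$unet$input_size
  grid <- plan_grid(dim(image), size, stride)
  xs <- extract_patches(image, grid)
  ps <- lapply(xs, function(patch) {
    o <- generator_forward(state$params, array(patch, c(dim(patch), 1)),
                           state$config$unet)
    o[, , 2]
  })
  prob <- assemble_patches(ps, grid, fill = 0)
  mask <- (prob >= 0.5) * region_mask
  structure(list(prob_map = prob, mask = mask, region = region_mask),
            class = "spot_prediction")
}

#' Spot-area percentage inside the evaluation region
#'
#' `100 * |mask & region| / |region|` - the skin-damage indicator compared
#' between true and synthetic UV images.
#'
#' @param pred a [detect_spots()] result.
#' @return percentage in [0, 100].
#' @export
spot_area_percentage <- function(pred) {
  npix <- sum(pred$region)
  if (npix == 0) stop("evaluation region is empty", call. = FALSE)
  100 * sum(pred$mask * pred$region) / npix
}
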