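# Three-phase adversarial training of the color -> UV generator:
#   phase 1: alternating generator/discriminator updates (joint),
#   phase 2: discriminator only, best by validation discriminator loss,
#   phase 3: generator only (discriminator frozen), best by validation L1.
# With lambda = 0 only the generator is trained (the "no discriminator"
# ablation) and phases 2-3 collapse into plain generator iterations.

#' Extract paired training patches from image pairs
#'
#' Plans a patch grid over each pair's face mask and extracts co-located
#' (color, UV) patches. When an alignment result is supplied, each color
#' window is translated by the shift of its assigned alignment tile before
#' extraction (windows pushed out of bounds are dropped).
#'
#' @param pairs list of `image_pair` objects.
#' @param patch_size,stride grid geometry in pixels.
#' @param min_mask_fraction minimum face coverage per window.
#' @param alignments optional list of [align_pairs()] results (same length).
#' @return list of `list(x = color patch, y = uv patch)`.
#' @export
training_patches <- function(pairs, patch_size = 64, stride = patch_size,
                             min_mask_fraction = 0.6, alignments = NULL) {
  out <- list()
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    grid <- plan_grid(dim(pair$face_mask), patch_size, stride,
                      region_mask = pair$face_mask,
                      min_mask_fraction = min_mask_fraction)
    if (is.null(alignments)) {
      xs <- extract_patches(pair$color, grid)
      ys <- extract_patches(pair$uv, grid)
      out <- c(out, lapply(seq_along(xs), function(k)
        list(x = xs[[k]], y = ys[[k]])))
    } else {
      out <- c(out, apply_alignment(pair, alignments[[i]], grid))
    }
  }
  out
}

#' Three-phase training schedule
#'
#' Iteration counts for the joint (alternating), discriminator-only and
#' generator-only phases, plus the validation/early-stopping cadence.
#'
#' @param joint,disc_only,gen_only iterations per phase.
#' @param val_every validate (and checkpoint) every this many iterations.
#' @return schedule list consumed by [train_uvnet()].
#' @export
default_schedule <- function(joint = 2000, disc_only = 100, gen_only = 400,
                             val_every = 250) {
  list(joint = joint, disc_only = disc_only, gen_only = gen_only,
       val_every = val_every)
}

#' Train the color-to-UV translation network
#'
#' @param train_patches,val_patches lists of `list(x, y)` patch pairs (see
#'   [training_patches()]); an empty validation set disables early stopping
#'   with a warning.
#' @param gen_config,disc_config network configurations.
#' @param lambda adversarial weight; 0 trains the generator alone under pure
#'   per-pixel L1.
#' @param schedule list `(joint, disc_only, gen_only, val_every)` iteration
#'   counts; see [default_schedule()].
#' @param batch_size patches per update.
#' @param lr Adam learning rate of the generator.
#' @param d_lr Adam learning rate of the discriminator. The default (lr / 4)
#'   keeps the two players balanced at desk scale: a discriminator that wins
#'   outright saturates the `log(1 - D)` generator term and the adversarial
#'   gradient vanishes.
#' @param seed RNG seed; identical seed + config reproduces the run exactly.
#' @param augment random flips / 90-degree rotations.
#' @param verbose print progress.
#' @return `uv_train_state`: best `gen_params`, `disc_params`, configs,
#'   `best_val_l1` (value + iteration), `traces` tibble (iteration, phase,
#'   g_loss, d_loss, val_l1), `seed`.
#' @export
train_uvnet <- function(train_patches, val_patches = list(),
                        gen_config = generator_config(),
                        disc_config = discriminator_config(
                          input_size = gen_config$input_size),
                        lambda = 0.005,
                        schedule = default_schedule(),
                        batch_size = 4, lr = 1e-3, d_lr = lr / 4, seed = 1,
                        augment = TRUE, verbose = FALSE) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  n <- length(train_patches)
  if (n == 0) stop("no training patches", call. = FALSE)
  has_val <- length(val_patches) > 0
  if (!has_val) warning("empty validation set: early stopping disabled")

  with_seed(seed, {
    gp <- init_generator(gen_config)
    dp <- init_discriminator(disc_config)
    ga <- adam_init(gp)
    da <- adam_init(dp)
    best_gen <- gp; best_disc <- dp
    best_l1 <- Inf; best_iter <- 0L
    trace <- list()

    disc_fn <- function(x, uv) disc_forward_cache(dp, x, uv, disc_config)$p
    p_fake_last <- NA_real_   # mean D(fake) of the latest discriminator step

    sample_batch <- function(k) {
      idx <- sample.int(n, min(k, n), replace = k > n)
      list(idx = idx, items = lapply(train_patches[idx], function(b) {
        if (augment) {
          a <- augment_pair(b$x, b$y)
          list(x = a$x, y = a$y)
        } else b
      }))
    }

    g_step <- function() {
      b <- sample_batch(batch_size)
      gacc <- NULL; l1s <- 0
      for (it in b$items) {
        r <- generator_grads(gp, gen_config, it$x, it$y, lambda = lambda,
                             disc = dp, disc_config = disc_config,
                             train = TRUE)
        gacc <- if (is.null(gacc)) r$grads else acc_grads(gacc, r$grads)
        l1s <- l1s + r$l1
      }
      gacc <- scale_grads(gacc, 1 / length(b$items))
      st <- adam_step(gp, gacc, ga, lr)
      gp <<- st$params; ga <<- st$state
      l1s / length(b$items)
    }

    d_step <- function() {
      # disjoint fake (I) / real (J) halves of one sample
      b <- sample_batch(2 * max(1, batch_size))
      half <- length(b$items) %/% 2
      fake <- b$items[seq_len(half)]
      real <- b$items[half + seq_len(half)]
      dacc <- NULL; lval <- 0; pf <- 0
      for (it in fake) {
        gx <- generator_forward(gp, it$x, gen_config, train = FALSE)
        fw <- disc_forward_cache(dp, it$x, gx, disc_config)
        pf <- pf + fw$p
        lval <- lval - log(1 - clamp_prob(fw$p)) / half
        bw <- disc_backward(dp, disc_config, fw, fw$p / half, wrt = "params")
        dacc <- if (is.null(dacc)) bw$grads else acc_grads(dacc, bw$grads)
      }
      for (it in real) {
        fw <- disc_forward_cache(dp, it$x, it$y, disc_config)
        lval <- lval - log(clamp_prob(fw$p)) / half
        bw <- disc_backward(dp, disc_config, fw, (fw$p - 1) / half,
                            wrt = "params")
        dacc <- acc_grads(dacc, bw$grads)
      }
      st <- adam_step(dp, dacc, da, d_lr)
      dp <<- st$params; da <<- st$state
      p_fake_last <<- pf / half
      lval
    }

    val_l1 <- function() {
      if (!has_val) return(NA_real_)
      mean(vapply(val_patches, function(b) {
        gx <- generator_forward(gp, b$x, gen_config, train = FALSE)
        mean(abs(b$y - gx))
      }, numeric(1)))
    }
    val_dloss <- function() {
      if (!has_val) return(NA_real_)
      half <- max(1, length(val_patches) %/% 2)
      fake <- lapply(val_patches[seq_len(half)], function(b)
        list(x = b$x, uv = generator_forward(gp, b$x, gen_config)))
      real <- val_patches[half + seq_len(min(half, length(val_patches) - half))]
      if (length(real) == 0) real <- val_patches[half]
      discriminator_loss(fake, real, disc_fn)
    }

    note <- function(iter, phase, g = NA, d = NA, v = NA)
      trace[[length(trace) + 1L]] <<- tibble::tibble(
        iteration = iter, phase = phase, g_loss = g, d_loss = d, val_l1 = v,
        p_fake = p_fake_last)

    check_best <- function(iter) {
      v <- val_l1()
      if (has_val && v < best_l1) {
        best_l1 <<- v; best_iter <<- iter
        best_gen <<- gp; best_disc <<- dp
      }
      v
    }

    # phase 1: alternating updates
    for (iter in seq_len(schedule$joint)) {
      gl <- g_step()
      dl <- if (lambda > 0) d_step() else NA_real_
      if (iter %% schedule$val_every == 0 || iter == schedule$joint) {
        v <- check_best(iter)
        note(iter, "joint", gl, dl, v)
        if (verbose) message(sprintf("joint %d: g=%.4f d=%.4f val=%.4f",
                                     iter, gl, dl, v))
      }
    }
    if (!has_val) { best_gen <- gp; best_disc <- dp }
    gp <- best_gen; dp <- best_disc

    # phase 2: discriminator refinement
    if (lambda > 0 && schedule$disc_only > 0) {
      best_dv <- Inf
      for (iter in seq_len(schedule$disc_only)) {
        dl <- d_step()
        if (iter %% schedule$val_every == 0 || iter == schedule$disc_only) {
          dv <- val_dloss()
          if (!has_val || (is.finite(dv) && dv < best_dv)) {
            best_dv <- dv; best_disc <- dp
          }
          note(schedule$joint + iter, "disc_only", NA, dl, NA)
        }
      }
      dp <- best_disc
    }

    # phase 3: generator refinement against the frozen discriminator
    if (schedule$gen_only > 0) {
      for (iter in seq_len(schedule$gen_only)) {
        gl <- g_step()
        if (iter %% schedule$val_every == 0 || iter == schedule$gen_only) {
          v <- check_best(schedule$joint + schedule$disc_only + iter)
          note(schedule$joint + schedule$disc_only + iter, "gen_only",
               gl, NA, v)
        }
      }
      if (has_val) gp <- best_gen else best_gen <- gp
    }

    structure(list(gen_params = best_gen, disc_params = best_disc,
                   gen_config = gen_config, disc_config = disc_config,
                   lambda = lambda, schedule = schedule, seed = seed,
                   batch_size = batch_size, lr = lr, d_lr = d_lr,
                   best_val_l1 = list(value = best_l1, iteration = best_iter),
                   traces = do.call(rbind, trace)),
              class = "uv_train_state")
  })
}

#' @export
print.uv_train_state <- function(x, ...) {
  cat("color->UV translation state\n")
  cat(sprintf("  lambda = %g, input %d px, depth %d, base %d channels\n",
              x$lambda, x$gen_config$input_size, x$gen_config$depth,
              x$gen_config$base_channels))
  cat(sprintf("  best validation L1 = %.4f at iteration %d\n",
              x$best_val_l1$value, x$best_val_l1$iteration))
  invisible(x)
}

#' Convert a whole color image to a synthetic UV image
#'
#' Plans a patch grid (restricted to the face map when given), converts each
#' color patch with the trained generator and reassembles the whole image;
#' pixels covered by no window pass through as the grayscale of the input.
#'
#' @param state a [train_uvnet()] result (or a list with `gen_params` +
#'   `gen_config`).
#' @param color H x W x 3 color image on [0, 1].
#' @param face_map optional binary face-region mask.
#' @param stride grid stride (defaults to the patch size: disjoint tiles).
#' @param min_mask_fraction minimum face coverage per converted window.
#' @return H x W synthetic UV image on [0, 1].
#' @export
convert_image <- function(state, color, face_map = NULL,
                          stride = state$gen_config$input_size,
                          min_mask_fraction = 0.05) {
  size <- state$gen_config$input_size
  grid <- plan_grid(dim(color)[1:2], size, stride, region_mask = face_map,
                    min_mask_fraction = if (is.null(face_map)) 0 else min_mask_fraction)
  xs <- extract_patches(color, grid)
  ys <- lapply(xs, function(p)
    generator_forward(state$gen_params, p, state$gen_config, train = FALSE))
  assemble_patches(ys, grid, fill = grayscale(color))
}
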