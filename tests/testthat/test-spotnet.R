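test_that("soft-DICE loss matches hand-computed values and is symmetric on binaries", {
  t <- matrix(0, 10, 10); t[1:5, ] <- 1               # 50 positive px
  expect_lt(dice_loss(t, t), 1e-2)                    # eps keeps it near 0
  expect_gt(dice_loss(1 - t, t), 0.98)
  p_half <- matrix(0.5, 10, 10)
  # 1 - (2*25 + 1) / (50 + 50 + 1)
  expect_equal(dice_loss(p_half, t), 1 - 51 / 101, tolerance = 1e-12)
  expect_equal(dice_loss(p_half, t), 0.495, tolerance = 1e-3)
  set.seed(81)
  a <- matrix(rbinom(100, 1, 0.4), 10, 10)
  b <- matrix(rbinom(100, 1, 0.4), 10, 10)
  expect_equal(dice_loss(a, b), dice_loss(b, a))
  expect_gte(dice_loss(a, b), 0)
  expect_lt(dice_loss(a, b), 1)
  expect_error(dice_loss(a, b[1:5, 1:5]), "shape")
  # analytic gradient agrees with finite differences
  p <- matrix(runif(25), 5, 5); tt <- matrix(rbinom(25, 1, 0.3), 5, 5)
  g <- uvsynth:::dice_loss_grad(p, tt)
  i <- sample(25, 5)
  num <- vapply(i, function(k) {
    p1 <- p; p1[k] <- p1[k] + 1e-6
    p2 <- p; p2[k] <- p2[k] - 1e-6
    (dice_loss(p1, tt) - dice_loss(p2, tt)) / 2e-6
  }, numeric(1))
  expect_equal(num, g[i], tolerance = 1e-6)
})

test_that("spot-net configuration validates the loss mixture", {
  expect_error(spot_train_config(ce_weight = 0, dice_weight = 0), "not both 0")
  expect_error(spot_train_config(ce_weight = -1), "not both 0|>= 0")
  cfg <- spot_train_config(ce_weight = 1, dice_weight = 0)
  expect_equal(cfg$unet$out_channels, 2L)
  expect_equal(cfg$unet$head, "softmax")
})

test_that("with dice_weight = 0 the training cost is pure cross-entropy", {
  set.seed(82)
  cfg <- spot_train_config(generator_config(input_size = 16, depth = 2,
                                            base_channels = 2,
                                            out_channels = 2,
                                            dropout_rate = 0),
                           ce_weight = 1, dice_weight = 0)
  p <- uvsynth:::with_seed(2, uvsynth:::init_generator(cfg$unet))
  x <- array(runif(256), c(16, 16, 1))
  t <- matrix(rbinom(256, 1, 0.3), 16, 16)
  r <- uvsynth:::spot_loss_and_grads(p, cfg, x, t)
  o <- generator_forward(p, x, cfg$unet)
  ce <- -sum(t * log(pmax(o[, , 2], 1e-8)) +
               (1 - t) * log(pmax(o[, , 1], 1e-8))) / length(t)
  expect_equal(r$loss, ce, tolerance = 1e-10)
  expect_equal(r$ce, ce, tolerance = 1e-10)
})

test_that("training is seeded-reproducible and refuses all-negative masks", {
  co <- make_cohort(2, tiny_params(seed = 83, misalign_max = 0,
                                   n_spots = 12))
  xs <- list(); ms <- list()
  for (pair in co) {
    g <- plan_grid(dim(pair$uv), 32, 32, region_mask = pair$face_mask,
                   min_mask_fraction = 0.6)
    xs <- c(xs, extract_patches(pair$uv, g))
    ms <- c(ms, extract_patches(pair$spot_mask, g))
  }
  cfg <- spot_train_config(generator_config(input_size = 32, depth = 3,
                                            base_channels = 4,
                                            out_channels = 2),
                           iterations = 40, batch_size = 2, val_every = 20,
                           seed = 3)
  s1 <- train_spot_net(xs, ms, cfg, xs[1:2], ms[1:2])
  s2 <- train_spot_net(xs, ms, cfg, xs[1:2], ms[1:2])
  expect_identical(s1$val_trace, s2$val_trace)
  zero_masks <- lapply(ms, function(m) m * 0)
  expect_error(train_spot_net(xs, zero_masks, cfg), "no positive")
})

test_that("spot predictions are restricted to the region and area % is exact arithmetic", {
  region <- matrix(0, 10, 10); region[1:5, ] <- 1     # 50 px region
  mask <- matrix(0, 10, 10); mask[1:5, 1:5] <- 1      # 25 spot px inside
  pred <- structure(list(prob_map = mask, mask = mask * region,
                         region = region), class = "spot_prediction")
  expect_equal(spot_area_percentage(pred), 50)
  pred2 <- pred; pred2$mask <- region
  expect_equal(spot_area_percentage(pred2), 100)
  pred3 <- pred; pred3$mask <- mask * 0
  expect_equal(spot_area_percentage(pred3), 0)
  pred4 <- structure(list(prob_map = mask, mask = matrix(0, 2, 2),
                          region = matrix(0, 2, 2)), class = "spot_prediction")
  expect_error(spot_area_percentage(pred4), "empty")
  # 25 spot px in a 500 px region -> 5 %
  region5 <- matrix(0, 25, 20); region5[1:25, 1:20] <- 1
  m5 <- matrix(0, 25, 20); m5[1:5, 1:5] <- 1
  pr5 <- structure(list(prob_map = m5, mask = m5, region = region5),
                   class = "spot_prediction")
  expect_equal(spot_area_percentage(pr5), 5)

  # detect_spots honors an empty region and the mask-subset invariant
  cfg <- spot_train_config(generator_config(input_size = 32, depth = 3,
                                            base_channels = 2,
                                            out_channels = 2))
  st <- structure(list(params = uvsynth:::with_seed(4, uvsynth:::init_generator(cfg$unet)),
                       config = cfg), class = "spot_net")
  img <- uvsynth:::with_seed(5, matrix(runif(64 * 64), 64, 64))
  e <- detect_spots(st, img, matrix(0, 64, 64))
  expect_equal(sum(e$mask), 0)
  r <- detect_spots(st, img, rbind(matrix(1, 32, 64), matrix(0, 32, 64)))
  expect_true(all(r$mask <= r$region))
  expect_true(all(r$prob_map >= 0 & r$prob_map <= 1))
})
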