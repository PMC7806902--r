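# Objective algebra with stub networks, forward-pass contracts, and a short
# seeded training run.

test_that("generator forward is bounded, deterministic in inference, shape-checked", {
  cfg <- tiny_gen_config()
  gp <- uvsynth:::with_seed(1, uvsynth:::init_generator(cfg))
  x <- uvsynth:::with_seed(2, array(runif(32 * 32 * 3), c(32, 32, 3)))
  o1 <- generator_forward(gp, x, cfg)
  o2 <- generator_forward(gp, x, cfg)
  expect_identical(o1, o2)
  expect_true(min(o1) >= 0 && max(o1) <= 1)
  expect_equal(dim(o1), c(32, 32))
  expect_error(generator_forward(gp, x[1:16, 1:16, ], cfg), "input_size")
})

test_that("innermost encoding halves the resolution per level", {
  cfg <- tiny_gen_config(input_size = 64, depth = 3)
  gp <- uvsynth:::with_seed(1, uvsynth:::init_generator(cfg))
  x <- array(0.5, c(64, 64, 3))
  fw <- generator_forward(gp, x, cfg, want_cache = TRUE)
  expect_equal(dim(fw$cache$enc[[3]])[1:2], c(8, 8))  # 64 / 2^3
  expect_equal(dim(fw$cache$enc[[1]])[1:2], c(32, 32))
})

test_that("discriminator output lies strictly inside (0, 1), near 1/2 at init", {
  dcfg <- discriminator_config(depth = 2, base_channels = 4, input_size = 32)
  dp <- uvsynth:::with_seed(3, uvsynth:::init_discriminator(dcfg))
  ps <- uvsynth:::with_seed(4, vapply(1:100, function(i) {
    x <- array(runif(32 * 32 * 3), c(32, 32, 3))
    uv <- matrix(runif(1024), 32, 32)
    discriminator_forward(dp, x, uv, dcfg)
  }, numeric(1)))
  expect_true(all(ps > 0 & ps < 1))
  expect_lt(abs(mean(ps) - 0.5), 0.15)
  # a saturated logit is clamped away from exactly 0/1
  dp2 <- dp
  dp2$fc.b <- 1e6
  expect_lt(discriminator_forward(dp2, array(0.5, c(32, 32, 3)),
                                  matrix(0.5, 32, 32), dcfg), 1)
  expect_error(discriminator_forward(dp, array(0.5, c(16, 16, 3)),
                                     matrix(0.5, 16, 16), dcfg), "size")
})

test_that("generator objective reduces to per-pixel L1 at lambda = 0 and adds the stub adversarial term", {
  cfg <- tiny_gen_config(input_size = 16, depth = 2, base_channels = 2)
  gp <- uvsynth:::with_seed(5, uvsynth:::init_generator(cfg))
  x <- array(0.5, c(16, 16, 3))
  gx <- generator_forward(gp, x, cfg)
  # batch where target equals the generator output -> zero L1
  b0 <- list(list(x = x, y = gx))
  expect_equal(generator_loss(b0, gp, cfg, lambda = 0)$loss, 0)
  # constant offset of 0.1 -> loss 0.1
  b1 <- list(list(x = x, y = gx + 0.1))
  expect_equal(generator_loss(b1, gp, cfg, lambda = 0)$loss, 0.1,
               tolerance = 1e-12)
  # D == 0.5 stub adds lambda * log(0.5)
  r <- generator_loss(b1, gp, cfg, lambda = 0.005,
                      disc_fn = function(x, uv) 0.5)
  expect_equal(r$loss, 0.1 + 0.005 * log(0.5), tolerance = 1e-12)
  expect_equal(r$terms$l1_term, 0.1, tolerance = 1e-12)
  expect_error(generator_loss(list(), gp, cfg), "empty")
})

test_that("discriminator objective matches stub closed forms and enforces disjoint index sets", {
  fake <- list(list(x = 0, uv = 0))
  real <- list(list(x = 0, y = 0))
  stub <- function(x, uv) 0.5
  expect_equal(discriminator_loss(fake, real, stub), 2 * log(2),
               tolerance = 1e-9)
  eps <- uvsynth:::DISC_EPS
  perfect <- local({i <- 0; function(x, uv) {i <<- i + 1; if (i == 1) eps else 1 - eps}})
  expect_lt(discriminator_loss(fake, real, perfect), 1e-5)
  anti <- local({i <- 0; function(x, uv) {i <<- i + 1; if (i == 1) 1 - eps else eps}})
  expect_equal(discriminator_loss(fake, real, anti), 2 * log(1 / eps),
               tolerance = 1e-6)
  expect_error(discriminator_loss(fake, real, stub, fake_idx = 1:3,
                                  real_idx = 3:5), "disjoint")
})

test_that("a single small generator step decreases the objective", {
  set.seed(21)
  cfg <- tiny_gen_config(input_size = 16, depth = 2, base_channels = 2)
  gp <- uvsynth:::init_generator(cfg)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(runif(256), 16, 16)
  r <- uvsynth:::generator_grads(gp, cfg, x, y, lambda = 0, train = FALSE)
  gp2 <- gp
  for (nm in names(gp)) gp2[[nm]] <- gp[[nm]] - 1e-3 * r$grads[[nm]]
  l0 <- mean(abs(y - generator_forward(gp, x, cfg)))
  l1 <- mean(abs(y - generator_forward(gp2, x, cfg)))
  expect_lt(l1, l0)
})

test_that("short seeded training runs are reproducible and reduce validation L1", {
  p <- tiny_params(seed = 31, misalign_max = 0)
  co <- make_cohort(5, p)
  tp <- training_patches(co[1:4], 32, 32, min_mask_fraction = 0.5)
  vp <- training_patches(co[5], 32, 32, min_mask_fraction = 0.5)
  sched <- default_schedule(joint = 200, disc_only = 0, gen_only = 0,
                            val_every = 50)
  st1 <- train_uvnet(tp, vp, gen_config = tiny_gen_config(), lambda = 0,
                     schedule = sched, batch_size = 2, lr = 1e-3, seed = 7)
  st2 <- train_uvnet(tp, vp, gen_config = tiny_gen_config(), lambda = 0,
                     schedule = sched, batch_size = 2, lr = 1e-3, seed = 7)
  expect_identical(st1$traces, st2$traces)
  tr <- st1$traces
  expect_lt(tr$val_l1[nrow(tr)], tr$val_l1[1])
  expect_s3_class(st1, "uv_train_state")
  expect_warning(train_uvnet(tp, list(), gen_config = tiny_gen_config(),
                             lambda = 0,
                             schedule = default_schedule(5, 0, 0, 5),
                             batch_size = 2, seed = 1),
                 "validation")
})

test_that("whole-image conversion assembles patches and passes through uncovered pixels", {
  p <- tiny_params(seed = 32, misalign_max = 0, noise_sigma = 0)
  pair <- make_phantom(p)
  cfg <- tiny_gen_config()
  gp <- uvsynth:::with_seed(6, uvsynth:::init_generator(cfg))
  st <- structure(list(gen_params = gp, gen_config = cfg),
                  class = "uv_train_state")
  uv <- convert_image(st, pair$color, pair$face_mask)
  expect_equal(dim(uv), dim(pair$uv))
  # pixels outside every face window equal the grayscale pass-through
  grid <- plan_grid(dim(pair$color)[1:2], 32, 32, region_mask = pair$face_mask,
                    min_mask_fraction = 0.05)
  covered <- matrix(FALSE, nrow(uv), ncol(uv))
  for (i in seq_len(nrow(grid$windows))) {
    w <- grid$windows[i, ]
    covered[(w$row0 + 1):min(w$row0 + w$size, nrow(uv)),
            (w$col0 + 1):min(w$col0 + w$size, ncol(uv))] <- TRUE
  }
  gs <- grayscale(pair$color)
  expect_equal(uv[!covered], gs[!covered])
})
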