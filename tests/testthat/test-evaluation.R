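test_that("per-pixel L1 aggregates masked 0-255 distances by median or mean", {
  a <- matrix(0.5, 3, 3)
  expect_equal(per_pixel_l1(a, a), 0)
  b <- a
  b[1, 1] <- a[1, 1] + 0 / 255
  b[1, 2] <- a[1, 2] + 10 / 255
  b[1, 3] <- a[1, 3] - 255 / 255 + 0.5   # distance 127.5... keep exact values
  b <- a
  mask <- matrix(0, 3, 3); mask[1, ] <- 1
  b[1, 1] <- 0.5; b[1, 2] <- 0.5 + 10 / 255; b[1, 3] <- 0.5 + 255 / 255
  expect_equal(per_pixel_l1(a, b, mask), 10)
  expect_equal(per_pixel_l1(a, b, mask, aggregate = "mean"),
               mean(c(0, 10, 255)), tolerance = 1e-9)
  # permutation invariance
  set.seed(61)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  p <- sample(64)
  expect_equal(per_pixel_l1(x, y),
               per_pixel_l1(matrix(x[p], 8, 8), matrix(y[p], 8, 8)))
  expect_error(per_pixel_l1(x, y, matrix(0, 8, 8)), "empty mask")
  expect_error(per_pixel_l1(x, y[1:4, 1:4]), "shape")
})

test_that("Frechet distance matches 1-D closed forms, symmetry and identity", {
  # identical sets
  set.seed(62)
  f <- matrix(rnorm(50 * 4), 50, 4)
  expect_lt(fid(f, f), 1e-8)
  # point masses at 0 and 1 -> squared mean distance 1
  expect_equal(fid(matrix(c(0, 0), 2, 1), matrix(c(1, 1), 2, 1)), 1)
  # 1-D sets with sample moments mu = (0, 1), var = (1, 4):
  # (0-1)^2 + 1 + 4 - 2*sqrt(4) = 2
  a <- c(-1, 0, 1)                # mean 0, var 1
  b <- c(-1, 1, 3)                # mean 1, var 4
  expect_equal(fid(matrix(a), matrix(b)), 2, tolerance = 1e-12)
  g <- matrix(rnorm(50 * 4, 1), 50, 4)
  expect_equal(fid(f, g), fid(g, f), tolerance = 1e-8)
  expect_gte(fid(f, g), 0)
  expect_error(fid(f, matrix(0, 10, 3)), "dimensionality")
  expect_error(fid(f[1, , drop = FALSE], f), "at least 2")
})

test_that("patch embedding is deterministic and separates spotty from spotless cohorts", {
  emb <- make_toy_embedder(seed = 7)
  clean_params <- function(seed) tiny_params(seed = seed, n_spots = 0,
                                             noise_sigma = 0, misalign_max = 0)
  spotty_params <- function(seed) tiny_params(seed = seed, n_spots = 25,
                                              spot_radius_range = c(3, 6),
                                              noise_sigma = 0,
                                              misalign_max = 0)
  cohort_feats <- function(pf, seeds) {
    imgs <- lapply(seeds, function(s) { pr <- make_phantom(pf(s)); pr$uv })
    masks <- lapply(seeds, function(s) make_phantom(pf(s))$face_mask)
    embed_patches(imgs, masks, patch_size = 32, embedder = emb)
  }
  fa <- cohort_feats(clean_params, 1:4)
  fa2 <- cohort_feats(clean_params, 1:4)
  expect_identical(fa, fa2)
  expect_lt(fid(fa, fa2), 1e-12)
  fb <- cohort_feats(clean_params, 5:8)
  fs <- cohort_feats(spotty_params, 9:12)
  expect_gt(fid(fa, fs), fid(fa, fb))
  expect_error(embed_patches(list(matrix(0, 64, 64)),
                             list(matrix(0, 64, 64)), 32, embedder = emb),
               "no region")
})

test_that("overlap metrics follow the confusion-count definitions and NA conventions", {
  # truth 100 px, prediction 50 px, overlap 25 px
  t2 <- matrix(0, 1, 200); t2[1:100] <- 1
  p2 <- matrix(0, 1, 200); p2[76:125] <- 1            # 50 px, overlap 25
  m2 <- mask_metrics(p2, t2)
  expect_equal(m2$iou, 25 / 125)
  expect_equal(m2$recall, 0.25)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$f, 2 * 0.5 * 0.25 / 0.75)
  # identical non-empty masks
  m3 <- mask_metrics(t2, t2)
  expect_equal(unlist(m3[c("iou", "recall", "precision", "f")]),
               c(iou = 1, recall = 1, precision = 1, f = 1))
  # disjoint non-empty
  d1 <- matrix(c(1, 0), 1, 2); d2 <- matrix(c(0, 1), 1, 2)
  m4 <- mask_metrics(d1, d2)
  expect_equal(unlist(m4[c("iou", "recall", "precision", "f")]),
               c(iou = 0, recall = 0, precision = 0, f = 0))
  # empty truth conventions
  z <- matrix(0, 2, 2)
  m5 <- mask_metrics(z, z)
  expect_equal(m5$iou, 1)
  m6 <- mask_metrics(d1, matrix(0, 1, 2))
  expect_true(is.na(m6$recall))
  expect_equal(m6$iou, 0)
  expect_equal(m6$precision, 0)
  # IoU never exceeds min(precision, recall); F is the harmonic mean
  set.seed(63)
  for (i in 1:20) {
    a <- matrix(rbinom(100, 1, 0.3), 10, 10)
    b <- matrix(rbinom(100, 1, 0.3), 10, 10)
    m <- mask_metrics(a, b)
    if (!anyNA(unlist(m[1:4])) && m$precision + m$recall > 0) {
      expect_lte(m$iou, min(m$precision, m$recall) + 1e-12)
      expect_equal(m$f, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
  }
})

test_that("correlation and no-intercept regression match direct-summation oracles", {
  expect_equal(pearson(1:5, 2 * (1:5)), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), pearson_oracle(c(1, 2, 3), c(1, 2, 4)),
               tolerance = 1e-12)
  expect_equal(round(pearson(c(1, 2, 3), c(1, 2, 4)), 4), 0.9820)
  expect_equal(regress_no_intercept(c(1, 2), c(2, 4)), 2)
  expect_equal(regress_no_intercept(1:7, 1:7), 1)
  expect_equal(regress_no_intercept(c(1, 2), c(1, 1)), 0.6)
  set.seed(64)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n, x)
    expect_equal(pearson(x, y), pearson_oracle(x, y), tolerance = 1e-12)
    expect_equal(regress_no_intercept(x, y), slope_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson(1:2, 1:2), "length")
  expect_error(regress_no_intercept(c(0, 0), c(1, 2)), "zero")
})

test_that("L1 heatmaps scale to 0-255 inside the mask and render an overlay", {
  a <- matrix(0.2, 8, 8); b <- matrix(0.6, 8, 8)
  mask <- matrix(0, 8, 8); mask[1:4, ] <- 1
  h <- l1_heatmap(a, b, mask)
  expect_equal(h$map[1, 1], 255 * 0.4)
  expect_true(all(h$map[5:8, ] == 0))
  expect_equal(dim(h$overlay), c(8, 8, 3))
  expect_true(all(h$overlay >= 0 & h$overlay <= 1))
  h0 <- l1_heatmap(a, a)
  expect_true(all(h0$map == 0))
})

test_that("the ablation report has the Table-2 shape with NA rows for missing variants", {
  p <- tiny_params(seed = 65, misalign_max = 0, noise_sigma = 0)
  test_pairs <- make_cohort(2, p)
  rep <- ablation_report(test_pairs, models = list(), patch_size = 32)
  expect_equal(nrow(rep), 8)
  expect_equal(sum(rep$method == "uv-net"), 4)
  expect_true(all(is.na(rep$median_l1[rep$method == "uv-net"])))
  base <- rep[rep$method != "uv-net", ]
  expect_true(all(base$median_l1 >= 0))
  expect_true(all(base$fid >= 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 8)
})
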