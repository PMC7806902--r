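test_that("shift search handles identity, planted translation and flat ties", {
  set.seed(41)
  tile <- matrix(runif(32 * 32), 32, 32)
  r <- search_shift(tile, tile, 5)
  expect_equal(c(r$dy, r$dx, r$score), c(0, 0, 0))
  # reference translated by (+3, -2): content moves +3 rows, -2 cols
  ref <- translate_image(tile, 3, -2, fill = "edge")
  # uv = tile; translating ref by (-3, +2) undoes the displacement
  r2 <- search_shift(tile, ref, 5)
  expect_equal(c(r2$dy, r2$dx), c(-3, 2))
  # constant tiles: every score ties; tie-break picks (0, 0)
  r3 <- search_shift(matrix(1, 16, 16), matrix(1, 16, 16), 4)
  expect_equal(c(r3$dy, r3$dx), c(0, 0))
  expect_error(search_shift(tile, tile[1:16, 1:16], 5), "same size")
  expect_error(search_shift(tile, tile, 40), "radius")
})

test_that("compiled shift search agrees exactly with the brute-force scorer", {
  set.seed(42)
  for (trial in 1:100) {
    radius <- sample(0:5, 1)
    uv <- matrix(runif(32 * 32), 32, 32)
    ref <- matrix(runif(32 * 32), 32, 32)
    if (trial %% 3 == 0) ref <- translate_image(uv, sample(-3:3, 1),
                                                sample(-3:3, 1), fill = "edge")
    a <- search_shift(uv, ref, radius)
    b <- search_shift_bruteforce(uv, ref, radius)
    expect_identical(c(a$dy, a$dx), c(b$dy, b$dx))
    expect_equal(a$score, b$score, tolerance = 1e-12)
  }
})

test_that("planted piecewise-constant shifts are recovered exactly with the oracle surrogate", {
  p <- tiny_params(seed = 43, noise_sigma = 0, misalign_max = 4,
                   misalign_tile = 32)
  pairs <- make_cohort(3, p)
  al <- align_pairs(pairs, function(pr) true_uv_oracle(pr), tile_size = 32,
                    stride = 32, search_radius = 6, min_mask_fraction = 0.2)
  for (i in seq_along(pairs)) {
    tiles <- al[[i]]$tiles
    expect_gt(nrow(tiles), 0)
    planted <- t(vapply(seq_len(nrow(tiles)), function(k)
      pairs[[i]]$shift_field[tiles$row0[k] + 1, tiles$col0[k] + 1, ],
      numeric(2)))
    expect_equal(cbind(tiles$dy, tiles$dx), unname(planted), ignore_attr = TRUE)
  }
  # zero-misalignment phantoms give all-zero shifts
  p0 <- tiny_params(seed = 44, misalign_max = 0)
  al0 <- align_pairs(make_cohort(1, p0), function(pr) true_uv_oracle(pr),
                     tile_size = 32, stride = 32, search_radius = 4)
  expect_true(all(al0[[1]]$tiles$dy == 0 & al0[[1]]$tiles$dx == 0))
})

test_that("halving the tile stride cannot reduce the tile count", {
  p <- tiny_params(seed = 45)
  pair <- make_phantom(p)
  a1 <- align_pairs(list(pair), function(pr) true_uv_oracle(pr),
                    tile_size = 48, stride = 48, search_radius = 4)
  a2 <- align_pairs(list(pair), function(pr) true_uv_oracle(pr),
                    tile_size = 48, stride = 24, search_radius = 4)
  expect_gte(nrow(a2[[1]]$tiles), nrow(a1[[1]]$tiles))
})

test_that("applying recovered shifts lowers the pairwise loss; zero shifts are a no-op", {
  p <- tiny_params(seed = 46, width = 128, height = 128, noise_sigma = 0,
                   misalign_max = 4, misalign_tile = 64)
  pair <- make_phantom(p)
  al <- align_pairs(list(pair), function(pr) true_uv_oracle(pr),
                    tile_size = 64, stride = 64, search_radius = 6,
                    min_mask_fraction = 0.2)[[1]]
  grid <- plan_grid(dim(pair$uv), 32, 32, region_mask = pair$face_mask,
                    min_mask_fraction = 0.8)
  aligned <- apply_alignment(pair, al, grid)
  expect_gt(length(aligned), 0)
  # compare against unaligned extraction through the ideal-UV lens:
  # the UV patch should match the ideal UV at the *shifted* color window
  ideal <- true_uv_oracle(pair)
  xs <- extract_patches(ideal, grid)
  ys <- extract_patches(pair$uv, grid)
  unaligned_l1 <- mean(vapply(seq_along(xs), function(i)
    mean(abs(ys[[i]] - xs[[i]])), numeric(1)))
  # per aligned pair, the UV patch must agree with the ideal UV at the
  # shifted color window actually used
  w <- grid$windows
  l1s <- c()
  for (i in seq_len(nrow(w))) {
    k <- uvsynth:::assign_tile(al, w$row0[i], w$col0[i], w$size[i])
    dy <- al$tiles$dy[k]; dx <- al$tiles$dx[k]
    r0 <- w$row0[i] - dy; c0 <- w$col0[i] - dx
    if (r0 < 0 || c0 < 0 || r0 + 32 > 128 || c0 + 32 > 128) next
    ideal_patch <- ideal[(r0 + 1):(r0 + 32), (c0 + 1):(c0 + 32)]
    uv_patch <- pair$uv[(w$row0[i] + 1):(w$row0[i] + 32),
                        (w$col0[i] + 1):(w$col0[i] + 32)]
    l1s <- c(l1s, mean(abs(uv_patch - ideal_patch)))
  }
  expect_lt(mean(l1s), unaligned_l1)
  # all-zero alignment reproduces the unaligned extraction
  al0 <- al
  al0$tiles$dy[] <- 0L; al0$tiles$dx[] <- 0L
  same <- apply_alignment(pair, al0, grid)
  xs_c <- extract_patches(pair$color, grid)
  expect_equal(length(same), nrow(w))
  expect_identical(same[[1]]$x, xs_c[[1]])
  expect_identical(same[[1]]$y, ys[[1]])
})

test_that("patch-to-tile assignment uses nearest center with row-major ties", {
  res <- structure(list(tiles = tibble::tibble(row0 = c(0, 0), col0 = c(0, 64),
                                               size = 64, dy = c(1L, 2L),
                                               dx = c(0L, 0L), score = 0),
                        tile_size = 64, search_radius = 4,
                        image_shape = c(64, 128)), class = "alignment_result")
  # patch centered exactly between the two tile centers -> first tile wins
  expect_equal(uvsynth:::assign_tile(res, 16, 48, 32), 1L)
  # clearly nearer the second tile
  expect_equal(uvsynth:::assign_tile(res, 16, 70, 32), 2L)
})

test_that("temporal surrogate training records lambda = 0 and is seeded", {
  p <- tiny_params(seed = 47, misalign_max = 0)
  co <- make_cohort(3, p)
  tp <- training_patches(co[1:2], 32, 32, min_mask_fraction = 0.5)
  vp <- training_patches(co[3], 32, 32, min_mask_fraction = 0.5)
  st <- temporal_uv(tp, vp, gen_config = tiny_gen_config(),
                    schedule = default_schedule(30, 0, 0, 10),
                    batch_size = 2, seed = 9)
  expect_equal(st$lambda, 0)
  st2 <- temporal_uv(tp, vp, gen_config = tiny_gen_config(),
                     schedule = default_schedule(30, 0, 0, 10),
                     batch_size = 2, seed = 9)
  expect_identical(st$traces, st2$traces)
})
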