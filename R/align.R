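# Local alignment of color and UV exposures. The two captures are mismatched
# by small subject motion; direct color/UV registration is unreliable because
# the two modalities carry different pixel statistics, so alignment runs
# between the observed UV image and a surrogate synthetic UV image produced by
# an L1-only generator. Large tiles are registered by exhaustive integer-shift
# search; the recovered tile shifts are then propagated to the smaller
# training patches by a nearest-tile-center rule.
#
# Sign convention (used everywhere): a tile shift (dy, dx) is the displacement
# of the UV content relative to the color/synthetic side, i.e. translating the
# reference tile by (dy, dx) (content moves +dy rows, +dx cols) best matches
# the UV tile. An aligned color window is therefore extracted at
# (row0 - dy, col0 - dx).

#' Train the surrogate generator used for alignment
#'
#' Trains the translation network with `lambda = 0` (no discriminator) and no
#' alignment; its outputs ("temporal" synthetic UV images) are used solely to
#' make UV-to-color registration tractable.
#'
#' @inheritParams train_uvnet
#' @param ... passed to [train_uvnet()].
#' @return a `uv_train_state` with `lambda = 0`.
#' @export
temporal_uv <- function(train_patches, val_patches = list(), ...) {
  train_uvnet(train_patches, val_patches, lambda = 0, ...)
}

#' Exhaustive integer-shift registration of one tile pair
#'
#' Scans all `(dy, dx)` in `[-radius, radius]^2`, scoring the mean per-pixel
#' L1 between the UV tile and the translated reference tile on the valid
#' overlap only. Ties prefer smaller `|dy| + |dx|`, then lexicographic
#' `(dy, dx)`.
#'
#' @param uv_tile,ref_tile equally sized matrices.
#' @param search_radius maximum absolute shift in pixels (>= 0, smaller than
#'   the tile).
#' @return list `(dy, dx, score)`.
#' @export
search_shift <- function(uv_tile, ref_tile, search_radius) {
  if (!all(dim(uv_tile) == dim(ref_tile)))
    stop("tiles must have the same size", call. = FALSE)
  if (search_radius >= min(dim(uv_tile)))
    stop("search radius must be smaller than the tile", call. = FALSE)
  search_shift_cpp(uv_tile, ref_tile, as.integer(search_radius))
}

#' Register all tiles of color/UV pairs via a surrogate generator
#'
#' For each pair, a synthetic UV surrogate is produced (trained state or any
#' `function(pair) -> H x W matrix`, e.g. [true_uv_oracle()] in tests), both
#' images are tiled over the face region, and each tile is registered with
#' [search_shift()].
#'
#' @param pairs list of `image_pair` objects.
#' @param surrogate a `uv_train_state` or a function of one pair.
#' @param tile_size tile side in pixels (900 at clinical scale; use the
#'   phantom's misalignment tile at desk scale).
#' @param stride tile stride (overlap allowed).
#' @param search_radius maximum shift searched.
#' @param min_mask_fraction minimum face coverage per tile.
#' @return list of `alignment_result` objects (one per pair): tibble `tiles`
#'   with `row0, col0, size, dy, dx, score`.
#' @export
align_pairs <- function(pairs, surrogate, tile_size = 96, stride = tile_size,
                        search_radius = 8, min_mask_fraction = 0.2) {
  synth_fn <- if (inherits(surrogate, "uv_train_state")) {
    function(pair) convert_image(surrogate, pair$color, pair$face_mask)
  } else surrogate
  lapply(pairs, function(pair) {
    synth <- synth_fn(pair)
    grid <- plan_grid(dim(pair$uv), tile_size, stride,
                      region_mask = pair$face_mask,
                      min_mask_fraction = min_mask_fraction)
    uv_t <- extract_patches(pair$uv, grid)
    sy_t <- extract_patches(synth, grid)
    res <- lapply(seq_along(uv_t), function(i)
      search_shift(uv_t[[i]], sy_t[[i]], search_radius))
    tiles <- grid$windows
    tiles$dy <- vapply(res, `[[`, integer(1), "dy")
    tiles$dx <- vapply(res, `[[`, integer(1), "dx")
    tiles$score <- vapply(res, `[[`, numeric(1), "score")
    structure(list(tiles = tiles, tile_size = tile_size,
                   search_radius = search_radius,
                   image_shape = grid$image_shape),
              class = "alignment_result")
  })
}

# nearest tile (center-to-center distance) for a patch window; ties resolved
# by row-major tile order (the first minimum wins)
assign_tile <- function(result, row0, col0, size) {
  tc_r <- result$tiles$row0 + result$tiles$size / 2
  tc_c <- result$tiles$col0 + result$tiles$size / 2
  pc_r <- row0 + size / 2
  pc_c <- col0 + size / 2
  which.min((tc_r - pc_r)^2 + (tc_c - pc_c)^2)
}

#' Extract locally aligned training patch pairs
#'
#' Each training window takes the shift of its nearest alignment tile; the
#' color window is translated by the negated shift before extraction so that
#' its content registers with the UV window. Windows translated out of the
#' image are dropped.
#'
#' @param pair an `image_pair`.
#' @param result the pair's `alignment_result` from [align_pairs()].
#' @param patch_grid a [plan_grid()] over the pair's face region.
#' @return list of aligned `list(x = color patch, y = uv patch)`.
#' @export
apply_alignment <- function(pair, result, patch_grid) {
  if (nrow(result$tiles) == 0)
    stop("alignment result covers no tiles", call. = FALSE)
  H <- patch_grid$image_shape[1]; W <- patch_grid$image_shape[2]
  w <- patch_grid$windows
  out <- list()
  for (i in seq_len(nrow(w))) {
    k <- assign_tile(result, w$row0[i], w$col0[i], w$size[i])
    dy <- result$tiles$dy[k]; dx <- result$tiles$dx[k]
    r0 <- w$row0[i] - dy; c0 <- w$col0[i] - dx
    if (r0 < 0 || c0 < 0 || r0 + w$size[i] > H || c0 + w$size[i] > W) next
    ru <- w$row0[i]; cu <- w$col0[i]
    if (ru + w$size[i] > H || cu + w$size[i] > W) next
    out[[length(out) + 1L]] <- list(
      x = pair$color[(r0 + 1):(r0 + w$size[i]), (c0 + 1):(c0 + w$size[i]), ,
                     drop = FALSE],
      y = pair$uv[(ru + 1):(ru + w$size[i]), (cu + 1):(cu + w$size[i]),
                  drop = FALSE])
  }
  out
}

#' Serialize an alignment result to JSON
#' @param result an `alignment_result`.
#' @param path file path.
#' @export
write_alignment <- function(result, path) {
  jsonlite::write_json(list(tiles = result$tiles, tile_size = result$tile_size,
                            search_radius = result$search_radius,
                            image_shape = result$image_shape),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
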