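# Skin-phantom generator: paired color/UV captures with known melanin spots,
# hemoglobin field, multiplicative shading, sensor noise and a planted
# piecewise-constant misalignment between the two exposures.

# chromophore absorbance per RGB channel: melanin rises toward blue,
# hemoglobin absorbs mostly green; shared with the ICA recovery tests.
MELANIN_ABS <- c(0.6, 0.8, 1.0)
HEMOGLOBIN_ABS <- c(0.1, 0.8, 0.5)
SKIN_TONE <- c(0.95, 0.88, 0.82)
# UV rendering: globally darker than the visible capture, melanin-dominated
UV_BASE <- 0.9
UV_MELANIN_GAIN <- 1.2

#' Parameters of the paired color/UV skin phantom
#'
#' Defaults describe the study conditions used throughout the package: a
#' 192 x 192 capture with around 30 pigment spots of 3-7 px radius whose
#' melanin boost is fully visible under UV but only fractionally
#' (`color_spot_contrast`) under visible light, a smooth hemoglobin redness
#' field, multiplicative shading, mild sensor noise, and a piecewise-constant
#' integer misalignment of the UV exposure relative to the color exposure
#' (constant over `misalign_tile` x `misalign_tile` tiles, at most
#' `misalign_max` px per axis), emulating subject motion between the two
#' captures.
#'
#' @param width,height phantom size in pixels (at least 64).
#' @param n_spots number of planted pigment spots.
#' @param spot_radius_range integer (min, max) spot radius in pixels.
#' @param spot_melanin_boost melanin increase inside a spot, in (0, 1].
#' @param color_spot_contrast fraction of the UV spot contrast that remains
#'   visible in the color image, in [0, 1].
#' @param hemoglobin_amplitude amplitude of the smooth hemoglobin field.
#' @param texture_amplitude amplitude of the fine-scale (~2 px) melanin
#'   micro-texture visible in both modalities; this is what makes pixel-level
#'   misalignment costly, as on real skin.
#' @param shading_scale smoothness (gaussian sigma, px) of the shading field.
#' @param noise_sigma additive gaussian sensor noise on the [0, 1] scale.
#' @param misalign_max maximum per-axis UV displacement in pixels (>= 0).
#' @param misalign_tile side of the constant-shift tiles in pixels.
#' @param seed RNG seed making the phantom fully reproducible.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(width = 192, height = 192, n_spots = 30,
                           spot_radius_range = c(3, 7),
                           spot_melanin_boost = 0.35,
                           color_spot_contrast = 0.3,
                           hemoglobin_amplitude = 0.12,
                           texture_amplitude = 0.04,
                           shading_scale = 32, noise_sigma = 0.02,
                           misalign_max = 4, misalign_tile = 96, seed = 1) {
  p <- list(width = as.integer(width), height = as.integer(height),
            n_spots = as.integer(n_spots),
            spot_radius_range = as.numeric(spot_radius_range),
            spot_melanin_boost = spot_melanin_boost,
            color_spot_contrast = color_spot_contrast,
            hemoglobin_amplitude = hemoglobin_amplitude,
            texture_amplitude = texture_amplitude,
            shading_scale = shading_scale, noise_sigma = noise_sigma,
            misalign_max = as.integer(misalign_max),
            misalign_tile = as.integer(misalign_tile),
            seed = as.integer(seed))
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$width < 64 || p$height < 64)
    stop("phantom width and height must be at least 64 pixels", call. = FALSE)
  if (length(p$spot_radius_range) != 2 || p$spot_radius_range[1] < 1 ||
      p$spot_radius_range[1] > p$spot_radius_range[2])
    stop("spot_radius_range must satisfy 1 <= min <= max", call. = FALSE)
  if (p$color_spot_contrast < 0 || p$color_spot_contrast > 1)
    stop("color_spot_contrast must lie in [0, 1]", call. = FALSE)
  if (p$misalign_max < 0) stop("misalign_max must be >= 0", call. = FALSE)
  if (p$n_spots < 0) stop("n_spots must be >= 0", call. = FALSE)
  invisible(p)
}

#' Generate one paired color/UV skin phantom
#'
#' Builds a melanin map (smooth base plus disc-shaped spot boosts), renders the
#' UV capture as `clip(1 - k * melanin) * shading + noise` and the color
#' capture through a log-linear two-chromophore model
#' (`channel = tone * exp(-melanin * abs_m - hemoglobin * abs_h) * shading`),
#' where the spot component of the melanin map is attenuated by
#' `color_spot_contrast` in the color rendering only. The observed UV raster is
#' the ideal UV displaced by a piecewise-constant integer shift field (the
#' ground-truth misalignment, UV relative to color). Deterministic given
#' `params$seed`.
#'
#' @param params a [phantom_params()] list.
#' @return an `image_pair` list with elements `color` (H x W x 3), `uv`
#'   (H x W, single channel), `face_mask`, `spot_mask`, `shift_field`
#'   (H x W x 2 integer displacements, `(dy, dx)`), plus the noise-free
#'   registered ground truth `uv_ideal` and the generating `params`.
#' @export
make_phantom <- function(params) {
  validate_phantom_params(params)
  p <- params
  H <- p$height; W <- p$width
  with_seed(p$seed, {
    # face region: centered ellipse
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    face <- ((rr - cy) / (0.47 * H))^2 + ((cc - cx) / (0.42 * W))^2 <= 1
    face_mask <- matrix(as.numeric(face), H, W)

    # melanin: smooth base + fine micro-texture + spot discs; the texture is
    # part of the base melanin, so it shows in both the color and UV captures
    base_mel <- 0.30 + 0.05 * smooth_field(H, W, p$shading_scale / 2)
    if (p$texture_amplitude > 0)
      base_mel <- base_mel + p$texture_amplitude * smooth_field(H, W, 1.5)
    spot_mask <- matrix(0, H, W)
    spots <- matrix(0, H, W)
    if (p$n_spots > 0) {
      inside <- which(face_mask > 0, arr.ind = TRUE)
      ctr <- inside[sample.int(nrow(inside), p$n_spots, replace = TRUE), ,
                    drop = FALSE]
      radii <- runif(p$n_spots, p$spot_radius_range[1], p$spot_radius_range[2])
      for (s in seq_len(p$n_spots)) {
        d2 <- (rr - ctr[s, 1])^2 + (cc - ctr[s, 2])^2
        spots[d2 <= radii[s]^2] <- 1
      }
      spots <- spots * face_mask
      spot_mask <- spots
    }
    melanin <- base_mel + p$spot_melanin_boost * spots
    melanin_color <- base_mel + p$color_spot_contrast * p$spot_melanin_boost * spots

    hemo <- p$hemoglobin_amplitude *
      clip01(0.5 + 0.35 * smooth_field(H, W, p$shading_scale / 2))
    shading <- clip01(1 + 0.08 * smooth_field(H, W, p$shading_scale))
    shading <- shading / mean(shading)

    uv_ideal <- clip01(UV_BASE - UV_MELANIN_GAIN * melanin) * shading
    color <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      color[, , ch] <- SKIN_TONE[ch] *
        exp(-melanin_color * MELANIN_ABS[ch] - hemo * HEMOGLOBIN_ABS[ch]) *
        shading
    }
    # dark backdrop outside the face
    backdrop <- 0.15
    uv_ideal <- uv_ideal * face_mask + backdrop * (1 - face_mask)
    for (ch in 1:3)
      color[, , ch] <- color[, , ch] * face_mask + backdrop * (1 - face_mask)

    # piecewise-constant shift field (UV displaced relative to color)
    shift_field <- array(0L, c(H, W, 2))
    if (p$misalign_max > 0) {
      nty <- ceiling(H / p$misalign_tile)
      ntx <- ceiling(W / p$misalign_tile)
      tdy <- matrix(sample(seq(-p$misalign_max, p$misalign_max), nty * ntx,
                           replace = TRUE), nty, ntx)
      tdx <- matrix(sample(seq(-p$misalign_max, p$misalign_max), nty * ntx,
                           replace = TRUE), nty, ntx)
      tr <- (rr - 1L) %/% p$misalign_tile + 1L
      tc <- (cc - 1L) %/% p$misalign_tile + 1L
      shift_field[, , 1] <- tdy[cbind(as.vector(tr), as.vector(tc))]
      shift_field[, , 2] <- tdx[cbind(as.vector(tr), as.vector(tc))]
    }
    uv_obs <- warp_by_field(uv_ideal, shift_field)

    if (p$noise_sigma > 0) {
      uv_obs <- uv_obs + matrix(rnorm(H * W, 0, p$noise_sigma), H, W)
      color <- color + array(rnorm(H * W * 3, 0, p$noise_sigma / 2), c(H, W, 3))
    }
    pair <- list(color = clip01(color), uv = clip01(uv_obs),
                 face_mask = face_mask, spot_mask = spot_mask,
                 shift_field = shift_field, uv_ideal = uv_ideal,
                 params = p)
    class(pair) <- "image_pair"
    pair
  })
}

# apply a per-pixel integer shift field: out(r,c) = img(r - dy(r,c), c - dx(r,c)),
# sampling clamped at the image edge
warp_by_field <- function(img, field) {
  H <- nrow(img); W <- ncol(img)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ri <- pmin(pmax(rr - field[, , 1], 1L), H)
  ci <- pmin(pmax(cc - field[, , 2], 1L), W)
  matrix(img[cbind(as.vector(ri), as.vector(ci))], H, W)
}

#' Generate a cohort of phantoms with per-subject seeds
#'
#' Sub-seeds are derived deterministically from `params$seed`. With
#' `spot_density_gradient = TRUE` the planted spot count increases
#' monotonically across subjects (from 20% to 180% of `params$n_spots`),
#' emulating the age trend of pigment-spot burden.
#'
#' @param n number of subjects (>= 1).
#' @param params base [phantom_params()].
#' @param spot_density_gradient logical; ramp the spot count across subjects.
#' @return list of `n` [make_phantom()] pairs.
#' @export
make_cohort <- function(n, params, spot_density_gradient = FALSE) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  seeds <- derive_seeds(params$seed, n)
  counts <- if (spot_density_gradient) {
    pmax(0L, as.integer(round(seq(0.2 * params$n_spots, 1.8 * params$n_spots,
                                  length.out = n))))
  } else rep(params$n_spots, n)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- seeds[i]
    p$n_spots <- counts[i]
    make_phantom(p)
  })
}

#' Noise-free, alignment-free UV ground truth of a phantom
#'
#' The registered clean UV rendering that a perfect color-to-UV generator
#' would produce; the reference used by the evaluation suite.
#'
#' @param pair an `image_pair` from [make_phantom()].
#' @return H x W intensity matrix on [0, 1].
#' @export
true_uv_oracle <- function(pair) {
  if (is.null(pair$uv_ideal))
    stop("pair was not produced by make_phantom()", call. = FALSE)
  pair$uv_ideal
}

#' Write a phantom pair to disk as 8-bit PNGs plus a JSON sidecar
#'
#' Files are named `<subject>_<view>_{color,uv,face,spots}.png`; the sidecar
#' `<subject>_<view>_params.json` records the generating parameters.
#'
#' @param pair an `image_pair`.
#' @param dir output directory (created if missing).
#' @param subject,view file-name stems.
#' @return invisibly, the vector of written paths.
#' @export
write_phantom <- function(pair, dir, subject = "s01", view = "front") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(subject, "_", view, "_"))
  paths <- c(color = paste0(stem, "color.png"), uv = paste0(stem, "uv.png"),
             face = paste0(stem, "face.png"), spots = paste0(stem, "spots.png"),
             params = paste0(stem, "params.json"))
  write_image(paths["color"], pair$color)
  write_image(paths["uv"], pair$uv)
  write_image(paths["face"], pair$face_mask)
  write_image(paths["spots"], pair$spot_mask)
  jsonlite::write_json(pair$params, paths["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
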