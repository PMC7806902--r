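# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the deterministic tests run in seconds.

# a fast phantom for unit tests (not the study-scale default)
tiny_params <- function(seed = 1, ...) {
  args <- list(width = 96, height = 96, n_spots = 8,
               spot_radius_range = c(2, 4), shading_scale = 16,
               noise_sigma = 0.01, misalign_max = 2, misalign_tile = 48,
               seed = seed)
  utils::modifyList(args, list(...)) |> do.call(phantom_params, args = _)
}

tiny_gen_config <- function(...) {
  args <- utils::modifyList(list(depth = 3, base_channels = 4,
                                 input_size = 32, dropout_rate = 0),
                            list(...))
  do.call(generator_config, args)
}

# direct-summation oracles for correlation / regression
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
slope_oracle <- function(x, y) sum(x * y) / sum(x^2)

# brute-force reference for the exhaustive shift search (R implementation,
# independent of the compiled path)
search_shift_bruteforce <- function(uv, ref, radius) {
  H <- nrow(uv); W <- ncol(uv)
  best <- Inf; bdy <- 0L; bdx <- 0L
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      r0 <- max(0, dy); r1 <- min(H, H + dy)
      c0 <- max(0, dx); c1 <- min(W, W + dx)
      if (r1 <= r0 || c1 <= c0) next
      a <- uv[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
      b <- ref[(r0 + 1 - dy):(r1 - dy), (c0 + 1 - dx):(c1 - dx), drop = FALSE]
      sc <- sum(abs(a - b)) / length(a)
      take <- sc < best
      if (!take && sc == best) {
        man <- abs(dy) + abs(dx); bman <- abs(bdy) + abs(bdx)
        take <- man < bman || (man == bman && (dy < bdy || (dy == bdy && dx < bdx)))
      }
      if (take) { best <- sc; bdy <- dy; bdx <- dx }
    }
  }
  list(dy = bdy, dx = bdx, score = best)
}
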