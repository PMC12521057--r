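# Small phantoms for fast unit tests: the body ellipse is scaled to the
# field of view so any slice size works.
small_spec <- function(shape = c(4, 96, 96), sigma_hu = 10, seed = 1, ...) {
  fov <- min(shape[2:3]) * 0.7
  phantom_spec(shape = shape, sigma_hu = sigma_hu, seed = seed,
               body_axes_mm = c(0.7 * fov, 0.5 * fov), ...)
}

small_phantom <- function(...) make_phantom(small_spec(...))

# brute-force local sample-SD oracle: nested loops, stats::sd per window
brute_force_sd_map <- function(x, w) {
  h <- w %/% 2
  out <- matrix(NA_real_, nrow(x), ncol(x))
  for (i in seq(h + 1, nrow(x) - h)) {
    for (j in seq(h + 1, ncol(x) - h)) {
      out[i, j] <- sd(x[(i - h):(i + h), (j - h):(j + h)])
    }
  }
  out
}
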