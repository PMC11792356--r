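# Independent brute-force oracles and small fixture builders.

# symmetric (edge-included) reflected index, 1-based
refl1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1L - i
    if (i > n) i <- 2L * n - i + 1L
  }
  i
}

# Brute-force per-pixel non-local means (direct transcription of the
# definition; independent of the package's offset-decomposition code path).
nlm_brute_force <- function(img, patch_r, search_r, h) {
  nr <- nrow(img); nc <- ncol(img)
  gv <- function(i, j) img[refl1(i, nr), refl1(j, nc)]
  out <- img
  psz <- (2 * patch_r + 1)^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ws <- 0; ac <- 0; wm <- 0
    for (di in -search_r:search_r) for (dj in -search_r:search_r) {
      if (di == 0 && dj == 0) next
      d2 <- 0
      for (pi in -patch_r:patch_r) for (pj in -patch_r:patch_r)
        d2 <- d2 + (gv(i + pi, j + pj) - gv(i + di + pi, j + dj + pj))^2
      d2 <- d2 / psz
      w <- if (h > 0) exp(-d2 / h^2) else as.numeric(d2 == 0)
      wm <- max(wm, w); ws <- ws + w; ac <- ac + w * gv(i + di, j + dj)
    }
    if (wm <= 0) wm <- 1
    out[i, j] <- (ac + wm * img[i, j]) / (ws + wm)
  }
  out
}

# Brute-force per-pixel Gaussian-weighted local mean threshold map.
adaptive_threshold_brute_force <- function(img, block, sigma, offset = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r <- (block - 1) / 2
  x <- -r:r
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  thr <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in seq_along(x)) for (b in seq_along(x))
      s <- s + K[a, b] * img[refl1(i + x[a], nr), refl1(j + x[b], nc)]
    thr[i, j] <- s
  }
  img - (thr + offset) > 1e-9 * max(1, max(abs(img)))
}

# Small, fast phantom geometry for unit tests (64 x 64 x 8, 24 mm fascia).
small_spec <- function(...) {
  args <- list(grid_shape = c(8L, 64L, 64L), fascia_radius_mm = 24,
               femur_radius_mm = 6, subcut_thickness_mm = 6,
               femur_offset_mm = 5, profile = "test")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# Truth volume restricted to a slice range, in cm^3.
truth_in_slices <- function(ph, mask, slices) {
  vv <- prod(ph$spec$pixel_spacing_mm) * ph$spec$slice_thickness_mm / 1000
  sum(mask[, , slices, drop = FALSE]) * vv
}
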