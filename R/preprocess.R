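#' Preprocessing configuration
#'
#' Parameters for the slice-wise preprocessing chain applied before fat
#' segmentation: non-local-means (NLM) denoising, multiplicative bias-field
#' correction, and intensity normalization to the `[0, 255]` range.
#'
#' @param nlm_patch_radius integer >= 1, NLM patch radius in pixels (radius 1
#'   compares 3 x 3 patches).
#' @param nlm_search_radius integer >= 1, NLM search-window radius in pixels.
#' @param nlm_h NLM filtering strength; `NULL` (default) estimates it per
#'   slice as `nlm_h_factor` times the noise SD obtained by the
#'   pseudo-residual method.
#' @param nlm_h_factor multiplier applied to the estimated noise SD.
#' @param bias_mode `"poly"` fits a low-order polynomial surface to the
#'   log-intensities; `"smooth"` uses a heavily Gaussian-smoothed
#'   log-intensity surface.
#' @param bias_poly_degree integer >= 1, total degree of the polynomial
#'   surface.
#' @param bias_smooth_sigma_mm Gaussian sigma (mm) for the `"smooth"` mode.
#' @param normalization_mode `"strict_minmax"` maps the volume's global
#'   min/max to 0/255; `"percentile_clip"` maps the `clip_percentiles`
#'   quantiles instead and clips.
#' @param clip_percentiles length-2 percentiles in `[0, 100]`, low < high.
#' @param normalization_scope `"volume"` (default) or `"slice"`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(nlm_patch_radius = 1L,
                              nlm_search_radius = 5L,
                              nlm_h = NULL,
                              nlm_h_factor = 0.8,
                              bias_mode = c("poly", "smooth"),
                              bias_poly_degree = 2L,
                              bias_smooth_sigma_mm = 30,
                              normalization_mode = c("strict_minmax",
                                                     "percentile_clip"),
                              clip_percentiles = c(0.5, 99.5),
                              normalization_scope = c("volume", "slice")) {
  stopifnot(nlm_patch_radius >= 1, nlm_search_radius >= 1,
            bias_poly_degree >= 1, bias_smooth_sigma_mm > 0,
            length(clip_percentiles) == 2,
            clip_percentiles[1] >= 0, clip_percentiles[2] <= 100,
            clip_percentiles[1] < clip_percentiles[2])
  structure(list(nlm_patch_radius = as.integer(nlm_patch_radius),
                 nlm_search_radius = as.integer(nlm_search_radius),
                 nlm_h = nlm_h,
                 nlm_h_factor = nlm_h_factor,
                 bias_mode = match.arg(bias_mode),
                 bias_poly_degree = as.integer(bias_poly_degree),
                 bias_smooth_sigma_mm = bias_smooth_sigma_mm,
                 normalization_mode = match.arg(normalization_mode),
                 clip_percentiles = clip_percentiles,
                 normalization_scope = match.arg(normalization_scope)),
            class = "preprocess_config")
}

# Noise SD estimate from pseudo-residuals: r = sqrt(4/5) * (I - mean of the
# four in-plane neighbours); robustified with the MAD.
estimate_noise_sd <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(stats::sd(m))
  ctr <- m[2:(nr - 1), 2:(nc - 1)]
  nb <- (m[1:(nr - 2), 2:(nc - 1)] + m[3:nr, 2:(nc - 1)] +
           m[2:(nr - 1), 1:(nc - 2)] + m[2:(nr - 1), 3:nc]) / 4
  r <- sqrt(4 / 5) * (ctr - nb)
  stats::mad(r, center = 0)
}

#' Non-local-means denoising
#'
#' Slice-wise NLM: every output pixel is the similarity-weighted average of
#' the pixels in its search window, weighted by
#' `exp(-patch_distance^2 / h^2)` where the patch distance is the root mean
#' squared difference between the local patches (symmetric boundary
#' reflection; self weight set to the maximum neighbour weight).
#'
#' @param image an [image_volume()] with finite intensities.
#' @param cfg a [preprocess_config()].
#' @return a denoised `image_volume` of identical shape and spacing.
#' @export
nlm_denoise <- function(image, cfg = preprocess_config()) {
  stopifnot(inherits(image, "image_volume"))
  if (!all(is.finite(image$data))) stop("image contains non-finite values")
  out <- image
  for (k in seq_len(dim(image$data)[3])) {
    sl <- image$data[, , k]
    h <- cfg$nlm_h
    if (is.null(h)) {
      h <- cfg$nlm_h_factor * estimate_noise_sd(sl)
      if (!is.finite(h)) h <- 0
    }
    out$data[, , k] <- nlm_denoise_slice(sl, cfg$nlm_patch_radius,
                                         cfg$nlm_search_radius, h)
  }
  out
}

# Polynomial design matrix over scaled coordinates, total degree <= d.
poly_design <- function(xn, yn, d) {
  cols <- list()
  for (i in 0:d) for (j in 0:(d - i)) cols[[length(cols) + 1L]] <- xn^i * yn^j
  do.call(cbind, cols)
}

# One slice of bias estimation: returns the strictly positive field.
estimate_bias_slice <- function(sl, m, cfg, spacing) {
  pos <- m & sl > 0
  logI <- log(sl[pos])
  nr <- nrow(sl); nc <- ncol(sl)
  if (cfg$bias_mode == "poly") {
    xn <- matrix(seq(-1, 1, length.out = nr), nr, nc)
    yn <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
    X <- poly_design(xn[pos], yn[pos], cfg$bias_poly_degree)
    w <- rep(1, length(logI))
    beta <- NULL
    for (it in 1:3) {  # IRLS with bisquare weights: damp anatomy outliers
      fit <- stats::lm.wfit(X, logI, w)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      r <- as.vector(logI - X %*% beta)
      s <- stats::mad(r, center = 0)
      if (s <= 0) break
      u <- pmin(abs(r) / (6 * s), 1)
      w <- (1 - u^2)^2
    }
    Xall <- poly_design(as.vector(xn), as.vector(yn), cfg$bias_poly_degree)
    lf <- matrix(Xall %*% beta, nr, nc)
  } else {
    sig_px <- cfg$bias_smooth_sigma_mm / sqrt(prod(spacing))
    size <- min(2L * as.integer(ceiling(3 * sig_px)) + 1L,
                2L * min(nr, nc) - 1L)
    if (size %% 2L == 0L) size <- size - 1L
    k <- gauss_kernel_1d(size, sig_px)
    L <- matrix(0, nr, nc); L[pos] <- log(sl[pos])
    M <- matrix(0, nr, nc); M[pos] <- 1
    num <- conv2_sep_reflect(L, k)
    den <- conv2_sep_reflect(M, k)
    lf <- num / pmax(den, 1e-8)
  }
  lf <- lf - mean(lf[pos])       # unit geometric mean inside the mask
  exp(lf)
}

#' Bias-field correction
#'
#' Estimates a smooth, strictly positive multiplicative intensity field on
#' each slice from the log-intensities inside `body_mask` (iteratively
#' reweighted polynomial surface by default, Gaussian-smoothed surface as an
#' alternative) and divides it out. The mean intensity inside the mask is
#' preserved exactly. The `corrector` argument is a seam for plugging in an
#' external correction routine (e.g. an ITK N4 wrapper): a function
#' `(slice_matrix, mask_matrix) -> corrected_matrix`.
#'
#' @param image an [image_volume()].
#' @param cfg a [preprocess_config()].
#' @param body_mask logical array on the image grid marking tissue (non-air)
#'   voxels; must be non-empty.
#' @param corrector optional replacement slice-correction function.
#' @return a corrected `image_volume`.
#' @export
correct_bias <- function(image, cfg = preprocess_config(), body_mask,
                         corrector = NULL) {
  stopifnot(inherits(image, "image_volume"))
  if (missing(body_mask) || is.null(body_mask)) {
    rng <- range(image$data)
    body_mask <- image$data > rng[1] + 0.2 * (rng[2] - rng[1])
  }
  if (!any(body_mask)) stop("body_mask is empty")
  if (!any(image$data[body_mask] > 0))
    stop("image is non-positive everywhere inside body_mask")
  out <- image
  for (k in seq_len(dim(image$data)[3])) {
    sl <- image$data[, , k]
    m <- body_mask[, , k]
    if (!any(m & sl > 0)) next
    if (!is.null(corrector)) {
      corr <- corrector(sl, m)
    } else {
      field <- estimate_bias_slice(sl, m, cfg, image$pixel_spacing_mm)
      corr <- sl / field
    }
    corr <- corr * mean(sl[m]) / mean(corr[m])
    out$data[, , k] <- corr
  }
  out
}

#' Intensity normalization to [0, 255]
#'
#' Affine map sending the reference low/high intensities to 0/255, with
#' clipping. `strict_minmax` uses the global minimum and maximum of the
#' volume; `percentile_clip` uses the configured percentiles (robust to hot
#' pixels). A constant volume maps to all zeros with a warning.
#'
#' @param image an [image_volume()].
#' @param cfg a [preprocess_config()].
#' @return a normalized `image_volume` with intensities in `[0, 255]`.
#' @export
normalize_intensity <- function(image, cfg = preprocess_config()) {
  stopifnot(inherits(image, "image_volume"))
  if (!all(is.finite(image$data))) stop("image contains non-finite values")
  norm_block <- function(x) {
    if (cfg$normalization_mode == "strict_minmax") {
      lo <- min(x); hi <- max(x)
    } else {
      q <- stats::quantile(x, cfg$clip_percentiles / 100, names = FALSE)
      lo <- q[1]; hi <- q[2]
    }
    if (hi <= lo) {
      warning("constant intensity block: normalized to all zeros")
      return(array(0, dim(x)))
    }
    pmin(pmax((x - lo) / (hi - lo) * 255, 0), 255)
  }
  out <- image
  if (cfg$normalization_scope == "volume") {
    out$data <- norm_block(image$data)
  } else {
    for (k in seq_len(dim(image$data)[3]))
      out$data[, , k] <- norm_block(image$data[, , k])
  }
  out
}

#' Full preprocessing chain
#'
#' Applies, in order, NLM denoising, bias-field correction, and intensity
#' normalization to `[0, 255]` — each stage operating slice by slice.
#'
#' @inheritParams correct_bias
#' @return a preprocessed `image_volume`.
#' @export
preprocess_volume <- function(image, cfg = preprocess_config(),
                              body_mask = NULL, corrector = NULL) {
  image <- nlm_denoise(image, cfg)
  image <- correct_bias(image, cfg, body_mask, corrector)
  normalize_intensity(image, cfg)
}
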