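# Internal helpers shared across the pipeline.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Normalized 1-D Gaussian kernel
#'
#' @param size odd integer kernel length in pixels.
#' @param sigma positive standard deviation in pixels.
#' @return numeric vector of length `size` summing to 1.
#' @keywords internal
#' @noRd
gauss_kernel_1d <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  x <- seq.int(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Symmetric (mirror, edge included) padding indices for a length-n axis.
reflect_index <- function(n, r) {
  if (r == 0) return(seq_len(n))
  if (r > n) stop("padding radius exceeds axis length; kernel too large")
  c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
}

# Separable 2-D convolution with symmetric boundary padding.
# `m` is a matrix, `k` an odd-length 1-D kernel applied along both axes.
conv2_sep_reflect <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  # rows
  p <- m[reflect_index(nrow(m), r), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    out <- out + k[t] * p[t:(t + nrow(m) - 1L), , drop = FALSE]
  }
  # columns
  p <- out[, reflect_index(ncol(m), r), drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    out <- out + k[t] * p[, t:(t + ncol(m) - 1L), drop = FALSE]
  }
  out
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
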