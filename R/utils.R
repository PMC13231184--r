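# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dice similarity coefficient between two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Otsu's threshold on a numeric vector (maximise between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  # between-class variance for threshold after bin k
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / nbins * diff(rng)
}

# 1-D Gaussian (derivative) kernel, truncated at ~3.5 sigma.
gaussian_kernel_1d <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  k <- if (order == 1L) -x / sigma^2 * g else (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)   # truncation correction: derivative kernels must sum to zero
}

# Separable 2-D convolution with reflective boundary handling.
# kx acts along dim 1 (rows), ky along dim 2 (columns).
conv2_sep <- function(m, kx, ky) {
  conv_axis <- function(m, k, axis) {
    r <- (length(k) - 1L) %/% 2L
    n <- dim(m)[axis]
    if (n == 1L) return(m * sum(k))
    # reflective (mirror without repeating the edge sample, like scipy 'reflect'
    # falls back to repetition when the axis is shorter than the pad)
    idx <- seq_len(n)
    pad_lo <- rev(pmin(n, idx[1] + seq_len(r)))
    pad_hi <- rev(pmax(1L, n - seq_len(r)))
    ext <- c(pad_lo, idx, pad_hi)
    if (axis == 1L) mp <- m[ext, , drop = FALSE] else mp <- m[, ext, drop = FALSE]
    out <- array(0, dim(m))
    for (j in seq_along(k)) {
      sl <- j - 1L + seq_len(n)
      out <- out + k[j] * (if (axis == 1L) mp[sl, , drop = FALSE] else mp[, sl, drop = FALSE])
    }
    out
  }
  conv_axis(conv_axis(m, kx, 1L), ky, 2L)
}

# Derive a child RNG seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

# Broadcast a 2-D lateral (X, Y) mask down the Z axis of a 3-D grid.
broadcast_roi <- function(roi_2d, dims3) {
  stopifnot(identical(dim(roi_2d), dims3[1:2]))
  array(rep(as.logical(roi_2d), dims3[3]), dim = dims3)
}
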