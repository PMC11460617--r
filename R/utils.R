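# Internal numerical utilities shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector/matrix of angles in radians.
#' @return object of the same shape with every value wrapped into (-pi, pi].
#' @export
wrap_pi <- function(x) {
  atan2(sin(x), cos(x))
}

# Run code with a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# FFT sample frequencies (cycles per unit), standard discrete convention:
# spacing 1/(n*d), ordered [0, 1, ..., n/2-1, -n/2, ..., -1] / (n*d).
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# 1-D Gaussian kernel, normalized to sum 1.
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D filtering with symmetric (reflective) boundary handling.
# Implemented as banded matrix products so it stays fast for the small
# kernels used by SSIM windows and phantom smoothing.
filter_separable <- function(img, kernel) {
  smooth_1d_mat <- function(n, kernel) {
    r <- (length(kernel) - 1L) / 2L
    idx <- outer(seq_len(n), seq.int(-r, r), `+`)
    # reflect indices at the borders (symmetric padding)
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    m <- matrix(0, n, n)
    for (j in seq_along(kernel)) {
      m[cbind(seq_len(n), idx[, j])] <- m[cbind(seq_len(n), idx[, j])] + kernel[j]
    }
    m
  }
  kr <- smooth_1d_mat(nrow(img), kernel)
  kc <- smooth_1d_mat(ncol(img), kernel)
  kr %*% img %*% t(kc)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  filter_separable(img, gaussian_kernel(sigma))
}

# Mode of a numeric sample via histogram binning, refined by the median of
# the values falling in the modal neighbourhood.
mode_estimate <- function(x, bin = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(0)
  if (diff(range(x)) < bin) return(stats::median(x))
  breaks <- seq(min(x) - bin, max(x) + bin, by = bin)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  centre <- h$mids[which.max(h$counts)]
  stats::median(x[abs(x - centre) <= 2 * bin])
}

# Separable Catmull-Rom bicubic resampling to an arbitrary factor >= 1.
# Returns the interpolation matrix mapping n input samples to n*factor
# output samples; boundary indices are clamped.
bicubic_matrix <- function(n, factor) {
  n_out <- as.integer(round(n * factor))
  # output sample centres expressed in input pixel coordinates (centre-aligned)
  x <- (seq_len(n_out) - 0.5) / factor + 0.5
  i0 <- floor(x)
  tt <- x - i0
  # Catmull-Rom weights for taps at offsets -1, 0, 1, 2
  w <- cbind(
    -0.5 * tt^3 + tt^2 - 0.5 * tt,
    1.5 * tt^3 - 2.5 * tt^2 + 1,
    -1.5 * tt^3 + 2 * tt^2 + 0.5 * tt,
    0.5 * tt^3 - 0.5 * tt^2
  )
  m <- matrix(0, n_out, n)
  for (k in 1:4) {
    idx <- pmin(pmax(i0 + (k - 2L), 1L), n)
    m[cbind(seq_len(n_out), idx)] <- m[cbind(seq_len(n_out), idx)] + w[, k]
  }
  m
}

# Bicubic upsampling of a real matrix by an integer factor.
bicubic_upsample <- function(img, factor) {
  if (factor == 1) return(img)
  mr <- bicubic_matrix(nrow(img), factor)
  mc <- bicubic_matrix(ncol(img), factor)
  mr %*% img %*% t(mc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
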