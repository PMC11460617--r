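# Total-variation denoising (Chambolle's dual projection algorithm), used as
# the pluggable denoising prior of the "dip-red" reconstruction mode.

#' Total-variation denoising
#'
#' Solves `min_u 1/2 ||u - f||^2 + lambda * TV(u)` with Chambolle's dual
#' projection iteration (isotropic TV, Neumann boundaries).
#'
#' @param f noisy image (matrix).
#' @param lambda regularization weight; larger means smoother.
#' @param n_iter dual iterations (default 60).
#' @param tau dual step size (<= 1/4 for convergence).
#' @return Denoised matrix.
#' @export
tv_denoise <- function(f, lambda = 0.1, n_iter = 60, tau = 0.25) {
  if (lambda <= 0) return(f)
  nr <- nrow(f); nc <- ncol(f)
  px <- matrix(0, nr, nc); py <- matrix(0, nr, nc)
  grad <- function(u) {
    gx <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], 0)
    gy <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], 0)
    list(gx = gx, gy = gy)
  }
  div <- function(px, py) {
    dx <- px - rbind(0, px[-nr, , drop = FALSE])
    dx[nr, ] <- -px[nr - 1, ]
    dy <- py - cbind(0, py[, -nc, drop = FALSE])
    dy[, nc] <- -py[, nc - 1]
    dx + dy
  }
  for (i in seq_len(n_iter)) {
    g <- grad(div(px, py) - f / lambda)
    denom <- 1 + tau * sqrt(g$gx^2 + g$gy^2)
    px <- (px + tau * g$gx) / denom
    py <- (py + tau * g$gy) / denom
  }
  f - lambda * div(px, py)
}
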