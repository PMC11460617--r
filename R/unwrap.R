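# 2-D phase unwrapping.
#
# Two algorithms are provided:
#   * "quality": quality-guided region growing. Pixels are admitted to the
#     unwrapped region in order of a quality map (inverse phase-derivative
#     variance), implemented as a banded threshold sweep so the flood stays
#     vectorized. Output is congruent to the input modulo 2*pi per pixel.
#   * "lsq": unweighted least-squares unwrapping (discrete Poisson solve via
#     DCT). Exact for residue-free wrapped maps, fast, but smooths over
#     inconsistencies.
# Absolute offset handling is left to the caller.

phase_quality <- function(psi) {
  nr <- nrow(psi); nc <- ncol(psi)
  dx <- wrap_pi(psi[-1, , drop = FALSE] - psi[-nr, , drop = FALSE])
  dy <- wrap_pi(psi[, -1, drop = FALSE] - psi[, -nc, drop = FALSE])
  gx <- matrix(0, nr, nc); gy <- gx
  gx[-1, ] <- dx; gx[1, ] <- dx[1, ]
  gy[, -1] <- dy; gy[, 1] <- dy[, 1]
  # local variance of wrapped gradients: low variance = high quality
  v <- gaussian_blur(gx^2, 1) - gaussian_blur(gx, 1)^2 +
    gaussian_blur(gy^2, 1) - gaussian_blur(gy, 1)^2
  1 / (1 + pmax(v, 0))
}

unwrap_quality_guided <- function(psi, n_levels = 64L) {
  nr <- nrow(psi); nc <- ncol(psi); n <- nr * nc
  qv <- as.vector(phase_quality(psi))
  u <- as.vector(psi)
  psiv <- u
  solved <- logical(n)
  solved[which.max(qv)] <- TRUE
  row_of <- rep.int(seq_len(nr), nc)
  col_of <- rep(seq_len(nc), each = nr)
  offsets <- c(-1L, 1L, -nr, nr)
  valid_dir <- function(i, off) {
    switch(match(off, offsets),
           row_of[i] > 1L, row_of[i] < nr, col_of[i] > 1L, col_of[i] < nc)
  }
  thresholds <- stats::quantile(qv, probs = seq(1, 0, length.out = n_levels),
                                names = FALSE)
  for (thr in thresholds) {
    repeat {
      # frontier: unsolved pixels adjacent to the solved region, quality >= thr
      idx <- which(solved)
      nb <- unlist(lapply(offsets, function(off) {
        i <- idx[valid_dir(idx, off)]
        i + off
      }), use.names = FALSE)
      cand_mask <- logical(n)
      cand_mask[nb] <- TRUE
      cand <- which(cand_mask & !solved & qv >= thr)
      if (length(cand) == 0L) break
      # unwrap each candidate from its highest-quality solved neighbour
      best_nb <- integer(length(cand))
      best_q <- rep(-Inf, length(cand))
      for (off in offsets) {
        ok <- valid_dir(cand, off)
        nbi <- cand + off
        nbi[!ok] <- 1L  # dummy, masked below
        use <- ok & solved[nbi] & qv[nbi] > best_q
        best_nb[use] <- nbi[use]
        best_q[use] <- qv[nbi[use]]
      }
      keep <- best_nb > 0L
      cand <- cand[keep]; best_nb <- best_nb[keep]
      if (length(cand) == 0L) break
      u[cand] <- u[best_nb] + wrap_pi(psiv[cand] - psiv[best_nb])
      solved[cand] <- TRUE
    }
  }
  matrix(u, nr, nc)
}

# Orthogonal-free type-II DCT / inverse via FFT of even extensions.
dct_cols <- function(m) {
  n <- nrow(m)
  ext <- rbind(m, m[n:1, , drop = FALSE])
  f <- stats::mvfft(ext)[1:n, , drop = FALSE]
  Re(f * exp(-1i * pi * (seq_len(n) - 1) / (2 * n))) / 2
}

idct_cols <- function(m) {
  n <- nrow(m)
  f <- 2 * m * exp(1i * pi * (seq_len(n) - 1) / (2 * n))
  ext <- matrix(0i, 2 * n, ncol(m))
  ext[1:n, ] <- f
  ext[(n + 2):(2 * n), ] <- Conj(f[n:2, , drop = FALSE])
  Re(stats::mvfft(ext, inverse = TRUE))[1:n, , drop = FALSE] / (2 * n)
}

dct2d <- function(x) t(dct_cols(t(dct_cols(x))))
idct2d <- function(x) t(idct_cols(t(idct_cols(x))))

unwrap_lsq <- function(psi) {
  nr <- nrow(psi); nc <- ncol(psi)
  dx <- wrap_pi(diff(psi))
  dy <- wrap_pi(t(diff(t(psi))))
  # divergence of the wrapped gradient field (Neumann boundaries)
  rho <- matrix(0, nr, nc)
  rho[1:(nr - 1), ] <- rho[1:(nr - 1), ] + dx
  rho[2:nr, ] <- rho[2:nr, ] - dx
  rho[, 1:(nc - 1)] <- rho[, 1:(nc - 1)] + dy
  rho[, 2:nc] <- rho[, 2:nc] - dy
  d <- dct2d(rho)
  denom <- outer(2 * cos(pi * (seq_len(nr) - 1) / nr) - 2,
                 2 * cos(pi * (seq_len(nc) - 1) / nc) - 2, `+`)
  denom[1, 1] <- 1
  d <- d / denom
  d[1, 1] <- 0
  sol <- idct2d(d)
  sol - sol[1, 1] + psi[1, 1]
}

#' Unwrap a 2-D wrapped phase map
#'
#' @param psi matrix of wrapped phases in (-pi, pi].
#' @param method `"quality"` for quality-guided region growing (default) or
#'   `"lsq"` for least-squares (DCT Poisson) unwrapping.
#' @return Matrix of unwrapped phases (radians).
#' @export
unwrap_phase <- function(psi, method = c("quality", "lsq")) {
  method <- match.arg(method)
  switch(method,
         quality = unwrap_quality_guided(psi),
         lsq = unwrap_lsq(psi))
}
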