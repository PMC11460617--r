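# Independent scalar-diffraction oracle: direct quadrature of the
# Rayleigh-Sommerfeld (first kind) integral on the sampling grid. Used only
# to cross-check the transfer-function propagation; deliberately shares no
# code with the production path.
rs_quadrature <- function(u, pitch_um, wavelength_um, z_um,
                          out_rows = seq_len(nrow(u)),
                          out_cols = seq_len(ncol(u))) {
  n <- nrow(u); m <- ncol(u)
  xy_r <- (seq_len(n) - n / 2 - 0.5) * pitch_um
  xy_c <- (seq_len(m) - m / 2 - 0.5) * pitch_um
  k <- 2 * pi / wavelength_um
  out <- matrix(0 + 0i, length(out_rows), length(out_cols))
  for (a in seq_along(out_rows)) {
    dx2 <- (xy_r - xy_r[out_rows[a]])^2
    for (b in seq_along(out_cols)) {
      rho <- sqrt(outer(dx2, (xy_c - xy_c[out_cols[b]])^2, `+`) + z_um^2)
      ker <- (z_um / (2 * pi * rho^2)) * (1 / rho - 1i * k) *
        exp(1i * k * rho) * pitch_um^2
      out[a, b] <- sum(u * ker)
    }
  }
  out
}

# Band-limited Gaussian probe field used by several propagation tests.
gaussian_probe <- function(n = 64, pitch_um = 1, wavelength_nm = 627,
                           sigma_um = 5, phase_amp = 0.4) {
  xy <- (seq_len(n) - n / 2 - 0.5) * pitch_um
  r2 <- outer(xy^2, xy^2, `+`)
  u <- exp(-r2 / (2 * sigma_um^2)) * exp(1i * phase_amp * exp(-r2 / (2 * sigma_um^2)))
  complex_field(u, pitch_um, wavelength_nm)
}
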