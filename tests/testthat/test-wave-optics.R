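# Forward model: angular-spectrum propagation, hologram formation,
# normalization, coherence and field-of-view calculators.

test_that("zero-distance propagation is the identity", {
  f <- gaussian_probe()
  g <- angular_spectrum_propagate(f, 0)
  expect_identical(g$values, f$values)
})

test_that("propagation is unitary and +z/-z is the identity on band-limited fields", {
  f <- gaussian_probe(n = 128, pitch_um = 1.67)
  for (z in c(0.25, 1, 3)) {
    v <- angular_spectrum_propagate(f, z)
    expect_lt(abs(sum(Mod(v$values)^2) - sum(Mod(f$values)^2)) /
                sum(Mod(f$values)^2), 1e-9)
    w <- angular_spectrum_propagate(v, -z)
    expect_lt(max(Mod(w$values - f$values)), 1e-6)
  }
})

test_that("transfer-function propagation matches direct quadrature of the diffraction integral", {
  f <- gaussian_probe(n = 64, pitch_um = 1, sigma_um = 5)
  z_um <- 100
  asm <- angular_spectrum_propagate(f, z_um / 1000)$values
  ctr <- 17:48  # central block, away from the periodic boundary
  oracle <- rs_quadrature(f$values, 1, 0.627, z_um, ctr, ctr)
  rel <- max(Mod(asm[ctr, ctr] - oracle)) / max(Mod(oracle))
  expect_lt(rel, 1e-3)
})

test_that("point-scatterer hologram shows Fresnel rings at sqrt(m lambda z)", {
  # Gaussian-apodized weak absorber so the pattern is band-limited; the
  # intensity perturbation follows -sin(pi r^2 / (lambda z)), giving zero
  # crossings at r = sqrt(m * lambda * z) (25.04 um for m = 1 at z = 1 mm).
  n <- 256; pitch <- 0.5; lam_um <- 0.627; z_mm <- 1
  xy <- (seq_len(n) - n / 2 - 0.5) * pitch
  r2 <- outer(xy^2, xy^2, `+`)
  u <- 1 - 0.05 * exp(-r2 / (2 * 0.8^2))
  f <- complex_field(u + 0i, pitch, 627)
  holo <- forward_hologram(f, optical_config(z2_mm = z_mm, pixel_pitch_um = pitch,
                                             sensor_shape = c(n, n)))
  prof <- holo$intensity[n / 2, ] - 1
  for (m in 1:2) {
    r_m <- sqrt(m * lam_um * z_mm * 1000)
    near <- which(xy > r_m - 1.5 & xy < r_m + 1.5)
    # the intensity perturbation changes sign within 1.5 um of each
    # predicted zone radius
    expect_true(min(prof[near]) < 0 && max(prof[near]) > 0)
  }
})

test_that("hologram of an empty object is unity and weak phase conserves energy", {
  n <- 64
  plane <- complex_field(matrix(1 + 0i, n, n), 1.67, 627)
  cfg <- optical_config(z2_mm = 1, sensor_shape = c(n, n))
  h0 <- forward_hologram(plane, cfg)
  expect_lt(max(abs(h0$intensity - 1)), 1e-10)

  xy <- (seq_len(n) - n / 2 - 0.5) * 1.67
  disc <- outer(xy^2, xy^2, `+`) < 15^2
  weak <- complex_field(exp(1i * 0.1 * disc), 1.67, 627)
  h1 <- forward_hologram(weak, cfg)
  expect_lt(abs(mean(h1$intensity) - 1), 0.01)
  expect_true(all(h1$intensity >= 0))
})

test_that("forward_hologram rejects non-positive z", {
  plane <- complex_field(matrix(1 + 0i, 16, 16), 1.67, 627)
  expect_error(forward_hologram(plane, optical_config(z2_mm = 1)$z2_mm * -1))
})

test_that("normalization removes an analytic vignetting field exactly", {
  set.seed(1)
  n <- 32
  I <- matrix(runif(n * n, 0.8, 1.2), n)
  xy <- seq(-1, 1, length.out = n)
  V <- 0.5 + 0.5 * exp(-outer(xy^2, xy^2, `+`))
  h <- normalize_hologram(V * I, V * 1)
  expect_equal(h$intensity, I, tolerance = 1e-12)
  # identity and scaling cases
  expect_lt(max(abs(normalize_hologram(I, I)$intensity - 1)), 1e-12)
  expect_lt(max(abs(normalize_hologram(2 * I, I)$intensity - 2)), 1e-12)
})

test_that("reference flooring is applied and reported", {
  ref <- matrix(1, 8, 8); ref[1, 1] <- 1e-12
  h <- normalize_hologram(matrix(1, 8, 8), ref)
  expect_equal(attr(h, "n_floored"), 1L)
  expect_true(all(is.finite(h$intensity)))
})

test_that("coherence limits match the closed forms", {
  cfg <- optical_config(wavelength_nm = 627, spectral_width_nm = 20,
                        medium_index = 1, z1_mm = 50, z2_mm = 1,
                        aperture_um = 100)
  cl <- coherence_limits(cfg)
  expect_equal(cl$delta_Lc_um, 8.673825285241177, tolerance = 1e-12)
  # doubling the spectral width halves the coherence length exactly
  cfg2 <- cfg; cfg2$spectral_width_nm <- 40
  expect_equal(coherence_limits(cfg2)$delta_Lc_um, cl$delta_Lc_um / 2,
               tolerance = 1e-12)
  # monochromatic source: infinite coherence length, not an error
  cfg3 <- cfg; cfg3$spectral_width_nm <- 0
  expect_identical(coherence_limits(cfg3)$delta_Lc_um, Inf)
  # enormous aperture: spatial coherence collapses
  cfg4 <- cfg; cfg4$aperture_um <- 1e9
  cl4 <- coherence_limits(cfg4)
  expect_lt(cl4$theta_max_spatial_rad, 1e-6)
  expect_lt(cl4$D_coh_um, 1e-3)
})

test_that("field of view follows sensor geometry", {
  expect_equal(field_of_view(optical_config(pixel_pitch_um = 1000,
                                            sensor_shape = c(1, 1))), 1)
  expect_equal(field_of_view(optical_config(pixel_pitch_um = 10,
                                            sensor_shape = c(100, 200))), 2)
})

test_that("field and hologram constructors enforce their invariants", {
  expect_error(complex_field(matrix(NaN, 8, 8), 1, 627), "finite")
  expect_error(complex_field(matrix(1 + 0i, 4, 4), 1, 627), "8x8")
  expect_error(complex_field(matrix(1 + 0i, 8, 8), -1, 627), "pitch")
  expect_error(hologram(matrix(-1, 8, 8), 1, 627, 1.67), "non-negative")
  expect_warning(optical_config(z1_mm = 5, z2_mm = 1), "z1")
})
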