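# Scalar diffraction forward model: angular spectrum free-space propagation,
# hologram formation and normalization, coherence-limited resolution.

# Free-space transfer function for the angular spectrum method on the FFT
# frequency grid of `dim_hw` at `pitch_um`. The propagation phase is
# exp(i * 2*pi * (z/lambda) * sqrt(1 - (lambda fx)^2 - (lambda fy)^2)); the
# sign of `dz_um` selects the direction, so propagate(z) and propagate(-z)
# are exact mutual inverses on the non-evanescent band. Frequencies with a
# negative square-root argument (evanescent waves) are zeroed.
asm_transfer <- function(dim_hw, pitch_um, wavelength_um, dz_um) {
  fx <- fft_freq(dim_hw[1], pitch_um)
  fy <- fft_freq(dim_hw[2], pitch_um)
  arg <- 1 - outer((wavelength_um * fx)^2, (wavelength_um * fy)^2, `+`)
  mask <- arg >= 0
  kz <- sqrt(pmax(arg, 0))
  h <- exp(2i * pi * (dz_um / wavelength_um) * kz)
  h[!mask] <- 0
  h
}

#' Angular spectrum free-space propagation
#'
#' Propagates a sampled complex field over a signed axial distance by
#' multiplying its spatial-frequency spectrum with the free-space transfer
#' function. Spatial frequencies on the evanescent band
#' (\eqn{1 - (\lambda f_x)^2 - (\lambda f_y)^2 < 0}) are removed. Positive
#' distances propagate from the object towards the sensor; negative distances
#' apply the conjugate kernel, so a +z / -z round trip is the identity for
#' band-limited fields.
#'
#' @param field a [complex_field()].
#' @param dz_mm signed propagation distance in millimetres.
#' @return A [complex_field()] of identical shape and pitch.
#' @export
angular_spectrum_propagate <- function(field, dz_mm) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.finite(dz_mm)) stop("`dz_mm` must be finite")
  if (dz_mm == 0) return(field)
  wavelength_um <- field$wavelength_nm / 1000
  # lambda * Nyquist >= 1 means the propagation phase turns over within one
  # frequency sample: warn about aliasing risk and proceed.
  if (wavelength_um / (2 * field$pitch_um) >= 1)
    warning("wavelength exceeds twice the pixel pitch: aliasing risk in propagation")
  h <- asm_transfer(dim(field$values), field$pitch_um, wavelength_um, dz_mm * 1000)
  u <- stats::fft(stats::fft(field$values) * h, inverse = TRUE) / length(field$values)
  complex_field(u, field$pitch_um, field$wavelength_nm)
}

#' Simulate an inline hologram from an object transmission
#'
#' Forms the normalized intensity recorded by a bare sensor at distance
#' `config$z2_mm` behind the object. The object field is the full complex
#' transmission under unit plane-wave illumination (unscattered reference
#' included), so the sensor intensity is \eqn{|P_{z_2}(u_o)|^2}. The no-sample
#' reference recording of the same geometry is the unit plane wave, whose
#' propagated intensity is 1, so normalization is division by 1 and the
#' returned hologram keeps the self-interference (twin-image) physics intact.
#'
#' @param object_field a [complex_field()] giving the object-plane
#'   transmission (amplitude in \[0, 1\], phase in radians).
#' @param config an [optical_config()]; `z2_mm`, wavelength and pitch are
#'   taken from the field where they are already carried.
#' @return A [hologram()].
#' @export
forward_hologram <- function(object_field, config) {
  stopifnot(inherits(object_field, "complex_field"))
  z2 <- if (inherits(config, "optical_config")) config$z2_mm else config
  if (!is.numeric(z2) || z2 <= 0) stop("sample-to-sensor distance z2 must be positive")
  sensor <- angular_spectrum_propagate(object_field, z2)
  intensity <- Mod(sensor$values)^2
  hologram(intensity, z2_mm = z2,
           wavelength_nm = object_field$wavelength_nm,
           pitch_um = object_field$pitch_um)
}

#' Normalize a raw hologram by a reference recording
#'
#' Element-wise division of the raw recording by the no-sample reference
#' recording. This removes the reference intensity profile (source envelope,
#' vignetting, fixed-pattern gain) so the undisturbed background sits at 1.
#' Reference pixels below `1e-6 * max(reference)` are floored to that value;
#' the number of floored pixels is reported as an attribute `n_floored`.
#'
#' @param raw numeric matrix, raw sensor intensity.
#' @param reference numeric matrix of the same shape, no-sample recording.
#' @param z2_mm,wavelength_nm,pitch_um acquisition metadata for the result.
#' @return A [hologram()] with attribute `n_floored`.
#' @export
normalize_hologram <- function(raw, reference, z2_mm = 1, wavelength_nm = 627,
                               pitch_um = 1.67) {
  if (!all(dim(raw) == dim(reference)))
    stop("`raw` and `reference` must have the same shape")
  floor_val <- 1e-6 * max(reference)
  low <- reference < floor_val
  reference[low] <- floor_val
  h <- hologram(raw / reference, z2_mm, wavelength_nm, pitch_um)
  attr(h, "n_floored") <- sum(low)
  h
}

#' Coherence-limited resolution of a lensless inline geometry
#'
#' Computes the temporal coherence length
#' \eqn{\Delta L_c = (2 \ln 2 / \pi) \lambda^2 / (n \Delta\lambda)}, the
#' spatial coherence diameter at the sample \eqn{D_{coh} = \lambda z_1 / D},
#' the maximal interference angles allowed by each
#' (\eqn{\theta_t = \arccos(z_2 / (z_2 + \Delta L_c))},
#' \eqn{\theta_s = \arctan(0.61 \lambda z_1 / (D z_2))}) and the resulting
#' conservative resolution estimate
#' \eqn{\Delta x = \lambda / (2 \sin \min(\theta_t, \theta_s))}.
#'
#' @param config an [optical_config()].
#' @return A list with elements `delta_Lc_um`, `D_coh_um`,
#'   `theta_max_temporal_rad`, `theta_max_spatial_rad`, `delta_x_um`.
#'   A zero spectral width yields an infinite coherence length (and a
#'   temporal angle of pi/2), not an error.
#' @export
coherence_limits <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  lambda_um <- config$wavelength_nm / 1000
  dlambda_um <- config$spectral_width_nm / 1000
  z1_um <- config$z1_mm * 1000
  z2_um <- config$z2_mm * 1000
  delta_Lc <- if (dlambda_um == 0) Inf else
    (2 * log(2) / pi) * lambda_um^2 / (config$medium_index * dlambda_um)
  D_coh <- lambda_um * z1_um / config$aperture_um
  theta_t <- if (is.infinite(delta_Lc)) pi / 2 else acos(z2_um / (z2_um + delta_Lc))
  theta_s <- atan(0.61 * lambda_um * z1_um / (config$aperture_um * z2_um))
  delta_x <- lambda_um / (2 * sin(min(theta_t, theta_s)))
  list(
    delta_Lc_um = delta_Lc, D_coh_um = D_coh,
    theta_max_temporal_rad = theta_t, theta_max_spatial_rad = theta_s,
    delta_x_um = delta_x
  )
}

#' Sensor field of view
#'
#' Area imaged by the bare sensor under the unit-magnification lensless
#' geometry: `(rows * pitch) * (cols * pitch)` converted to square
#' millimetres.
#'
#' @param config an [optical_config()].
#' @return Field of view in mm^2.
#' @export
field_of_view <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  prod(config$sensor_shape) * (config$pixel_pitch_um / 1000)^2
}
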