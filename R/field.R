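# Domain containers: complex optical fields, acquisition geometry, holograms.
#
# Lengths are stored internally in micrometres; wavelengths are supplied in
# nanometres and axial distances in millimetres at the user-facing boundary,
# matching how acquisition metadata is usually reported.

#' Complex optical field
#'
#' A 2-D complex wave amplitude sampled on a regular grid, together with the
#' physical sampling interval (pixel pitch) and the illumination wavelength.
#'
#' @param values complex (or numeric) matrix of field amplitudes.
#' @param pitch_um sampling interval in micrometres per pixel (> 0).
#' @param wavelength_nm illumination wavelength in nanometres (> 0).
#' @return An object of class `complex_field` with elements `values`,
#'   `pitch_um`, `wavelength_nm`.
#' @export
complex_field <- function(values, pitch_um, wavelength_nm) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.complex(values)) values <- values + 0i
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("complex field values must be finite")
  if (nrow(values) < 8L || ncol(values) < 8L)
    stop("field grid must be at least 8x8")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0)
    stop("`pitch_um` must be a single positive number")
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L || wavelength_nm <= 0)
    stop("`wavelength_nm` must be a single positive number")
  structure(
    list(values = values, pitch_um = pitch_um, wavelength_nm = wavelength_nm),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %d x %d px, pitch %.4g um, lambda %.4g nm, mean |u| = %.4g\n",
    nrow(x$values), ncol(x$values), x$pitch_um, x$wavelength_nm,
    mean(Mod(x$values))
  ))
  invisible(x)
}

#' Acquisition geometry of a lensless inline holographic microscope
#'
#' Describes the source, the geometry and the sensor of a lensless inline
#' setup: a quasi-monochromatic source of wavelength `wavelength_nm` and
#' spectral width `spectral_width_nm` behind an aperture of diameter
#' `aperture_um`, a large source-to-sample distance `z1_mm`, a millimetre-scale
#' sample-to-sensor distance `z2_mm`, and a bare sensor of `sensor_shape`
#' pixels at `pixel_pitch_um`. Unit magnification is assumed, so the field of
#' view equals the sensor area.
#'
#' @param wavelength_nm central wavelength (nm).
#' @param spectral_width_nm source spectral width (nm), strictly less than
#'   the wavelength; `0` denotes an idealized monochromatic source.
#' @param medium_index refractive index of the propagation medium.
#' @param z1_mm source-to-sample distance (mm).
#' @param z2_mm sample-to-sensor distance (mm).
#' @param aperture_um illumination aperture diameter (um).
#' @param pixel_pitch_um sensor pixel pitch (um).
#' @param sensor_shape integer vector (rows, cols) of sensor pixels.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength_nm = 627,
                           spectral_width_nm = 20,
                           medium_index = 1,
                           z1_mm = 50,
                           z2_mm = 1,
                           aperture_um = 100,
                           pixel_pitch_um = 1.67,
                           sensor_shape = c(512L, 512L)) {
  lens <- c(wavelength_nm, medium_index, z1_mm, z2_mm, aperture_um, pixel_pitch_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths and indices in the optical configuration must be positive")
  if (spectral_width_nm < 0) stop("`spectral_width_nm` must be >= 0")
  if (spectral_width_nm >= wavelength_nm)
    stop("spectral width must be smaller than the wavelength")
  if (z1_mm < 10 * z2_mm)
    warning("z1 < 10 * z2: the plane-wave illumination approximation is poor")
  sensor_shape <- as.integer(sensor_shape)
  if (length(sensor_shape) != 2L || any(sensor_shape < 1L))
    stop("`sensor_shape` must be two positive integers")
  structure(
    list(
      wavelength_nm = wavelength_nm, spectral_width_nm = spectral_width_nm,
      medium_index = medium_index, z1_mm = z1_mm, z2_mm = z2_mm,
      aperture_um = aperture_um, pixel_pitch_um = pixel_pitch_um,
      sensor_shape = sensor_shape
    ),
    class = "optical_config"
  )
}

#' Normalized inline hologram
#'
#' A non-negative real intensity image, normalized by a no-sample reference
#' recording so the undisturbed background sits near 1, plus the acquisition
#' metadata needed to reconstruct it.
#'
#' @param intensity non-negative numeric matrix.
#' @param z2_mm sample-to-sensor distance (mm).
#' @param wavelength_nm illumination wavelength (nm).
#' @param pitch_um pixel pitch (um).
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, z2_mm, wavelength_nm, pitch_um) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  if (any(!is.finite(intensity))) stop("hologram intensity must be finite")
  if (any(intensity < 0)) stop("hologram intensity must be non-negative")
  if (z2_mm <= 0) stop("`z2_mm` must be positive")
  structure(
    list(intensity = intensity, z2_mm = z2_mm,
         wavelength_nm = wavelength_nm, pitch_um = pitch_um),
    class = "hologram"
  )
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf(
    "<hologram> %d x %d px, pitch %.4g um, lambda %.4g nm, z2 %.4g mm, mean I = %.4g\n",
    nrow(x$intensity), ncol(x$intensity), x$pitch_um, x$wavelength_nm,
    x$z2_mm, mean(x$intensity)
  ))
  invisible(x)
}
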