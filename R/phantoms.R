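# Synthetic ground-truth objects: phase beads and cell-like phantoms, plus
# sensor-side plumbing (binning, noise). Everything is a pure function of its
# arguments and seed, so datasets regenerate identically.

#' Ground-truth phase object
#'
#' @param phase matrix of optical phase delays (radians).
#' @param amplitude matrix of transmission amplitudes in \[0, 1\].
#' @param pitch_um sampling interval (um).
#' @param physical_params optional list with `h_um` (thickness map or peak,
#'   um), `n1`, `n2` (sample / medium refractive indices).
#' @return An object of class `ground_truth_object`.
#' @export
ground_truth_object <- function(phase, amplitude = NULL, pitch_um = 1.67,
                                physical_params = NULL) {
  if (is.null(amplitude)) amplitude <- matrix(1, nrow(phase), ncol(phase))
  if (any(!is.finite(phase))) stop("phase must be finite")
  if (any(amplitude < 0 | amplitude > 1)) stop("amplitude must lie in [0, 1]")
  if (!all(dim(phase) == dim(amplitude))) stop("phase/amplitude shape mismatch")
  structure(
    list(phase = phase, amplitude = amplitude, pitch_um = pitch_um,
         physical_params = physical_params),
    class = "ground_truth_object"
  )
}

#' Object transmission field of a ground-truth object
#'
#' @param object a [ground_truth_object()].
#' @param wavelength_nm illumination wavelength (nm).
#' @return A [complex_field()] `amplitude * exp(i * phase)`.
#' @export
object_field <- function(object, wavelength_nm = 627) {
  complex_field(object$amplitude * exp(1i * object$phase),
                object$pitch_um, wavelength_nm)
}

#' Spherical-cap microbead phantom
#'
#' Places `n_beads` non-overlapping spherical beads of the given diameter on
#' the grid. Each bead contributes a spherical-cap thickness profile
#' \eqn{h(r) = d \sqrt{1 - (r/R)^2}} for \eqn{r \le R} and an optical phase
#' \eqn{\phi = 2\pi h (n_1 - n_2) / \lambda}; the transmission amplitude is 1
#' (pure phase object). A 4 um polystyrene bead (n1 = 1.68) in water
#' (n2 = 1.33) at 627 nm has a peak phase of 2*pi*4*0.35/0.627 = 14.03 rad.
#'
#' @param n_beads number of beads to place.
#' @param bead_diameter_um bead diameter (um); must be at least two pixels.
#' @param n1 bead refractive index.
#' @param n2 medium refractive index.
#' @param wavelength_nm illumination wavelength (nm).
#' @param pitch_um grid pitch (um).
#' @param size grid size in pixels (scalar or length 2).
#' @param seed RNG seed; placement is a pure function of the arguments.
#' @param margin_px keep bead centres this far from the border.
#' @return A [ground_truth_object()] whose `physical_params` records the
#'   thickness map and indices, with the bead centres as attribute `centers`.
#' @export
make_bead_phantom <- function(n_beads = 1, bead_diameter_um = 4,
                              n1 = 1.68, n2 = 1.33, wavelength_nm = 627,
                              pitch_um = 1.67, size = 256, seed = 1,
                              margin_px = 24) {
  size <- rep(as.integer(size), length.out = 2L)
  if (bead_diameter_um < 2 * pitch_um)
    stop("bead diameter must be at least two pixels for the profile to be sampled")
  radius_um <- bead_diameter_um / 2
  lambda_um <- wavelength_nm / 1000
  centers <- with_seed(seed, {
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(placed) < n_beads) {
      tries <- tries + 1L
      if (tries > 200L * n_beads)
        stop("could not place ", n_beads, " beads without overlap; ",
             "reduce n_beads or bead_diameter_um")
      cand <- c(stats::runif(1, margin_px + 1, size[1] - margin_px),
                stats::runif(1, margin_px + 1, size[2] - margin_px))
      cand <- round(cand)  # snap to the grid so r = 0 is sampled exactly
      if (nrow(placed) == 0L ||
          all(sqrt(rowSums(sweep(placed, 2, cand)^2)) * pitch_um >
              1.5 * bead_diameter_um)) {
        placed <- rbind(placed, cand)
      }
    }
    placed
  })
  xg <- seq_len(size[1]) * pitch_um
  yg <- seq_len(size[2]) * pitch_um
  h <- matrix(0, size[1], size[2])
  for (b in seq_len(n_beads)) {
    dx2 <- (xg - centers[b, 1] * pitch_um)^2
    dy2 <- (yg - centers[b, 2] * pitch_um)^2
    r2 <- outer(dx2, dy2, `+`)
    inside <- r2 <= radius_um^2
    h[inside] <- h[inside] +
      bead_diameter_um * sqrt(1 - r2[inside] / radius_um^2)
  }
  phase <- 2 * pi * h * (n1 - n2) / lambda_um
  obj <- ground_truth_object(
    phase, pitch_um = pitch_um,
    physical_params = list(h_um = h, n1 = n1, n2 = n2,
                           bead_diameter_um = bead_diameter_um,
                           wavelength_nm = wavelength_nm)
  )
  attr(obj, "centers") <- centers
  obj
}

#' Cell-like smooth phase phantom
#'
#' A parametric stand-in for an unstained epithelial cell: an elliptical
#' cytoplasm blob of low phase with one or two denser nuclei, Gaussian
#' smoothed so the object is band-limited at the grid pitch, then rescaled so
#' the maximum phase equals `peak_phase_rad` exactly. Purely a function of
#' the seed.
#'
#' @param size grid size in pixels (scalar or length 2).
#' @param pitch_um grid pitch (um).
#' @param peak_phase_rad peak optical phase (radians); 0 gives a blank
#'   object.
#' @param seed RNG seed.
#' @param smooth_sigma_px Gaussian smoothing radius in pixels.
#' @return A [ground_truth_object()] (pure phase, amplitude 1).
#' @export
make_cell_phantom <- function(size = 256, pitch_um = 1.67, peak_phase_rad = 4,
                              seed = 1, smooth_sigma_px = 3) {
  size <- rep(as.integer(size), length.out = 2L)
  if (peak_phase_rad < 0) stop("`peak_phase_rad` must be >= 0")
  phase <- with_seed(seed, {
    cx <- size[1] / 2 + stats::runif(1, -0.18, 0.18) * size[1]
    cy <- size[2] / 2 + stats::runif(1, -0.18, 0.18) * size[2]
    # cytoplasm: rotated ellipse, up to ~a third of the grid across
    a <- stats::runif(1, 0.13, 0.28) * size[1]
    b <- stats::runif(1, 0.1, 0.24) * size[2]
    th <- stats::runif(1, 0, pi)
    x <- sweep(matrix(seq_len(size[1]), size[1], size[2]), 1, cx)
    y <- sweep(matrix(rep(seq_len(size[2]), each = size[1]), size[1]), 1, cy)
    xr <- x * cos(th) + y * sin(th)
    yr <- -x * sin(th) + y * cos(th)
    rr <- sqrt((xr / a)^2 + (yr / b)^2)
    # soft-edged cytoplasm with a little lobed irregularity
    lobe <- 1 + 0.15 * sin(3 * atan2(yr, xr) + stats::runif(1, 0, 2 * pi))
    cyto <- pmax(0, 1 - (rr / lobe)^2)^1.5
    m <- cyto * 0.35
    n_nuclei <- sample(1:2, 1)
    for (k in seq_len(n_nuclei)) {
      nx <- cx + stats::runif(1, -0.4, 0.4) * a
      ny <- cy + stats::runif(1, -0.4, 0.4) * b
      nr <- stats::runif(1, 0.15, 0.3) * min(a, b)
      d2 <- (x + cx - nx)^2 + (y + cy - ny)^2
      m <- m + exp(-d2 / (2 * nr^2)) * cyto
    }
    m
  })
  phase <- gaussian_blur(phase, smooth_sigma_px)
  phase[phase < 0] <- 0
  if (max(phase) > 0) phase <- phase * (peak_phase_rad / max(phase))
  ground_truth_object(phase, pitch_um = pitch_um)
}

#' Bin a hologram to a coarser sensor pitch
#'
#' Non-overlapping `factor x factor` pixel-mean binning; the pitch is
#' multiplied by `factor`. Used to emulate a low-resolution sensor recording
#' of a finely simulated diffraction pattern.
#'
#' @param holo a [hologram()].
#' @param factor integer binning factor; must divide both dimensions.
#' @return A [hologram()].
#' @export
downsample_sensor <- function(holo, factor) {
  stopifnot(inherits(holo, "hologram"))
  factor <- as.integer(factor)
  if (factor == 1L) return(holo)
  d <- dim(holo$intensity)
  if (any(d %% factor != 0L))
    stop("binning factor must divide both image dimensions")
  # mean over factor x factor blocks: average rows, transpose, average again
  x <- colMeans(array(holo$intensity, c(factor, d[1] %/% factor, d[2])))
  x <- colMeans(array(t(x), c(factor, d[2] %/% factor, d[1] %/% factor)))
  hologram(t(x), holo$z2_mm, holo$wavelength_nm, holo$pitch_um * factor)
}

#' Add sensor noise to a hologram
#'
#' Poisson shot noise at `shot_scale` photons per unit intensity followed by
#' additive Gaussian read noise of standard deviation `read_sigma` (in
#' normalized intensity units), clipped at zero. `shot_scale = 0` disables
#' shot noise. Seeded and reproducible.
#'
#' @param holo a [hologram()].
#' @param shot_scale photons per unit normalized intensity (0 = off).
#' @param read_sigma read-noise standard deviation (0 = off).
#' @param seed RNG seed.
#' @return A [hologram()].
#' @export
add_noise <- function(holo, shot_scale = 0, read_sigma = 0, seed = 1) {
  stopifnot(inherits(holo, "hologram"))
  if (shot_scale < 0 || read_sigma < 0) stop("noise parameters must be >= 0")
  if (shot_scale == 0 && read_sigma == 0) return(holo)
  x <- holo$intensity
  x <- with_seed(seed, {
    if (shot_scale > 0)
      x <- matrix(stats::rpois(length(x), x * shot_scale) / shot_scale,
                  nrow(x), ncol(x))
    if (read_sigma > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, read_sigma), nrow(x), ncol(x))
    x
  })
  x[x < 0] <- 0
  hologram(x, holo$z2_mm, holo$wavelength_nm, holo$pitch_um)
}
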