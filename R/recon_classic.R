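# Baseline single-shot reconstruction: hologram back-propagation with the
# angular spectrum method, sharpness-based autofocus, amplitude/phase
# extraction with unwrapping.

#' Backpropagate a hologram to the object plane
#'
#' Treats the normalized intensity itself as the sensor-plane field (the
#' classic intensity-reconstruction convention, not its square root) and
#' applies the conjugate angular-spectrum kernel over distance `z_mm`. The
#' result carries the twin-image artifact by construction: a single
#' unconstrained propagation cannot separate the conjugate wavefront.
#'
#' @param holo a [hologram()].
#' @param z_mm reconstruction distance (mm), positive towards the object.
#' @return A [complex_field()] in the object plane.
#' @export
backpropagate <- function(holo, z_mm) {
  stopifnot(inherits(holo, "hologram"))
  if (z_mm <= 0 || z_mm > 10 * holo$z2_mm)
    warning("reconstruction distance outside (0, 10 * z2]")
  f <- complex_field(holo$intensity + 0i, holo$pitch_um, holo$wavelength_nm)
  angular_spectrum_propagate(f, -z_mm)
}

# Focus criteria, all *minimized* at the object plane.
#
# "sparsity_l1l2" (default): L1/L2 ratio of the modulus of the backprojected
# DC-removed hologram. The scattered component of the hologram collapses to
# the compact object at the true distance, which minimizes the L1/L2 ratio
# (maximal sparsity); the defocused twin only spreads. Robust for compact
# and sharp-featured samples.
#
# "grad_l1" and "tamura_gradient": mean / Tamura coefficient of the gradient
# magnitude of the backpropagated amplitude. For weakly scattering phase
# samples the object vanishes from the amplitude in focus.

#' Focus criterion of an object-plane field
#'
#' @param u complex matrix: for `"sparsity_l1l2"` the backprojected
#'   DC-removed hologram, otherwise the backpropagated field whose modulus
#'   is scored.
#' @param criterion criterion name; see Details in [autofocus()].
#' @return Scalar score, smaller at better focus.
#' @export
focus_score <- function(u, criterion = c("sparsity_l1l2", "grad_l1",
                                         "tamura_gradient")) {
  criterion <- match.arg(criterion)
  if (criterion == "sparsity_l1l2") {
    d <- Mod(u)
    s2 <- sqrt(sum(d^2))
    return(if (s2 < .Machine$double.eps) 0 else sum(d) / s2)
  }
  amplitude <- Mod(u)
  gx <- amplitude[-1, , drop = FALSE] - amplitude[-nrow(amplitude), , drop = FALSE]
  gy <- amplitude[, -1, drop = FALSE] - amplitude[, -ncol(amplitude), drop = FALSE]
  g <- sqrt(gx[, -ncol(gx), drop = FALSE]^2 + gy[-nrow(gy), , drop = FALSE]^2)
  if (criterion == "grad_l1") return(mean(g))
  m <- mean(g)
  if (m < .Machine$double.eps) return(0)
  sqrt(stats::sd(g) / m)
}

#' Autofocus by sharpness search over the reconstruction distance
#'
#' Sweeps a coarse grid of `n_coarse` distances over `[z_min_mm, z_max_mm]`,
#' evaluating a sharpness criterion on the backpropagated amplitude, then
#' refines around the coarse optimum by golden-section search. All criteria
#' are minimized at focus; the default L1/L2 sparsity of the backprojected
#' DC-removed hologram is the most reliable for compact, sharp-featured
#' samples (smooth extended phase blobs carry little defocus information at
#' these Fresnel numbers whatever the criterion).
#'
#' @param holo a [hologram()].
#' @param z_min_mm,z_max_mm search interval (mm).
#' @param n_coarse number of coarse samples (>= 3).
#' @param n_fine golden-section refinement iterations.
#' @param criterion focus criterion, see [focus_score()] choices.
#' @return A list of class `focus_result`: `z_star_mm`, `criterion_curve`
#'   (data.frame of z and score), `criterion_name`, and `flat` (TRUE when the
#'   criterion had no contrast, in which case the interval midpoint is
#'   returned).
#' @export
autofocus <- function(holo, z_min_mm = 0.5, z_max_mm = 2,
                      n_coarse = 26, n_fine = 25,
                      criterion = "sparsity_l1l2") {
  stopifnot(inherits(holo, "hologram"), z_min_mm < z_max_mm, n_coarse >= 3)
  ac <- complex_field(holo$intensity - mean(holo$intensity) + 0i,
                      holo$pitch_um, holo$wavelength_nm)
  score_at <- function(z) {
    u <- if (criterion == "sparsity_l1l2") {
      angular_spectrum_propagate(ac, -z)$values
    } else {
      backpropagate(holo, z)$values
    }
    focus_score(u, criterion)
  }
  zs <- seq(z_min_mm, z_max_mm, length.out = n_coarse)
  scores <- vapply(zs, score_at, numeric(1))
  curve <- data.frame(z_mm = zs, score = scores)
  if (diff(range(scores)) < 1e-12) {
    return(structure(
      list(z_star_mm = mean(c(z_min_mm, z_max_mm)), criterion_curve = curve,
           criterion_name = criterion, flat = TRUE),
      class = "focus_result"
    ))
  }
  i <- which.min(scores)
  lo <- zs[max(i - 1L, 1L)]
  hi <- zs[min(i + 1L, length(zs))]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- score_at(c1); f2 <- score_at(c2)
  for (k in seq_len(n_fine)) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- score_at(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- score_at(c2)
    }
  }
  structure(
    list(z_star_mm = (a + b) / 2, criterion_curve = curve,
         criterion_name = criterion, flat = FALSE),
    class = "focus_result"
  )
}

#' Extract amplitude and phase from a complex field
#'
#' Amplitude is the modulus; phase is the argument in (-pi, pi], optionally
#' 2-D unwrapped and offset so that the modal value of a 10-pixel border
#' frame (the undisturbed background) is zero. Zero-modulus pixels get phase
#' 0; their count is reported as attribute `n_zero`.
#'
#' @param field a [complex_field()].
#' @param unwrap unwrap the phase (logical).
#' @param method unwrapping method passed to [unwrap_phase()].
#' @param border_px width of the background frame used for the zero offset.
#' @return A list with `amplitude` and `phase` matrices.
#' @export
extract_amp_phase <- function(field, unwrap = TRUE, method = "quality",
                              border_px = 10) {
  stopifnot(inherits(field, "complex_field"))
  amplitude <- Mod(field$values)
  phase <- Arg(field$values)
  zero <- amplitude == 0
  phase[zero] <- 0
  if (unwrap) phase <- unwrap_phase(phase, method)
  nr <- nrow(phase); nc <- ncol(phase)
  b <- min(border_px, floor(min(nr, nc) / 4))
  border <- c(phase[c(seq_len(b), nr - seq_len(b) + 1L), ],
              phase[, c(seq_len(b), nc - seq_len(b) + 1L)])
  phase <- phase - mode_estimate(border)
  out <- list(amplitude = amplitude, phase = phase)
  attr(out, "n_zero") <- sum(zero)
  out
}

#' Classic single-shot reconstruction
#'
#' Backpropagation at a fixed or autofocused distance followed by
#' amplitude/phase extraction.
#'
#' @param holo a [hologram()].
#' @param z_mm reconstruction distance in mm, or `"auto"` for autofocus.
#' @param unwrap unwrap the phase.
#' @param ... passed to [autofocus()] when `z_mm = "auto"`.
#' @return A list with `amplitude`, `phase`, `z_mm` and (for autofocus) the
#'   `focus` result.
#' @export
reconstruct_classic <- function(holo, z_mm = "auto", unwrap = TRUE, ...) {
  focus <- NULL
  if (identical(z_mm, "auto")) {
    focus <- autofocus(holo, ...)
    z_mm <- focus$z_star_mm
  }
  field <- backpropagate(holo, z_mm)
  ap <- extract_amp_phase(field, unwrap = unwrap)
  list(amplitude = ap$amplitude, phase = ap$phase, z_mm = z_mm,
       field = field, focus = focus)
}
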