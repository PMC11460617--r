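# Image and metadata persistence. Holograms are stored as 16-bit grayscale
# TIFF (or PNG) with a YAML sidecar carrying the acquisition metadata and
# the quantization scale; phase maps and complex fields as 32-bit float
# TIFF with values mapped through a recorded offset/scale (the TIFF writer
# clamps to [0, 1]).

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

write_image_scaled <- function(img, path, bits = 16L) {
  lo <- min(img); hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  scaled <- (img - lo) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = bits)
  }
  list(offset = lo, scale = scale)
}

read_image_scaled <- function(path, offset, scale) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * scale + offset
}

#' Write / read a hologram with its sidecar metadata
#'
#' The intensity image goes to 16-bit TIFF (or PNG, by extension); the
#' sidecar YAML holds `z2_mm`, `wavelength_nm`, `pitch_um` and the
#' quantization `offset`/`scale` used to map intensities into the file.
#'
#' @param holo a [hologram()].
#' @param path image path (`.tiff`/`.tif`/`.png`).
#' @return `read_hologram` returns the [hologram()].
#' @export
write_hologram <- function(holo, path) {
  stopifnot(inherits(holo, "hologram"))
  q <- write_image_scaled(holo$intensity, path, bits = 16L)
  yaml::write_yaml(
    list(type = "hologram", z2_mm = holo$z2_mm,
         wavelength_nm = holo$wavelength_nm, pitch_um = holo$pitch_um,
         offset = q$offset, scale = q$scale),
    sidecar_path(path)
  )
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  img <- read_image_scaled(path, meta$offset, meta$scale)
  img[img < 0] <- 0
  hologram(img, meta$z2_mm, meta$wavelength_nm, meta$pitch_um)
}

#' Write / read a phase map (32-bit float TIFF plus sidecar)
#'
#' @param phase matrix of phases (radians).
#' @param path image path.
#' @param pitch_um,wavelength_nm optional metadata stored in the sidecar.
#' @return `read_phase` returns the matrix (attributes `pitch_um`,
#'   `wavelength_nm` if present in the sidecar).
#' @export
write_phase <- function(phase, path, pitch_um = NULL, wavelength_nm = NULL) {
  q <- write_image_scaled(phase, path, bits = 32L)
  yaml::write_yaml(
    list(type = "phase", offset = q$offset, scale = q$scale,
         pitch_um = pitch_um, wavelength_nm = wavelength_nm),
    sidecar_path(path)
  )
  invisible(path)
}

#' @rdname write_phase
#' @export
read_phase <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  img <- read_image_scaled(path, meta$offset, meta$scale)
  attr(img, "pitch_um") <- meta$pitch_um
  attr(img, "wavelength_nm") <- meta$wavelength_nm
  img
}

#' Write / read a complex field as a two-channel 32-bit float TIFF
#'
#' Channels are (real, imaginary); the sidecar records per-channel
#' offset/scale plus `pitch_um` and `wavelength_nm`.
#'
#' @param field a [complex_field()].
#' @param path image path (TIFF).
#' @return `read_field` returns the [complex_field()].
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  re <- Re(field$values); im <- Im(field$values)
  qs <- lapply(list(re, im), function(ch) {
    lo <- min(ch); hi <- max(ch)
    list(offset = lo, scale = if (hi > lo) hi - lo else 1)
  })
  arr <- array(0, c(dim(re), 2L))
  arr[, , 1] <- (re - qs[[1]]$offset) / qs[[1]]$scale
  arr[, , 2] <- (im - qs[[2]]$offset) / qs[[2]]$scale
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  yaml::write_yaml(
    list(type = "complex_field", pitch_um = field$pitch_um,
         wavelength_nm = field$wavelength_nm,
         real = qs[[1]], imag = qs[[2]]),
    sidecar_path(path)
  )
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  arr <- suppressWarnings(tiff::readTIFF(path))
  re <- arr[, , 1] * meta$real$scale + meta$real$offset
  im <- arr[, , 2] * meta$imag$scale + meta$imag$offset
  complex_field(matrix(complex(real = re, imaginary = im), nrow(re), ncol(re)),
                meta$pitch_um, meta$wavelength_nm)
}
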