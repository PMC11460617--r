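# Seeded synthetic datasets: paired holograms and ground-truth phases with a
# YAML manifest, emulating the simulation protocol used to train and test
# learned reconstruction (propagation distance drawn per record from a fixed
# z-set, fixed wavelength, fixed peak phase, disjoint train/val/test splits).

#' Dataset specification
#'
#' @param n_total total number of records.
#' @param split_fractions length-3 numeric (train, val, test) summing to 1.
#' @param z_choices_mm propagation distances (mm) sampled per record.
#' @param wavelength_nm illumination wavelength (nm).
#' @param peak_phase_rad peak object phase (radians).
#' @param pitch_um grid pitch (um).
#' @param image_size grid size in pixels.
#' @param seed master seed; record seeds are derived deterministically.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_total = 6,
                         split_fractions = c(1800, 148, 100) / 2048,
                         z_choices_mm = c(0.8, 0.9, 1, 1.1, 1.2, 1.3),
                         wavelength_nm = 627, peak_phase_rad = 4,
                         pitch_um = 1.67, image_size = 128, seed = 1) {
  stopifnot(n_total >= 1, length(split_fractions) == 3,
            abs(sum(split_fractions) - 1) < 1e-9, length(z_choices_mm) >= 1)
  structure(
    list(n_total = as.integer(n_total), split_fractions = split_fractions,
         z_choices_mm = z_choices_mm, wavelength_nm = wavelength_nm,
         peak_phase_rad = peak_phase_rad, pitch_um = pitch_um,
         image_size = as.integer(image_size), seed = as.integer(seed)),
    class = "dataset_spec"
  )
}

#' Split sizes of a dataset spec
#'
#' Train and validation sizes are floored; the remainder goes to test, so
#' the three splits are disjoint and exhaustive.
#'
#' @param spec a [dataset_spec()].
#' @return Named integer vector (train, val, test).
#' @export
split_sizes <- function(spec) {
  n_train <- floor(spec$n_total * spec$split_fractions[1])
  n_val <- floor(spec$n_total * spec$split_fractions[2])
  c(train = n_train, val = n_val, test = spec$n_total - n_train - n_val)
}

#' Build a synthetic hologram dataset on disk
#'
#' Each record pairs a hologram (simulated at a z drawn from the spec's
#' z-set) with its ground-truth phase image, stored under the same file name
#' in parallel `holograms/` and `phases/` folders. The manifest
#' (`manifest.yaml`) echoes the spec and records z, wavelength and the
#' derived seed per record, so every record regenerates identically from
#' (spec, seed). A record that fails to write is marked incomplete in the
#' manifest rather than silently dropped.
#'
#' @param spec a [dataset_spec()].
#' @param dir output directory (created).
#' @return Invisibly, the manifest as a list.
#' @export
build_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "dataset_spec"))
  dir.create(file.path(dir, "holograms"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "phases"), showWarnings = FALSE, recursive = TRUE)
  ns <- split_sizes(spec)
  split_of <- rep(c("train", "val", "test"), times = ns)
  draws <- with_seed(spec$seed, {
    data.frame(
      z_mm = sample(spec$z_choices_mm, spec$n_total, replace = TRUE),
      rec_seed = sample.int(.Machine$integer.max - 1L, spec$n_total)
    )
  })
  records <- vector("list", spec$n_total)
  for (i in seq_len(spec$n_total)) {
    name <- sprintf("rec_%04d.tiff", i)
    rec <- list(name = name, split = split_of[i], z_mm = draws$z_mm[i],
                wavelength_nm = spec$wavelength_nm, seed = draws$rec_seed[i],
                complete = FALSE)
    status <- try({
      obj <- make_cell_phantom(spec$image_size, spec$pitch_um,
                               spec$peak_phase_rad, seed = draws$rec_seed[i])
      holo <- forward_hologram(
        object_field(obj, spec$wavelength_nm),
        optical_config(wavelength_nm = spec$wavelength_nm,
                       z2_mm = draws$z_mm[i], pixel_pitch_um = spec$pitch_um,
                       sensor_shape = rep(spec$image_size, 2))
      )
      write_hologram(holo, file.path(dir, "holograms", name))
      write_phase(obj$phase, file.path(dir, "phases", name),
                  pitch_um = spec$pitch_um,
                  wavelength_nm = spec$wavelength_nm)
    }, silent = TRUE)
    rec$complete <- !inherits(status, "try-error")
    records[[i]] <- rec
  }
  manifest <- list(spec = unclass(spec), records = records)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a dataset manifest
#' @param dir dataset directory.
#' @return The manifest list (`spec`, `records`).
#' @export
read_manifest <- function(dir) {
  yaml::read_yaml(file.path(dir, "manifest.yaml"))
}

#' Load dataset records into memory
#'
#' @param dir dataset directory.
#' @param split optional split filter ("train", "val", "test").
#' @param n optional cap on the number of records returned.
#' @return List of records, each with `holo`, `gt_phase`, `z_mm`, `name`.
#' @export
load_records <- function(dir, split = NULL, n = NULL) {
  man <- read_manifest(dir)
  recs <- Filter(function(r) isTRUE(r$complete), man$records)
  if (!is.null(split)) recs <- Filter(function(r) r$split == split, recs)
  if (!is.null(n)) recs <- recs[seq_len(min(n, length(recs)))]
  lapply(recs, function(r) {
    list(holo = read_hologram(file.path(dir, "holograms", r$name)),
         gt_phase = read_phase(file.path(dir, "phases", r$name)),
         z_mm = r$z_mm, name = r$name)
  })
}
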