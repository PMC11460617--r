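# Synthetic ground-truth objects and dataset plumbing.

test_that("bead phantom peak phase matches the optical-path closed form", {
  b <- make_bead_phantom(1, 4, 1.68, 1.33, 627, 1.67, 128, seed = 3)
  expect_equal(max(b$phase), 14.029440877274993, tolerance = 1e-9)
  # phase is the optical path of the thickness map everywhere, not just at peak
  expect_equal(b$phase,
               2 * pi * b$physical_params$h_um * (1.68 - 1.33) / 0.627,
               tolerance = 1e-9)
  # index matching removes the object
  b0 <- make_bead_phantom(1, 4, 1.5, 1.5, 627, 1.67, 128, seed = 3)
  expect_true(all(b0$phase == 0))
})

test_that("bead phantom is deterministic and refuses impossible packings", {
  b1 <- make_bead_phantom(3, 6, 1.68, 1.33, size = 128, seed = 9)
  b2 <- make_bead_phantom(3, 6, 1.68, 1.33, size = 128, seed = 9)
  expect_identical(b1$phase, b2$phase)
  expect_error(make_bead_phantom(500, 20, size = 64, seed = 1), "overlap")
  expect_error(make_bead_phantom(1, bead_diameter_um = 1, pitch_um = 1.67),
               "two pixels")
})

test_that("cell phantom hits the requested peak exactly and varies with seed", {
  c1 <- make_cell_phantom(128, peak_phase_rad = 4, seed = 1)
  expect_equal(max(c1$phase), 4, tolerance = 1e-12)
  expect_true(all(c1$phase >= 0))
  expect_true(all(make_cell_phantom(64, peak_phase_rad = 0, seed = 1)$phase == 0))
  # diversity across seeds
  pairs <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), ncol = 2, byrow = TRUE)
  ss <- apply(pairs, 1, function(p) {
    ssim(make_cell_phantom(64, seed = p[1])$phase,
         make_cell_phantom(64, seed = p[2])$phase)
  })
  expect_true(all(ss < 0.9))
})

test_that("sensor binning averages blocks and scales the pitch", {
  h <- hologram(matrix(as.numeric(1:16), 4), 1, 627, 1.67)
  d <- downsample_sensor(h, 2)
  expect_equal(d$intensity, matrix(c(3.5, 5.5, 11.5, 13.5), 2), tolerance = 1e-12)
  expect_equal(d$pitch_um, 3.34)
  # checkerboard of period 2 collapses to its mean
  cb <- hologram(outer(1:8, 1:8, function(i, j) (i + j) %% 2), 1, 627, 1)
  expect_true(all(abs(downsample_sensor(cb, 2)$intensity - 0.5) < 1e-12))
  # identity and error cases
  expect_identical(downsample_sensor(h, 1), h)
  expect_error(downsample_sensor(h, 3), "divide")
})

test_that("sensor noise is seeded, scaled and clipped", {
  h <- hologram(matrix(1, 512, 512), 1, 627, 1.67)
  expect_identical(add_noise(h, 0, 0), h)
  n1 <- add_noise(h, 0, 0.01, seed = 5)
  n2 <- add_noise(h, 0, 0.01, seed = 5)
  expect_identical(n1$intensity, n2$intensity)
  s <- stats::sd(n1$intensity)
  expect_gt(s, 0.009); expect_lt(s, 0.011)
  n3 <- add_noise(hologram(matrix(0.01, 64, 64), 1, 627, 1.67), 50, 0.2, seed = 1)
  expect_true(all(n3$intensity >= 0))
})

test_that("dataset builder writes paired records with the stated split rule", {
  dir <- withr::local_tempdir()
  spec <- dataset_spec(n_total = 10, split_fractions = c(0.8, 0.1, 0.1),
                       image_size = 32, seed = 4)
  expect_equal(unname(split_sizes(spec)), c(8, 1, 1))
  # the published protocol proportions reproduce the published counts
  expect_equal(unname(split_sizes(dataset_spec(n_total = 2048))),
               c(1800, 148, 100))
  man <- build_dataset(spec, dir)
  expect_length(man$records, 10)
  expect_true(all(vapply(man$records, `[[`, TRUE, "complete")))
  expect_setequal(list.files(file.path(dir, "holograms"), pattern = "tiff$"),
                  list.files(file.path(dir, "phases"), pattern = "tiff$"))
  recs <- load_records(dir, split = "train")
  expect_length(recs, 8)
  expect_true(all(recs[[1]]$holo$intensity >= 0))
  expect_lte(max(recs[[1]]$gt_phase), spec$peak_phase_rad + 1e-6)
  # z values come from the configured z-set
  zs <- vapply(man$records, `[[`, 0, "z_mm")
  expect_true(all(zs %in% spec$z_choices_mm))
})

test_that("dataset regenerates identically from the same spec", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- dataset_spec(n_total = 3, image_size = 32, seed = 11)
  build_dataset(spec, d1)
  build_dataset(spec, d2)
  for (f in list.files(file.path(d1, "holograms"))) {
    expect_identical(readBin(file.path(d1, "holograms", f), "raw", 1e6),
                     readBin(file.path(d2, "holograms", f), "raw", 1e6))
  }
  m1 <- read_manifest(d1); m2 <- read_manifest(d2)
  expect_identical(m1, m2)
})

test_that("weak-phase bead hologram round-trips through classic reconstruction", {
  # peak phase below pi: backpropagation plus unwrapping recovers the peak
  # within 5 percent (twin-image bias stays small for a compact weak object)
  b <- make_bead_phantom(1, 12, 1.3467, 1.33, 627, 1.67, 256, seed = 2)
  peak <- max(b$phase)
  expect_lt(peak, pi)
  h <- forward_hologram(object_field(b), optical_config(z2_mm = 2,
                                                        sensor_shape = c(256, 256)))
  r <- reconstruct_classic(h, 2)
  expect_lt(abs(max(r$phase) - peak) / peak, 0.05)
})
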