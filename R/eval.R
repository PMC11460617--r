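# Quantitative evaluation: phase signal-to-noise ratio, SSIM, MSE,
# phase-to-thickness conversion, and parameter-robustness sweeps.

#' Phase signal-to-noise ratio (dB)
#'
#' `p-SNR = 10 * log10((max(P) - mu) / sigma)` where `mu` and `sigma` are
#' the mean and standard deviation of the phase image (or of a region of
#' interest). The ratio is a dimensionless amplitude ratio: how far the
#' phase peak rises above the background fluctuation.
#'
#' @param phase phase image (radians), finite.
#' @param roi optional logical mask restricting the statistics.
#' @return p-SNR in dB; `Inf` for a constant image (sigma = 0).
#' @export
psnr_phase <- function(phase, roi = NULL) {
  if (!is.null(roi)) phase <- phase[roi]
  if (any(!is.finite(phase))) stop("phase must be finite")
  s <- stats::sd(phase)
  if (s == 0) return(Inf)
  10 * log10((max(phase) - mean(phase)) / s)
}

#' Structural similarity index (mean SSIM)
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), stabilizers
#' `K1 = 0.01`, `K2 = 0.03`, and the dynamic range taken from the reference
#' image.
#'
#' @param x image to score.
#' @param reference reference image of the same shape; sets the data range.
#' @return Mean SSIM in \[-1, 1\].
#' @export
ssim <- function(x, reference) {
  if (!all(dim(x) == dim(reference))) stop("shape mismatch")
  L <- diff(range(reference))
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  k <- gaussian_kernel(1.5, radius = 5)
  mu_x <- filter_separable(x, k)
  mu_y <- filter_separable(reference, k)
  sxx <- filter_separable(x^2, k) - mu_x^2
  syy <- filter_separable(reference^2, k) - mu_y^2
  sxy <- filter_separable(x * reference, k) - mu_x * mu_y
  m <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  mean(m)
}

#' Mean squared error
#' @param x,reference same-shape images.
#' @return Mean of squared differences.
#' @export
mse <- function(x, reference) {
  if (!all(dim(x) == dim(reference))) stop("shape mismatch")
  mean((x - reference)^2)
}

#' Convert unwrapped phase to physical thickness
#'
#' `h = p * lambda / (2 * pi * (n1 - n2))`, the optical-path-length relation
#' between the phase delay `p` of a sample of refractive index `n1` in a
#' medium of index `n2`.
#'
#' @param phase unwrapped phase (radians), scalar or matrix.
#' @param wavelength_nm wavelength (nm).
#' @param n1 sample refractive index.
#' @param n2 medium refractive index (must differ from `n1`).
#' @return Thickness in micrometres, same shape as `phase`.
#' @export
thickness_map <- function(phase, wavelength_nm, n1, n2) {
  if (n1 == n2) stop("n1 = n2: thickness is undefined without index contrast")
  phase * (wavelength_nm / 1000) / (2 * pi * (n1 - n2))
}

#' Parameter-robustness sweep
#'
#' Reconstructs each record of a list of (hologram, ground-truth) pairs with
#' each method over a sweep axis (propagation distance `z` or wavelength
#' `lambda`) and scores SSIM, MSE and p-SNR of the recovered phase against
#' the ground truth. Also reports, per method, the interval of sweep values
#' where SSIM stays at or above 95 percent of its per-method maximum (the
#' "width of the peak performance").
#'
#' @param records list of lists with elements `holo` (a [hologram()]) and
#'   `gt_phase` (matrix); records without ground truth are skipped with a
#'   warning.
#' @param methods named list of functions `f(holo, value)` returning a phase
#'   matrix at the ground-truth shape.
#' @param axis `"z"` or `"lambda"`; the swept acquisition parameter,
#'   substituted into the hologram metadata before reconstruction.
#' @param values numeric sweep values (mm for `"z"`, nm for `"lambda"`).
#' @return An object of class `eval_report`: data.frame `per_image` with one
#'   row per (record, method, value), aggregate `summary`, and `peak_width`.
#' @export
sweep_eval <- function(records, methods, axis = c("z", "lambda"), values) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1, length(methods) >= 1,
            !is.null(names(methods)))
  rows <- list()
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    if (is.null(rec$gt_phase)) {
      warning("record ", ri, " has no ground truth; skipped")
      next
    }
    for (v in values) {
      holo <- rec$holo
      if (axis == "z") holo$z2_mm <- v else holo$wavelength_nm <- v
      for (m in names(methods)) {
        ph <- methods[[m]](holo, v)
        rows[[length(rows) + 1L]] <- data.frame(
          record = ri, method = m, value = v,
          ssim = ssim(ph, rec$gt_phase), mse = mse(ph, rec$gt_phase),
          psnr_phase = psnr_phase(ph)
        )
      }
    }
  }
  per_image <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(ssim, mse, psnr_phase) ~ method + value,
                              per_image, mean)
  peak_width <- do.call(rbind, lapply(split(summary, summary$method), function(d) {
    thr <- 0.95 * max(d$ssim)
    ok <- d$value[d$ssim >= thr]
    data.frame(method = d$method[1], lo = min(ok), hi = max(ok),
               n_values = length(ok))
  }))
  rownames(peak_width) <- NULL
  structure(list(per_image = per_image, summary = summary,
                 peak_width = peak_width, axis = axis),
            class = "eval_report")
}

#' Write an evaluation report to CSV/JSON
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "per_image.csv")
  p2 <- file.path(dir, "summary.csv")
  p3 <- file.path(dir, "report.json")
  utils::write.csv(report$per_image, p1, row.names = FALSE)
  utils::write.csv(report$summary, p2, row.names = FALSE)
  jsonlite::write_json(
    list(axis = report$axis, summary = report$summary,
         peak_width = report$peak_width),
    p3, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(c(p1, p2, p3))
}

#' Plot a sweep report
#'
#' Writes a two-panel figure (mean SSIM and MSE versus the sweep value, one
#' line per method) as PNG or SVG, chosen by the file extension.
#'
#' @param report an `eval_report` from [sweep_eval()].
#' @param path output file (`.png` or `.svg`).
#' @param width,height device size in inches.
#' @return Invisibly, `path`.
#' @export
plot_eval_report <- function(report, path, width = 8, height = 4) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100)
  on.exit(grDevices::dev.off())
  s <- report$summary
  methods <- unique(s$method)
  cols <- seq_along(methods)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (metric in c("ssim", "mse")) {
    rng <- range(s[[metric]])
    graphics::plot(NA, xlim = range(s$value), ylim = rng,
                   xlab = report$axis, ylab = toupper(metric))
    for (i in seq_along(methods)) {
      d <- s[s$method == methods[i], ]
      graphics::lines(d$value, d[[metric]], col = cols[i], type = "b", pch = 16)
    }
    graphics::legend("topright", legend = methods, col = cols, lty = 1,
                     pch = 16, cex = 0.8, bty = "n")
  }
  invisible(path)
}
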