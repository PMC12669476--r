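# FPM digital camera: simulates the raw intensity stack captured under each
# LED of a plan. Per LED n the camera sees
#   I_n = | IFT{ P(k) . O_hat(k - k_n) } |^2,
# i.e. the object spectrum shifted by the illumination wavevector, clipped
# by the pupil and propagated to the (lower-resolution) sensor grid.
# Downsampling to the sensor is done by Fourier cropping — the central
# sensor-band window of the object spectrum — which is exactly the forward
# model the Gauss-Newton reconstruction inverts. Spectrum shifts are
# rounded to integer pixels on the object Fourier grid (residuals kept in
# metadata); FFTs are unitary throughout.

#' Simulate the raw FPM intensity stack of a phantom
#'
#' For each LED in the plan, forms the low-resolution complex field by
#' shifting the phantom's spectrum by the LED wavevector, applying the
#' pupil, and inverse transforming on the sensor grid; the recorded frame is
#' the field intensity scaled to `photons_bf` mean brightfield
#' photoelectrons and multiplied by the LED's exposure scale factor, with
#' optional Poisson shot noise, Gaussian read noise and full-well clipping.
#'
#' @param ph a [generate_phantom()] result (or any object with `amplitude`,
#'   `phase`, `pixel_size`).
#' @param sys an [optical_system()].
#' @param plan an LED plan from [build_led_plan()].
#' @param pupil optional [make_pupil()] on the sensor grid; built
#'   aberration-free if `NULL`.
#' @param wavelength nm; defaults to the plan's wavelength.
#' @param downsample_factor integer ratio of object grid to sensor grid.
#' @param photons_bf mean brightfield photoelectrons per sensor pixel for a
#'   transparent sample.
#' @param noise_params list: `shot` (logical), `read_sigma` (electrons),
#'   `full_well` (electrons). `shot = FALSE, read_sigma = 0` gives the
#'   noiseless deterministic forward model.
#' @param seed integer seed for the noise draws.
#' @return object of class `fpm_stack`: `frames` (list of raw sensor
#'   matrices, photoelectrons, plan order), `plan`, `pupil`, `shifts`
#'   (integer spectrum shifts, with sub-pixel residuals in
#'   `shift_residuals`), grid metadata and noise settings.
#' @export
capture_stack <- function(ph, sys, plan, pupil = NULL, wavelength = NULL,
                          downsample_factor = 3, photons_bf = 5000,
                          noise_params = list(shot = TRUE, read_sigma = 2,
                                              full_well = 30000),
                          seed = 1) {
  np <- utils::modifyList(list(shot = TRUE, read_sigma = 2,
                               full_well = 30000), noise_params)
  if (is.null(wavelength)) wavelength <- attr(plan, "wavelength")
  lam_um <- wavelength * 1e-3
  obj <- phantom_field(ph)
  N <- dim(obj)
  ds <- as.integer(downsample_factor)
  if (any(N %% ds != 0))
    stop("object grid must be divisible by `downsample_factor`", call. = FALSE)
  n_lr <- N %/% ds
  p_hr <- ph$pixel_size
  na_syn <- synthetic_na(sys, plan)
  p_req <- lam_um / (2 * na_syn)
  if (p_hr >= p_req)
    stop(sprintf(
      "object pixel %.4f um undersamples the synthetic NA band; need < %.4f um",
      p_hr, p_req), call. = FALSE)
  if (is.null(pupil))
    pupil <- make_pupil(sys, wavelength, n_lr, p_hr * ds)
  # object spectrum, centre-origin order; unitary FFT
  S <- fftshift2(fft2(obj))
  df_y <- 1 / (N[1] * p_hr); df_x <- 1 / (N[2] * p_hr)
  shift_y <- plan$ky / df_y; shift_x <- plan$kx / df_x
  iy <- round(shift_y); ix <- round(shift_x)
  cy <- floor(N[1] / 2) + 1; cx <- floor(N[2] / 2) + 1
  half_y <- floor(n_lr[1] / 2); half_x <- floor(n_lr[2] / 2)
  # note (row, col) = (-y, x): +ky shifts toward lower row index
  rows0 <- cy - half_y; cols0 <- cx - half_x
  if (any(rows0 - abs(iy) < 1) || any(cols0 - abs(ix) < 1))
    stop("LED wavevectors exceed the object Fourier grid", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scale_fac <- prod(n_lr) / prod(N)  # (n/N)^2 for the unitary crop-ifft pair
  frames <- vector("list", nrow(plan))
  saturated <- logical(nrow(plan))
  for (n in seq_len(nrow(plan))) {
    r <- (rows0 - iy[n]):(rows0 - iy[n] + n_lr[1] - 1)
    cc <- (cols0 + ix[n]):(cols0 + ix[n] + n_lr[2] - 1)
    sub <- S[r, cc] * pupil$grid
    field <- ifft2(ifftshift2(sub)) * sqrt(scale_fac)
    inten <- Mod(field)^2 * photons_bf * plan$exposure_scale[n]
    if (isTRUE(np$shot)) inten <- matrix(stats::rpois(length(inten),
                                                      pmin(inten, 1e7)),
                                         n_lr[1], n_lr[2])
    if (np$read_sigma > 0)
      inten <- inten + matrix(stats::rnorm(length(inten), 0, np$read_sigma),
                              n_lr[1], n_lr[2])
    sat <- inten >= np$full_well
    saturated[n] <- any(sat)
    inten[sat] <- np$full_well
    inten[inten < 0] <- 0
    frames[[n]] <- inten
  }
  structure(list(frames = frames, plan = plan, pupil = pupil,
                 wavelength = wavelength, downsample_factor = ds,
                 photons_bf = photons_bf,
                 pixel_size_obj = p_hr, pixel_size_raw = p_hr * ds,
                 object_shape = N, sensor_shape = n_lr,
                 shifts = cbind(iy = iy, ix = ix),
                 shift_residuals = cbind(dy = shift_y - iy, dx = shift_x - ix),
                 noise_params = np, saturated = saturated, seed = seed),
            class = "fpm_stack")
}

#' @export
print.fpm_stack <- function(x, ...) {
  cat(sprintf("<fpm_stack> %d frames of %d x %d px (object %d x %d, ds %d)\n",
              length(x$frames), x$sensor_shape[1], x$sensor_shape[2],
              x$object_shape[1], x$object_shape[2], x$downsample_factor))
  cat(sprintf("  lambda %g nm, %d brightfield LEDs, shot=%s read_sigma=%g\n",
              x$wavelength, sum(x$plan$is_brightfield),
              x$noise_params$shot, x$noise_params$read_sigma))
  invisible(x)
}

#' Linear brightfield-equivalent sum of an FPM stack
#'
#' Rescales all frames to the common brightfield exposure and sums them
#' pixelwise — the low-resolution "raw" image against which the
#' resolution gain of the reconstruction is measured.
#'
#' @param stack an [capture_stack()] result.
#' @return intensity matrix on the sensor grid.
#' @export
brightfield_sum <- function(stack) {
  frames <- rescale_intensity(stack$frames, stack$plan)
  Reduce(`+`, frames)
}

#' Normalised-variance focus score
#'
#' The autofocus figure of merit: var(I) / mean(I)^2 of the summed
#' darkfield-ring image. Invariant to overall intensity scaling; largest
#' when the darkfield scatter image is sharpest.
#'
#' @param frames a single intensity matrix or a list of matrices (summed
#'   before scoring).
#' @return scalar score.
#' @export
autofocus_metric <- function(frames) {
  img <- if (is.list(frames)) Reduce(`+`, frames) else frames
  m <- mean(img)
  if (abs(m) < .Machine$double.eps)
    stop("zero-mean image: focus metric undefined", call. = FALSE)
  stats::var(as.vector(img)) / m^2
}

#' Indices of the innermost fully-darkfield LED ring
#'
#' The default ring used for autofocus: the first complete equal-radius
#' shell of LEDs whose illumination NA exceeds the objective NA.
#'
#' @param plan an LED plan.
#' @return integer vector of row indices into `plan`.
#' @export
darkfield_ring_indices <- function(plan) {
  df <- which(!plan$is_brightfield)
  if (!length(df)) stop("plan has no darkfield LEDs", call. = FALSE)
  d0 <- round(plan$d[df[1]], 9)
  df[round(plan$d[df], 9) == d0]
}

#' Autofocus over a through-focus series
#'
#' Picks the focal position maximising the normalised variance of the
#' darkfield image at each z, with optional parabolic refinement of the
#' peak between grid points.
#'
#' @param frames_by_z list over z positions; each element a darkfield
#'   intensity matrix or list of matrices.
#' @param z numeric vector of focal positions (same length).
#' @param refine logical: parabolically interpolate the peak.
#' @return list with `z_star`, `scores`, and `z_grid_star` (the unrefined
#'   grid argmax).
#' @export
autofocus <- function(frames_by_z, z, refine = TRUE) {
  stopifnot(length(frames_by_z) == length(z))
  scores <- vapply(frames_by_z, autofocus_metric, numeric(1))
  i <- which.max(scores)
  z_star <- z[i]
  if (refine && i > 1 && i < length(z)) {
    y1 <- scores[i - 1]; y2 <- scores[i]; y3 <- scores[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps) {
      delta <- 0.5 * (y1 - y3) / denom
      z_star <- z[i] + delta * (z[i + 1] - z[i])
    }
  }
  list(z_star = z_star, scores = scores, z_grid_star = z[i])
}
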