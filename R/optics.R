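# System geometry and illumination planning for an LED-array Fourier
# ptychographic microscope: synthetic NA, magnification, field of view,
# depth of field, LED selection, pupil models and exposure scheduling.

#' Define an FPM optical system
#'
#' Describes the imaging pathway of an LED-array Fourier ptychographic
#' microscope: a low-NA objective designed for a reference tube-lens focal
#' length, used with an actual tube lens, and a monochrome camera. The
#' default values describe a 4x/0.16 objective (180 mm reference) with a
#' 200 mm tube lens and a large-format sCMOS camera, giving an effective
#' magnification of 4.44.
#'
#' @param na_obj numerical aperture of the objective (0 < NA < 1).
#' @param mag_nominal nominal objective magnification.
#' @param f_tube tube-lens focal length, mm.
#' @param f_reference objective design reference focal length, mm.
#' @param wavelengths named numeric vector of LED central wavelengths, nm.
#' @param pixel_pitch_camera camera pixel pitch, micrometres.
#' @param sensor_shape sensor size in pixels, `c(rows, cols)` = (H, W).
#' @return an object of class `optical_system`.
#' @examples
#' sys <- optical_system()
#' effective_magnification(sys)  # 4.44
#' @export
optical_system <- function(na_obj = 0.16, mag_nominal = 4,
                           f_tube = 200, f_reference = 180,
                           wavelengths = c(red = 629, green = 530, blue = 475),
                           pixel_pitch_camera = 4.25,
                           sensor_shape = c(2960L, 5056L)) {
  if (!is.numeric(na_obj) || na_obj <= 0 || na_obj >= 1)
    stop("`na_obj` must lie in (0, 1)", call. = FALSE)
  if (f_tube <= 0 || f_reference <= 0)
    stop("focal lengths must be positive", call. = FALSE)
  stopifnot_scalar_pos(mag_nominal, "mag_nominal")
  structure(list(na_obj = na_obj, mag_nominal = mag_nominal,
                 f_tube = f_tube, f_reference = f_reference,
                 wavelengths = wavelengths,
                 pixel_pitch_camera = pixel_pitch_camera,
                 sensor_shape = as.integer(sensor_shape)),
            class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat(sprintf("<optical_system> %gx/%.2f, f_tube %g mm (ref %g mm), mag_eff %.3f\n",
              x$mag_nominal, x$na_obj, x$f_tube, x$f_reference,
              effective_magnification(x)))
  cat(sprintf("  wavelengths [nm]: %s\n",
              paste(sprintf("%s=%g", names(x$wavelengths), x$wavelengths),
                    collapse = ", ")))
  cat(sprintf("  sensor: %d x %d px @ %g um\n", x$sensor_shape[1],
              x$sensor_shape[2], x$pixel_pitch_camera))
  invisible(x)
}

#' Define the LED illumination array
#'
#' A planar square-grid LED array placed below the sample. `centering`
#' controls whether one LED sits on the optical axis (`"on_led"`) or the axis
#' passes between the four central LEDs (`"between_leds"`). The on-LED
#' layout reproduces the 177-LED circular selection of the reference
#' geometry (22 x 22 grid, 7 mm pitch, 81 mm below the sample).
#'
#' @param n_rows,n_cols grid size.
#' @param pitch LED spacing, mm.
#' @param height array-to-sample distance, mm.
#' @param centering `"on_led"` or `"between_leds"`.
#' @return object of class `led_array`.
#' @export
led_array <- function(n_rows = 22, n_cols = 22, pitch = 7, height = 81,
                      centering = c("on_led", "between_leds")) {
  centering <- match.arg(centering)
  stopifnot_scalar_pos(pitch, "pitch")
  stopifnot_scalar_pos(height, "height")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pitch = pitch, height = height, centering = centering),
            class = "led_array")
}

led_grid_offsets <- function(arr) {
  # integer grid offsets from the optical axis, in LED-pitch units
  off <- function(n) {
    if (arr$centering == "on_led") seq_len(n) - 1 - floor(n / 2)
    else seq_len(n) - 1 - (n - 1) / 2
  }
  list(i = off(arr$n_rows), j = off(arr$n_cols))
}

#' Build an ordered LED illumination plan
#'
#' Selects the LEDs closest to the optical axis according to either a target
#' LED count or a ceiling on illumination NA, and computes for each LED its
#' radial distance, illumination wavevector, brightfield/darkfield label and
#' exposure scale factor. LEDs at equal radial distance form indivisible
#' shells: a count criterion that falls inside a shell is rounded to the
#' nearest attainable count with a warning.
#'
#' Illumination geometry: an LED at in-plane position (x, y) and height h
#' below the sample illuminates at sin(theta) = d / sqrt(d^2 + h^2) with
#' d = sqrt(x^2 + y^2); its spatial-frequency offset is
#' (kx, ky) = (sin(theta_x), sin(theta_y)) / lambda in cycles per micrometre.
#' A brightfield LED is one whose illumination NA does not exceed the
#' objective NA. Darkfield exposure scale factors grow as (d / d_bf_edge)^2,
#' where d_bf_edge is the radius at which the illumination NA equals the
#' objective NA, and are clamped to be at least 1.
#'
#' @param arr an [led_array()].
#' @param sys an [optical_system()].
#' @param n_leds target number of LEDs (mutually exclusive with
#'   `max_illum_na`).
#' @param max_illum_na ceiling on illumination NA.
#' @param wavelength wavelength (nm) used for the wavevectors; defaults to
#'   the system's green channel.
#' @return a `data.frame` of class `led_plan`, ordered by increasing radial
#'   distance, with columns `x`, `y` (mm), `d` (mm), `sin_theta_x`,
#'   `sin_theta_y`, `illum_na`, `kx`, `ky` (cycles/um), `is_brightfield`,
#'   `exposure_scale`.
#' @examples
#' plan <- build_led_plan(led_array(), optical_system(), max_illum_na = 0.54)
#' nrow(plan)           # 177
#' @export
build_led_plan <- function(arr, sys, n_leds = NULL, max_illum_na = NULL,
                           wavelength = NULL) {
  if (is.null(n_leds) == is.null(max_illum_na))
    stop("give exactly one of `n_leds` or `max_illum_na`", call. = FALSE)
  if (is.null(wavelength))
    wavelength <- if ("green" %in% names(sys$wavelengths))
      sys$wavelengths[["green"]] else sys$wavelengths[[1]]
  off <- led_grid_offsets(arr)
  g <- expand.grid(i = off$i, j = off$j)
  x <- g$j * arr$pitch
  y <- g$i * arr$pitch
  d <- sqrt(x^2 + y^2)
  h <- arr$height
  hyp <- sqrt(d^2 + h^2)
  illum_na <- d / hyp

  ord <- order(d, atan2(y, x))
  x <- x[ord]; y <- y[ord]; d <- d[ord]
  hyp <- hyp[ord]; illum_na <- illum_na[ord]

  if (!is.null(max_illum_na)) {
    keep <- illum_na <= max_illum_na + 1e-12
    if (!any(keep)) stop("no LED satisfies `max_illum_na`", call. = FALSE)
    n_sel <- sum(keep)
  } else {
    n_leds <- as.integer(n_leds)
    if (n_leds < 1 || n_leds > length(d))
      stop("`n_leds` exceeds the LED array extent", call. = FALSE)
    # complete radius shells: shrink/grow to the nearest shell boundary
    dr <- round(d, 9)
    shell_end <- cumsum(table(factor(dr, levels = unique(dr))))
    cand <- as.numeric(shell_end)
    n_sel <- cand[which.min(abs(cand - n_leds))]
    if (n_sel != n_leds)
      warning(sprintf(
        "requested %d LEDs falls inside an equal-radius shell; using %d",
        n_leds, n_sel))
  }
  idx <- seq_len(n_sel)
  lam_um <- wavelength * 1e-3
  d_bf_edge <- h * sys$na_obj / sqrt(1 - sys$na_obj^2)
  is_bf <- illum_na[idx] <= sys$na_obj + 1e-12
  exposure_scale <- pmax(1, (d[idx] / d_bf_edge)^2)
  exposure_scale[is_bf] <- 1
  plan <- data.frame(
    x = x[idx], y = y[idx], d = d[idx],
    sin_theta_x = x[idx] / hyp[idx], sin_theta_y = y[idx] / hyp[idx],
    illum_na = illum_na[idx],
    kx = x[idx] / hyp[idx] / lam_um, ky = y[idx] / hyp[idx] / lam_um,
    is_brightfield = is_bf,
    exposure_scale = exposure_scale)
  attr(plan, "wavelength") <- wavelength
  attr(plan, "height") <- h
  class(plan) <- c("led_plan", "data.frame")
  plan
}

#' Effective magnification of the imaging pathway
#'
#' The objective's nominal magnification rescaled by the ratio of the actual
#' to the design tube-lens focal length.
#'
#' @param sys an [optical_system()].
#' @return dimensionless magnification.
#' @examples
#' effective_magnification(optical_system())  # 4 * 200 / 180 = 4.44
#' @export
effective_magnification <- function(sys) {
  if (sys$f_tube <= 0 || sys$f_reference <= 0)
    stop("focal lengths must be positive", call. = FALSE)
  sys$mag_nominal * sys$f_tube / sys$f_reference
}

#' Synthetic numerical aperture of an FPM acquisition
#'
#' NA_syn = NA_obj + sin(theta_max), where theta_max is the illumination
#' angle of the outermost LED in the plan. This sets the band limit of the
#' reconstructed complex field.
#'
#' @param sys an [optical_system()].
#' @param plan an [build_led_plan()] result.
#' @return dimensionless synthetic NA.
#' @export
synthetic_na <- function(sys, plan) {
  if (nrow(plan) == 0) stop("empty LED plan", call. = FALSE)
  sys$na_obj + max(plan$illum_na)
}

#' Depth of field of the objective
#'
#' Diffraction-limited depth of field lambda / NA^2 (no refractive-index
#' term). For a 0.16-NA objective at 530 nm this is about 20 micrometres.
#'
#' @param sys an [optical_system()].
#' @param wavelength wavelength in nm (default: green channel).
#' @return depth of field in micrometres.
#' @export
depth_of_field <- function(sys, wavelength = NULL) {
  if (is.null(wavelength))
    wavelength <- if ("green" %in% names(sys$wavelengths))
      sys$wavelengths[["green"]] else sys$wavelengths[[1]]
  (wavelength * 1e-3) / sys$na_obj^2
}

#' Field of view at the sample plane
#'
#' Sensor extent divided by the effective magnification, per axis.
#'
#' @param sys an [optical_system()].
#' @return named numeric `c(x = , y = )` in mm (x = sensor columns).
#' @export
field_of_view <- function(sys) {
  mag <- effective_magnification(sys)
  px_mm <- sys$pixel_pitch_camera * 1e-3
  c(x = sys$sensor_shape[2] * px_mm / mag,
    y = sys$sensor_shape[1] * px_mm / mag)
}

zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s <- 0:((n - m) / 2)
  out <- 0
  for (k in s) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

zernike_phase <- function(kr, ktheta, cutoff, coeffs) {
  # coeffs: named vector, names "Zn,m" (e.g. "Z2,2" astigmatism), radians
  phi <- kr * 0
  rho <- pmin(kr / cutoff, 1)
  for (nm in names(coeffs)) {
    p <- as.numeric(strsplit(sub("^Z", "", nm), ",")[[1]])
    n <- p[1]; m <- p[2]
    ang <- if (m >= 0) cos(m * ktheta) else sin(-m * ktheta)
    phi <- phi + coeffs[[nm]] * zernike_radial(n, m, rho) * ang
  }
  phi
}

#' Build a pupil function
#'
#' Circular coherent pupil of radius NA_obj / lambda on a centred frequency
#' grid, with optional defocus and Zernike aberrations. Defocus over a
#' distance z multiplies the pupil by
#' exp(i * 2*pi/lambda * z * sqrt(1 - lambda^2 k^2)).
#'
#' @param sys an [optical_system()].
#' @param wavelength nm.
#' @param grid_shape `c(rows, cols)` of the (low-resolution) frequency grid.
#' @param pixel_size sample-plane pixel size of that grid, micrometres.
#' @param defocus defocus distance z, micrometres.
#' @param zernike named numeric vector of Zernike phase coefficients in
#'   radians, names `"Zn,m"` (e.g. `c("Z2,2" = 0.5)` for astigmatism), on
#'   the unit disk rho = k / cutoff.
#' @return object of class `pupil`: list with complex `grid` (centre-origin
#'   order), `cutoff` (cycles/um), `kr`, `wavelength`, `defocus`.
#' @export
make_pupil <- function(sys, wavelength, grid_shape, pixel_size,
                       defocus = 0, zernike = NULL) {
  lam_um <- wavelength * 1e-3
  cutoff <- sys$na_obj / lam_um
  nyq <- 1 / (2 * pixel_size)
  if (cutoff > nyq)
    stop(sprintf(
      "pupil cutoff %.3f cycles/um exceeds grid Nyquist %.3f; need pixel < %.3f um",
      cutoff, nyq, 1 / (2 * cutoff)), call. = FALSE)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  fy <- freq_axis(nr, pixel_size)
  fx <- freq_axis(nc, pixel_size)
  kr <- sqrt(outer(fy^2, fx^2, `+`))
  ktheta <- atan2(outer(fy, rep(1, nc)), outer(rep(1, nr), fx))
  inside <- kr <= cutoff
  phase <- matrix(0, nr, nc)
  if (defocus != 0) {
    arg <- pmax(1 - (lam_um * kr)^2, 0)
    phase <- phase + 2 * pi / lam_um * defocus * sqrt(arg)
  }
  if (!is.null(zernike) && length(zernike))
    phase <- phase + zernike_phase(kr, ktheta, cutoff, zernike)
  grid <- ifelse(inside, 1, 0) * exp(1i * phase)
  structure(list(grid = grid, cutoff = cutoff, kr = kr,
                 wavelength = wavelength, pixel_size = pixel_size,
                 defocus = defocus, zernike = zernike),
            class = "pupil")
}

#' Per-LED exposure schedule
#'
#' Brightfield LEDs are exposed for the base brightfield time `t_bf`;
#' darkfield exposures grow with the squared radial distance of the LED so
#' that weak darkfield signals are captured with adequate signal-to-noise.
#'
#' @param plan an LED plan from [build_led_plan()].
#' @param t_bf brightfield exposure time, ms.
#' @return numeric vector of per-LED exposures, ms.
#' @export
exposure_schedule <- function(plan, t_bf) {
  stopifnot_scalar_pos(t_bf, "t_bf")
  plan$exposure_scale * t_bf
}

#' Rescale raw frames to a common (brightfield) exposure
#'
#' Inverts the exposure schedule: each raw frame is divided by its exposure
#' scale factor T_n / T_BF, so all frames are expressed on the brightfield
#' exposure scale.
#'
#' @param frames list of intensity matrices (one per LED, plan order).
#' @param plan the LED plan used for capture.
#' @return list of rescaled frames.
#' @export
rescale_intensity <- function(frames, plan) {
  if (length(frames) != nrow(plan))
    stop("frame count does not match plan", call. = FALSE)
  Map(function(f, s) f / s, frames, plan$exposure_scale)
}
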