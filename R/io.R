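# Disk formats: FPM stacks as multi-page 32-bit TIFF with a JSON metadata
# sidecar; phantoms and complex fields as 32-bit TIFF pairs with
# provenance sidecars. TIFF payloads are stored min-max normalised (the
# TIFF writer clips to [0,1]); the offset/scale needed to restore physical
# values lives in the sidecar.

norm_for_tiff <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) list(img = x * 0, offset = r[1], scale = 1)
  else list(img = (x - r[1]) / (r[2] - r[1]), offset = r[1],
            scale = r[2] - r[1])
}

#' Write an FPM stack to TIFF + JSON sidecar
#'
#' Frames go to a multi-page 32-bit float TIFF (jointly normalised so
#' relative intensities across frames are preserved); the LED plan,
#' exposure scales, grid geometry, noise settings and normalisation go to
#' a JSON sidecar next to it.
#'
#' @param stack an [capture_stack()] result.
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fpm_stack <- function(stack, path) {
  mx <- max(vapply(stack$frames, max, numeric(1)))
  frames <- lapply(stack$frames, function(f) f / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    scale = mx,
    wavelength = stack$wavelength,
    downsample_factor = stack$downsample_factor,
    photons_bf = stack$photons_bf,
    pixel_size_obj = stack$pixel_size_obj,
    pixel_size_raw = stack$pixel_size_raw,
    object_shape = stack$object_shape,
    sensor_shape = stack$sensor_shape,
    noise_params = stack$noise_params,
    seed = stack$seed,
    saturated = stack$saturated,
    shifts = stack$shifts,
    shift_residuals = stack$shift_residuals,
    plan = as.data.frame(unclass(stack$plan)),
    plan_wavelength = attr(stack$plan, "wavelength"),
    plan_height = attr(stack$plan, "height"),
    pupil = list(cutoff = stack$pupil$cutoff,
                 wavelength = stack$pupil$wavelength,
                 pixel_size = stack$pupil$pixel_size,
                 defocus = stack$pupil$defocus,
                 zernike = stack$pupil$zernike))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an FPM stack written by [write_fpm_stack()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return an `fpm_stack` object.
#' @export
read_fpm_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(frames, function(f) {
    f <- f * meta$scale; dimnames(f) <- NULL; f
  })
  shifts <- as.matrix(meta$shifts)
  dimnames(shifts) <- list(NULL, c("iy", "ix"))
  shift_res <- as.matrix(meta$shift_residuals)
  dimnames(shift_res) <- list(NULL, c("dy", "dx"))
  plan <- meta$plan
  attr(plan, "wavelength") <- meta$plan_wavelength
  attr(plan, "height") <- meta$plan_height
  class(plan) <- c("led_plan", "data.frame")
  sys_tmp <- optical_system(na_obj = meta$pupil$cutoff *
                              meta$pupil$wavelength * 1e-3)
  pupil <- make_pupil(sys_tmp, meta$pupil$wavelength, meta$sensor_shape,
                      meta$pupil$pixel_size, defocus = meta$pupil$defocus,
                      zernike = unlist(meta$pupil$zernike))
  structure(list(frames = frames, plan = plan, pupil = pupil,
                 wavelength = meta$wavelength,
                 downsample_factor = meta$downsample_factor,
                 photons_bf = meta$photons_bf,
                 pixel_size_obj = meta$pixel_size_obj,
                 pixel_size_raw = meta$pixel_size_raw,
                 object_shape = meta$object_shape,
                 sensor_shape = meta$sensor_shape,
                 shifts = shifts,
                 shift_residuals = shift_res,
                 noise_params = meta$noise_params,
                 saturated = meta$saturated, seed = meta$seed),
            class = "fpm_stack")
}

#' Write a complex field as amplitude/phase TIFF pair
#'
#' @param cf a [complex_field()].
#' @param prefix file prefix; writes `<prefix>_amplitude.tif`,
#'   `<prefix>_phase.tif` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_complex_field <- function(cf, prefix) {
  na <- norm_for_tiff(cf$amplitude)
  np <- norm_for_tiff(cf$phase)
  tiff::writeTIFF(na$img, paste0(prefix, "_amplitude.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(np$img, paste0(prefix, "_phase.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size = cf$pixel_size, na_limit = cf$na_limit,
         amplitude = na[c("offset", "scale")],
         phase = np[c("offset", "scale")],
         provenance = cf$provenance),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a complex field written by [write_complex_field()]
#' @param prefix file prefix used when writing.
#' @return a `complex_field`.
#' @export
read_complex_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  amp <- tiff::readTIFF(paste0(prefix, "_amplitude.tif")) *
    meta$amplitude$scale + meta$amplitude$offset
  phs <- tiff::readTIFF(paste0(prefix, "_phase.tif")) *
    meta$phase$scale + meta$phase$offset
  complex_field(amp * exp(1i * phs), meta$pixel_size, meta$na_limit,
                provenance = meta$provenance)
}

#' Write a phantom (and optionally its stained rendering) to a directory
#'
#' @param ph a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @param stained optional [render_hne()] result.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir, stained = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(ph$amplitude, file.path(dir, "amplitude.tif"),
                  bits.per.sample = 32L)
  np <- norm_for_tiff(ph$phase)
  tiff::writeTIFF(np$img, file.path(dir, "phase.tif"), bits.per.sample = 32L)
  if (!is.null(stained)) {
    tiff::writeTIFF(stained$rgb, file.path(dir, "hne_rgb.tif"),
                    bits.per.sample = 8L)
    ns <- norm_for_tiff(stained$phase_stained)
    tiff::writeTIFF(ns$img, file.path(dir, "phase_stained.tif"),
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(
    list(pixel_size = ph$pixel_size, seed = ph$seed, params = ph$params,
         phase = np[c("offset", "scale")]),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a YAML system/LED configuration
#'
#' Builds an [optical_system()] and [led_array()] (and, when `led$n_leds`
#' or `led$max_illum_na` is present, an LED plan) from a YAML block with
#' keys `na_obj`, `mag_nominal`, `f_tube_mm`, `f_reference_mm`,
#' `wavelengths_nm`, `pixel_pitch_um`, `sensor_shape`, and `led:` (`rows`,
#' `cols`, `pitch_mm`, `height_mm`, `centering`, `n_leds`/`max_illum_na`).
#' Missing keys fall back to the reference-geometry defaults.
#'
#' @param path YAML file.
#' @return list with `sys`, `arr`, and `plan` (possibly `NULL`).
#' @export
read_config <- function(path) {
  cfgy <- yaml::read_yaml(path)
  wl <- unlist(cfgy$wavelengths_nm %||% c(red = 629, green = 530, blue = 475))
  sys <- optical_system(
    na_obj = cfgy$na_obj %||% 0.16,
    mag_nominal = cfgy$mag_nominal %||% 4,
    f_tube = cfgy$f_tube_mm %||% 200,
    f_reference = cfgy$f_reference_mm %||% 180,
    wavelengths = wl,
    pixel_pitch_camera = cfgy$pixel_pitch_um %||% 4.25,
    sensor_shape = unlist(cfgy$sensor_shape %||% c(2960L, 5056L)))
  led <- cfgy$led %||% list()
  arr <- led_array(n_rows = led$rows %||% 22, n_cols = led$cols %||% 22,
                   pitch = led$pitch_mm %||% 7,
                   height = led$height_mm %||% 81,
                   centering = led$centering %||% "on_led")
  plan <- NULL
  if (!is.null(led$n_leds)) plan <- build_led_plan(arr, sys, n_leds = led$n_leds)
  else if (!is.null(led$max_illum_na))
    plan <- build_led_plan(arr, sys, max_illum_na = led$max_illum_na)
  list(sys = sys, arr = arr, plan = plan)
}
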