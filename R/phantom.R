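# Seeded synthetic tissue phantoms: thin-section complex transmission
# (amplitude + phase) with crypt-like annular structures lined by
# ellipsoidal nuclei, plus a Beer-Lambert H&E rendering of the same section
# and geometric misalignment fixtures for registration tests.
#
# Nuclei are assigned a LOWER phase than the surrounding cytoplasm,
# reflecting the lower refractive index of the cell nucleus relative to the
# cytoplasm in real tissue, which is what makes nuclei stand out in
# quantitative phase images of unstained sections.

band_limited_noise <- function(nr, nc, sigma_px) {
  gauss_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma_px)
}

draw_ellipse <- function(mask, cy, cx, ry, rx, theta) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1, floor(cy - ry - rx)); r1 <- min(nr, ceiling(cy + ry + rx))
  c0 <- max(1, floor(cx - ry - rx)); c1 <- min(nc, ceiling(cx + ry + rx))
  if (r0 > r1 || c0 > c1) return(mask)
  yy <- outer((r0:r1) - cy, rep(1, c1 - c0 + 1))
  xx <- outer(rep(1, r1 - r0 + 1), (c0:c1) - cx)
  xr <- xx * cos(theta) + yy * sin(theta)
  yr <- -xx * sin(theta) + yy * cos(theta)
  inside <- (xr / rx)^2 + (yr / ry)^2 <= 1
  mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | inside
  mask
}

#' Generate a synthetic tissue-section phantom
#'
#' Builds a seeded, reproducible thin-section phantom: a tissue blob with
#' band-limited stromal texture, `n_crypts` crypt-like annular structures
#' whose rims are lined with ellipsoidal nuclei, and scattered stromal
#' nuclei. The complex transmission has amplitude near 1 (weakly absorbing)
#' and phase up to `phase_scale` radians, with nuclei at lower phase than
#' cytoplasm. Background (outside the tissue mask) has amplitude exactly 1
#' and phase exactly 0.
#'
#' @param shape image size `c(rows, cols)`, at least 64 x 64.
#' @param pixel_size sample-plane pixel size, micrometres.
#' @param n_crypts number of crypt structures.
#' @param nucleus_density expected stromal nuclei per 10,000 px of tissue.
#' @param phase_scale peak cytoplasm phase, radians. The default 1.5 rad
#'   keeps the section within the thin-object regime of the capture model.
#' @param texture_params list: `sigma_coarse`, `sigma_fine` (blur scales in
#'   px of the stromal texture), `fine_weight` (relative weight of the fine
#'   component).
#' @param seed integer seed; the phantom is a pure function of
#'   (seed, parameters).
#' @return object of class `tissue_phantom`: list with `amplitude`, `phase`
#'   (matrices), `nucleus_mask`, `tissue_mask` (logical matrices),
#'   `pixel_size`, `seed`, `params`.
#' @examples
#' ph <- generate_phantom(shape = c(128, 128), seed = 1)
#' mean(ph$phase[ph$nucleus_mask]) < mean(ph$phase[ph$tissue_mask & !ph$nucleus_mask])
#' @export
generate_phantom <- function(shape = c(256, 256), pixel_size = 0.319,
                             n_crypts = 3, nucleus_density = 6,
                             phase_scale = 1.5,
                             texture_params = list(sigma_coarse = 6,
                                                   sigma_fine = 0.8,
                                                   fine_weight = 0.35),
                             seed = 1) {
  if (any(shape < 64)) stop("shape must be at least 64 x 64", call. = FALSE)
  stopifnot_scalar_pos(phase_scale, "phase_scale")
  nr <- shape[1]; nc <- shape[2]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # tissue blob: smooth noise thresholded to cover most of the field
  blob <- band_limited_noise(nr, nc, max(nr, nc) / 10)
  tissue_mask <- blob > stats::quantile(blob, 0.12)

  nucleus_mask <- matrix(FALSE, nr, nc)
  crypt_lumen <- matrix(FALSE, nr, nc)
  min_dim <- min(nr, nc)
  r_outer <- min_dim / 10
  nuc_r <- max(2.2, min_dim / 110)

  place_crypts <- function() {
    centres <- matrix(NA_real_, 0, 2)
    for (i in seq_len(n_crypts)) {
      ok <- FALSE
      for (try in 1:30) {
        cy <- stats::runif(1, r_outer + 4, nr - r_outer - 4)
        cx <- stats::runif(1, r_outer + 4, nc - r_outer - 4)
        if (nrow(centres) == 0 ||
            all(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2) >
                2.2 * r_outer)) { ok <- TRUE; break }
      }
      if (!ok) return(NULL)
      centres <- rbind(centres, c(cy, cx))
    }
    centres
  }
  centres <- NULL
  if (n_crypts > 0) {
    centres <- place_crypts()
    if (is.null(centres)) {
      warning("crypt placement degenerate; retrying layout")
      centres <- place_crypts()
      if (is.null(centres))
        stop("could not place non-overlapping crypts; reduce n_crypts",
             call. = FALSE)
    }
    for (i in seq_len(nrow(centres))) {
      cy <- centres[i, 1]; cx <- centres[i, 2]
      crypt_lumen <- draw_ellipse(crypt_lumen, cy, cx,
                                  0.45 * r_outer, 0.45 * r_outer, 0)
      # ellipsoidal nuclei lining the rim, long axis tangential
      n_rim <- max(8, round(2 * pi * 0.72 * r_outer / (2.4 * nuc_r)))
      ang <- seq(0, 2 * pi, length.out = n_rim + 1)[-1] +
        stats::runif(1, 0, 2 * pi)
      for (a in ang) {
        ny <- cy + 0.72 * r_outer * sin(a)
        nx <- cx + 0.72 * r_outer * cos(a)
        nucleus_mask <- draw_ellipse(nucleus_mask, ny, nx,
                                     1.6 * nuc_r, 0.9 * nuc_r, a + pi / 2)
      }
    }
  }

  # scattered stromal nuclei
  if (nucleus_density > 0) {
    n_stromal <- stats::rpois(1, nucleus_density * sum(tissue_mask) / 1e4)
    if (n_stromal > 0) {
      ys <- stats::runif(n_stromal, 3, nr - 3)
      xs <- stats::runif(n_stromal, 3, nc - 3)
      ths <- stats::runif(n_stromal, 0, pi)
      for (i in seq_len(n_stromal)) {
        if (!tissue_mask[round(ys[i]), round(xs[i])]) next
        if (crypt_lumen[round(ys[i]), round(xs[i])]) next
        nucleus_mask <- draw_ellipse(nucleus_mask, ys[i], xs[i],
                                     1.3 * nuc_r, 0.85 * nuc_r, ths[i])
      }
    }
  }
  nucleus_mask <- nucleus_mask & tissue_mask & !crypt_lumen

  # phase: cytoplasm texture, nuclei at lower phase, lumen near background
  tp <- utils::modifyList(list(sigma_coarse = 6, sigma_fine = 0.8,
                               fine_weight = 0.35), texture_params)
  tex <- band_limited_noise(nr, nc, tp$sigma_coarse)
  tex <- minmax01(tex)
  fine <- band_limited_noise(nr, nc, tp$sigma_fine)
  fine <- (fine - mean(fine)) / (stats::sd(fine) + 1e-12)
  cyto <- phase_scale * (0.55 + 0.35 * tex + 0.10 * tp$fine_weight * fine)
  phase <- ifelse(tissue_mask, cyto, 0)
  phase[crypt_lumen & tissue_mask] <- 0.12 * phase_scale
  phase[nucleus_mask] <- 0.55 * phase[nucleus_mask]
  # soften mask edges slightly so the section is not binary-edged
  phase <- gauss_blur(phase, 0.7)
  phase[!tissue_mask] <- 0

  amplitude <- ifelse(tissue_mask, 0.92 + 0.05 * tex, 1)
  amplitude[nucleus_mask] <- amplitude[nucleus_mask] - 0.04
  amplitude <- pmin(pmax(gauss_blur(amplitude, 0.7), 0), 1)
  amplitude[!tissue_mask] <- 1

  structure(list(amplitude = amplitude, phase = phase,
                 nucleus_mask = nucleus_mask, tissue_mask = tissue_mask,
                 crypt_lumen = crypt_lumen,
                 pixel_size = pixel_size, seed = seed,
                 params = list(shape = shape, n_crypts = n_crypts,
                               nucleus_density = nucleus_density,
                               phase_scale = phase_scale,
                               texture_params = tp)),
            class = "tissue_phantom")
}

# save/restore the global RNG state so generators are pure functions of seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %d x %d px @ %.3f um, seed %d\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size, x$seed))
  cat(sprintf("  tissue %.0f%%, nuclei %.1f%%, peak phase %.2f rad\n",
              100 * mean(x$tissue_mask), 100 * mean(x$nucleus_mask),
              max(x$phase)))
  invisible(x)
}

#' Complex transmission of a phantom
#' @param ph a [generate_phantom()] result.
#' @return complex matrix `amplitude * exp(1i * phase)`.
#' @export
phantom_field <- function(ph) ph$amplitude * exp(1i * ph$phase)

# Ruifrok-Johnston style H&E absorbance unit vectors (RGB order)
HEMATOXYLIN_RGB <- c(0.650, 0.704, 0.286)
EOSIN_RGB <- c(0.072, 0.990, 0.105)

#' Render a chemically stained counterpart of a phantom
#'
#' Beer-Lambert staining model: optical density per RGB channel is the sum
#' of a hematoxylin term on the (slightly blurred) nucleus mask and an eosin
#' term on the remaining tissue, using standard H&E absorbance unit vectors;
#' transmitted intensity is `exp(-OD)`. The post-staining phase image is a
#' blurred, contrast-reduced copy of the unstained phase, emulating the loss
#' of fine phase detail observed after chemical staining.
#'
#' @param ph a [generate_phantom()] result.
#' @param stain_params list: `c_hematoxylin`, `c_eosin` (stain
#'   concentrations, OD units), `phase_blur_sigma` (px, default 2) and
#'   `phase_contrast` (default 0.6) for the stained-phase model.
#' @return object of class `stained_phantom`: `rgb` (rows x cols x 3 array
#'   in `[0,1]`), `phase_stained`, `provenance`.
#' @export
render_hne <- function(ph, stain_params = list()) {
  sp <- utils::modifyList(list(c_hematoxylin = 0.9, c_eosin = 0.45,
                               phase_blur_sigma = 2, phase_contrast = 0.6),
                          stain_params)
  nr <- nrow(ph$phase); nc <- ncol(ph$phase)
  h_conc <- gauss_blur(ifelse(ph$nucleus_mask, 1, 0), 0.8) * sp$c_hematoxylin
  cyto <- ph$tissue_mask & !ph$nucleus_mask & !ph$crypt_lumen
  e_conc <- gauss_blur(ifelse(cyto, 1, 0), 0.8) * sp$c_eosin
  # modulate by local phase so stain uptake tracks tissue density
  dens <- minmax01(ph$phase)
  h_conc <- h_conc * (0.7 + 0.3 * dens)
  e_conc <- e_conc * (0.6 + 0.4 * dens)
  h_conc[!ph$tissue_mask] <- 0
  e_conc[!ph$tissue_mask] <- 0
  rgb <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    od <- h_conc * HEMATOXYLIN_RGB[ch] + e_conc * EOSIN_RGB[ch]
    rgb[, , ch] <- exp(-od)
  }
  phase_stained <- gauss_blur(ph$phase, sp$phase_blur_sigma) * sp$phase_contrast
  structure(list(rgb = rgb, phase_stained = phase_stained,
                 provenance = list(seed = ph$seed, stain_params = sp)),
            class = "stained_phantom")
}

#' Misalign an image by a known transform
#'
#' Registration test fixture: warps an image by a supplied (or randomly
#' drawn) perspective homography and/or Brown-Conrady distortion, returning
#' both the warped image and the exact ground-truth transform so recovery
#' accuracy can be measured.
#'
#' @param img matrix or 3-d array.
#' @param homography 3x3 matrix (moving -> fixed), or `NULL`.
#' @param distortion_params list with `k1`, `k2`, `p1`, `p2`, or `NULL`.
#' @param fill fill value outside the source.
#' @return list with `image` (warped), `homography`, `distortion_params`.
#' @export
misalign <- function(img, homography = NULL, distortion_params = NULL,
                     fill = 0) {
  out <- img
  if (!is.null(homography)) {
    if (abs(det(homography)) < 1e-12)
      stop("homography is not invertible", call. = FALSE)
    out <- warp_perspective(out, homography, fill = fill)
  }
  if (!is.null(distortion_params)) {
    dp <- utils::modifyList(list(k1 = 0, k2 = 0, p1 = 0, p2 = 0),
                            distortion_params)
    out <- distort_brown_conrady(out, dp$k1, dp$k2, dp$p1, dp$p2)
    distortion_params <- dp
  }
  list(image = out, homography = homography,
       distortion_params = distortion_params)
}

#' Draw a small random perspective homography
#'
#' Identity plus a translation, small rotation/scale, and corner
#' perturbations; useful for registration round-trip tests.
#'
#' @param shape image size `c(rows, cols)`.
#' @param max_shift max translation, px.
#' @param max_rot max rotation, radians.
#' @param max_persp max perspective term (dimensionless).
#' @param seed integer seed.
#' @return 3x3 homography.
#' @export
random_homography <- function(shape, max_shift = 6, max_rot = 0.02,
                              max_persp = 2e-5, seed = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  th <- stats::runif(1, -max_rot, max_rot)
  s <- 1 + stats::runif(1, -0.01, 0.01)
  tx <- stats::runif(1, -max_shift, max_shift)
  ty <- stats::runif(1, -max_shift, max_shift)
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  # rotate/scale about the image centre, then translate
  A <- s * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t0 <- c(cx, cy) - A %*% c(cx, cy) + c(tx, ty)
  H <- rbind(cbind(A, t0),
             c(stats::runif(2, -max_persp, max_persp), 1))
  H
}
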