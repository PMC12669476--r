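# Inverse problem: sequential Gauss-Newton phase retrieval recovering the
# complex object (and optionally the pupil) from an FPM intensity stack,
# plus the post-processing chain applied to reconstructed patches: digital
# refocusing, phase flattening, amplitude histogram matching, stitching and
# lens-distortion correction.

#' Reconstruction configuration
#'
#' @param patch_size_raw raw-sensor patch size in pixels (full-scale
#'   processing uses 243; simulations use whatever the stack provides).
#' @param upsample integer upsampling factor from sensor to object grid;
#'   must give an output Nyquist covering the synthetic NA.
#' @param n_iters epochs over the LED sequence.
#' @param gn_alpha,gn_beta Gauss-Newton regularisers, as fractions of
#'   max|P|^2 and max|O|^2.
#' @param pupil_recovery jointly update the pupil estimate.
#' @param blur_kernel_px kernel size for [phase_flatten()].
#' @param overlap_frac patch overlap fraction for patchwise processing.
#' @return list of class `recon_config`.
#' @export
recon_config <- function(patch_size_raw = 243, upsample = 3, n_iters = 10,
                         gn_alpha = 1e-3, gn_beta = 1e-3,
                         pupil_recovery = FALSE, blur_kernel_px = 31,
                         overlap_frac = 0.25) {
  if (patch_size_raw < 64) stop("patch_size_raw must be >= 64", call. = FALSE)
  structure(list(patch_size_raw = patch_size_raw, upsample = as.integer(upsample),
                 n_iters = n_iters, gn_alpha = gn_alpha, gn_beta = gn_beta,
                 pupil_recovery = pupil_recovery,
                 blur_kernel_px = blur_kernel_px,
                 overlap_frac = overlap_frac),
            class = "recon_config")
}

#' Make a complex-field result object
#' @param field complex matrix.
#' @param pixel_size micrometres.
#' @param na_limit band limit of validity (NA units).
#' @param provenance free-form list.
#' @return object of class `complex_field` with `amplitude`, `phase`
#'   (radians, (-pi, pi]) and the above metadata.
#' @export
complex_field <- function(field, pixel_size, na_limit, provenance = list()) {
  structure(list(amplitude = Mod(field), phase = Arg(field),
                 pixel_size = pixel_size, na_limit = na_limit,
                 provenance = provenance),
            class = "complex_field")
}

#' Complex matrix of a `complex_field`
#' @param cf a [complex_field()].
#' @return complex matrix `amplitude * exp(1i * phase)`.
#' @export
cf_complex <- function(cf) cf$amplitude * exp(1i * cf$phase)

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px @ %.3f um, NA limit %.2f\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_size, x$na_limit))
  invisible(x)
}

#' Sequential Gauss-Newton FPM reconstruction
#'
#' Recovers the high-resolution complex object from the intensity stack by
#' sequential per-LED second-order updates. For each LED the low-resolution
#' field is forward-modelled from the current object spectrum and pupil, its
#' modulus is replaced by the square root of the measured intensity (phase
#' kept), and the residual is back-propagated into the object spectrum —
#' and, when `cfg$pupil_recovery` is on, into the pupil — with regularised
#' magnitude-adaptive Gauss-Newton step sizes
#' |P| conj(P) / (max|P| (|P|^2 + alpha max|P|^2)), and symmetrically in
#' the object for the pupil update (for the ideal unit-modulus pupil the
#' object step reduces to conj(P) dk). LEDs are visited in order of increasing
#' |k_n| (the plan order); `cfg$n_iters` epochs are run. The data misfit
#' sum((sqrt(I_model) - sqrt(I_obs))^2) is recorded per epoch; if it rises
#' for 3 consecutive epochs the solver warns and returns the best iterate.
#'
#' @param stack an [capture_stack()] result (or a stack read from disk).
#' @param cfg a [recon_config()]; `cfg$upsample` must equal the stack's
#'   `downsample_factor`.
#' @return a [complex_field()] with `na_limit` set to the synthetic NA, and
#'   attributes: `misfit` (per-epoch), `pupil` (recovered or input pupil
#'   grid).
#' @export
gauss_newton_reconstruct <- function(stack, cfg = recon_config()) {
  if (length(stack$frames) != nrow(stack$plan))
    stop("frame count does not match the LED plan", call. = FALSE)
  if (cfg$upsample != stack$downsample_factor)
    stop("cfg$upsample must match the stack's downsample_factor", call. = FALSE)
  plan <- stack$plan
  N <- stack$object_shape; n_lr <- stack$sensor_shape
  sf <- prod(n_lr) / prod(N)
  P <- stack$pupil$grid
  # target amplitudes on the normalised field scale
  amps <- lapply(seq_len(nrow(plan)), function(n)
    sqrt(pmax(stack$frames[[n]], 0) /
           (stack$photons_bf * plan$exposure_scale[n])))
  # initialise from the rescaled on-axis frame, Fourier-upsampled, phase 0
  a0 <- amps[[which.min(plan$d)]]
  S <- matrix(0 + 0i, N[1], N[2])
  cy <- floor(N[1] / 2) + 1; cx <- floor(N[2] / 2) + 1
  half_y <- floor(n_lr[1] / 2); half_x <- floor(n_lr[2] / 2)
  rows0 <- cy - half_y; cols0 <- cx - half_x
  S[rows0:(rows0 + n_lr[1] - 1), cols0:(cols0 + n_lr[2] - 1)] <-
    fftshift2(fft2(a0)) / sqrt(sf)
  iy <- stack$shifts[, "iy"]; ix <- stack$shifts[, "ix"]
  misfit <- numeric(cfg$n_iters)
  best <- list(S = S, P = P, misfit = Inf)
  rising <- 0
  for (epoch in seq_len(cfg$n_iters)) {
    err <- 0
    for (n in seq_len(nrow(plan))) {
      r <- (rows0 - iy[n]):(rows0 - iy[n] + n_lr[1] - 1)
      cc <- (cols0 + ix[n]):(cols0 + ix[n] + n_lr[2] - 1)
      O_sub <- S[r, cc]
      psi_k <- O_sub * P
      psi <- ifft2(ifftshift2(psi_k)) * sqrt(sf)
      mod_psi <- Mod(psi)
      err <- err + sum((mod_psi - amps[[n]])^2)
      psi_new <- amps[[n]] * psi / (mod_psi + 1e-12)
      dk <- fftshift2(fft2(psi_new)) / sqrt(sf) - psi_k
      # magnitude-adaptive second-order steps: |.|/( max|.| (|.|^2 + reg) )
      # (for the ideal unit pupil the object step reduces to conj(P) dk)
      mP <- max(Mod(P)); mO <- max(Mod(O_sub))
      S[r, cc] <- O_sub + Mod(P) * Conj(P) /
        (mP * (Mod(P)^2 + cfg$gn_alpha * mP^2)) * dk
      if (cfg$pupil_recovery) {
        P <- (P + Mod(O_sub) * Conj(O_sub) /
                (mO * (Mod(O_sub)^2 + cfg$gn_beta * mO^2)) * dk) *
          P_support(stack)
      }
    }
    misfit[epoch] <- err
    if (err < best$misfit) best <- list(S = S, P = P, misfit = err)
    rising <- if (epoch > 1 && err > misfit[epoch - 1]) rising + 1 else 0
    if (rising >= 3) {
      warning("data misfit increased for 3 consecutive epochs; returning best iterate")
      S <- best$S; P <- best$P
      misfit <- misfit[seq_len(epoch)]
      break
    }
  }
  obj <- ifft2(ifftshift2(S))
  sys_na <- attr(stack$plan, "na_syn")
  na_syn <- if (!is.null(sys_na)) sys_na else
    stack$pupil$cutoff * (stack$wavelength * 1e-3) + max(plan$illum_na)
  cf <- complex_field(obj, stack$pixel_size_obj, na_syn,
                      provenance = list(n_iters = cfg$n_iters,
                                        pupil_recovery = cfg$pupil_recovery,
                                        seed = stack$seed))
  attr(cf, "misfit") <- misfit
  attr(cf, "pupil") <- P
  cf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

P_support <- function(stack) ifelse(Mod(stack$pupil$grid) > 0, 1, 0)

#' Spectral coverage of an FPM acquisition
#'
#' Logical mask (object Fourier grid, centre-origin order) of the
#' frequencies actually sampled by the acquisition: the union of the pupil
#' support shifted to each LED wavevector. Its outer envelope reaches the
#' synthetic NA, but narrow gaps remain between the outermost pupil
#' positions; frequencies outside this mask are never measured and cannot
#' be recovered by any solver.
#'
#' @param stack an [capture_stack()] result.
#' @return logical matrix of the object grid size.
#' @export
spectral_coverage <- function(stack) {
  N <- stack$object_shape; n_lr <- stack$sensor_shape
  cov <- matrix(FALSE, N[1], N[2])
  cy <- floor(N[1] / 2) + 1; cx <- floor(N[2] / 2) + 1
  rows0 <- cy - floor(n_lr[1] / 2); cols0 <- cx - floor(n_lr[2] / 2)
  pup <- Mod(stack$pupil$grid) > 0
  for (i in seq_len(nrow(stack$plan))) {
    r <- (rows0 - stack$shifts[i, 1]):(rows0 - stack$shifts[i, 1] + n_lr[1] - 1)
    cc <- (cols0 + stack$shifts[i, 2]):(cols0 + stack$shifts[i, 2] + n_lr[2] - 1)
    cov[r, cc] <- cov[r, cc] | pup
  }
  cov
}

#' Band-limited NRMSE between two complex fields
#'
#' Compares two fields after restricting both to a common passband
#' (a logical Fourier mask, typically [spectral_coverage()]) and aligning
#' the global phase/scale gauge. This is the reconstruction-accuracy
#' measure used by all solver tests: only frequencies the acquisition
#' sampled are compared.
#'
#' @param x,ref complex matrices of equal size.
#' @param mask logical Fourier mask (centre-origin order), or `NULL` for
#'   the full grid.
#' @return scalar NRMSE.
#' @export
band_nrmse <- function(x, ref, mask = NULL) {
  Sx <- fftshift2(fft2(x)); Sr <- fftshift2(fft2(ref))
  if (!is.null(mask)) { Sx[!mask] <- 0; Sr[!mask] <- 0 }
  Sx <- align_global_phase(Sx, Sr)
  sqrt(sum(Mod(Sx - Sr)^2) / sum(Mod(Sr)^2))
}

#' Digitally refocus a complex field
#'
#' Multiplies the field spectrum by the angular-spectrum defocus transfer
#' function exp(i * 2*pi/lambda * z * sqrt(1 - lambda^2 k^2)) (phase-only;
#' frequencies beyond 1/lambda are left unchanged). Refocusing by z then -z
#' is the identity, and refocus distances add.
#'
#' @param cf a [complex_field()].
#' @param z defocus distance, micrometres.
#' @param wavelength nm.
#' @param warn_beyond_dof warn if |z| exceeds ~5x the depth of field implied
#'   by `cf$na_limit`.
#' @return refocused [complex_field()].
#' @export
digital_refocus <- function(cf, z, wavelength, warn_beyond_dof = TRUE) {
  if (z == 0) return(cf)
  lam_um <- wavelength * 1e-3
  dof <- lam_um / cf$na_limit^2
  if (warn_beyond_dof && abs(z) > 5 * dof)
    warning(sprintf("|z| = %g um is far beyond the ~%.1f um depth of field", z, dof))
  f <- cf_complex(cf)
  kr <- freq_radius(nrow(f), ncol(f), cf$pixel_size)
  arg <- 1 - (lam_um * kr)^2
  tf <- ifelse(arg > 0, exp(1i * 2 * pi / lam_um * z * sqrt(pmax(arg, 0))), 1 + 0i)
  S <- fftshift2(fft2(f)) * tf
  out <- stats::fft(ifftshift2(S), inverse = TRUE) / sqrt(length(S))
  complex_field(out, cf$pixel_size, cf$na_limit,
                provenance = c(cf$provenance, list(refocus_z = z)))
}

#' Flatten scalar offsets and gradients in a phase patch
#'
#' Normalises the patch (subtract mean, divide by standard deviation), then
#' subtracts a Gaussian-blurred copy (kernel `blur_kernel_px`, sigma =
#' size/6), removing slowly varying offsets and ramps so background regions
#' sit near zero.
#'
#' @param patch phase matrix, radians.
#' @param blur_kernel_px odd kernel size in pixels.
#' @return corrected patch; a constant input returns zeros with attribute
#'   `flagged = TRUE`.
#' @export
phase_flatten <- function(patch, blur_kernel_px = 31) {
  s <- stats::sd(patch)
  if (s < .Machine$double.eps) {
    out <- patch * 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  p <- (patch - mean(patch)) / s
  brush <- EBImage::makeBrush(blur_kernel_px, shape = "Gaussian",
                              sigma = blur_kernel_px / 6)
  # circular boundary: the normalised kernel preserves the patch mean, so
  # the flattened output is mean-zero by construction
  blurred <- EBImage::imageData(EBImage::filter2(EBImage::Image(p), brush))
  p - matrix(as.numeric(blurred), nrow(p), ncol(p))
}

#' Histogram-match a matrix to a reference
#'
#' Monotone intensity remap of `src` so its empirical distribution matches
#' `ref`: each pixel is mapped through its (mid-rank) empirical CDF value
#' to the linearly interpolated reference quantile, so the remapped CDF
#' tracks the reference to within one part in the sample size.
#'
#' @param src,ref numeric matrices (any sizes).
#' @param n_bins unused for the mapping itself; kept as the histogram
#'   resolution for reporting.
#' @return remapped `src`, on `ref`'s intensity scale.
#' @export
match_histogram <- function(src, ref, n_bins = 256) {
  if (diff(range(src)) == 0)
    return(matrix(stats::median(ref), nrow(src), ncol(src)))
  # empirical CDF of the source values; with p = (rank-1)/(n-1) and
  # type-7 interpolation, matching an image to itself is the identity
  p <- (rank(src, ties.method = "average") - 1) / (length(src) - 1)
  out <- stats::quantile(ref, probs = p, names = FALSE, type = 7)
  matrix(out, nrow(src), ncol(src))
}

#' Exposure-correct a high-resolution amplitude patch
#'
#' Histogram matches the reconstructed high-resolution amplitude patch to
#' the (upsampled) low-resolution brightfield patch covering the same field
#' region, correcting patchwise intensity variations.
#'
#' @param hr_amp high-resolution amplitude patch.
#' @param lr_bf low-resolution brightfield patch of the same region.
#' @param n_bins quantisation levels for the matching.
#' @return corrected amplitude patch.
#' @export
amplitude_match <- function(hr_amp, lr_bf, n_bins = 256) {
  ref <- EBImage::imageData(EBImage::resize(EBImage::Image(lr_bf),
                                            w = nrow(hr_amp),
                                            h = ncol(hr_amp)))
  match_histogram(hr_amp, matrix(as.numeric(ref), nrow(hr_amp), ncol(hr_amp)),
                  n_bins)
}

#' Stitch patches into a full-field image
#'
#' Places patches at known grid offsets and blends overlapping regions.
#' `blend = "linear"` weights each pixel by its distance to the patch edge
#' (a separable linear ramp), so seams fade smoothly; `"none"` overwrites.
#' Optional integer phase-correlation refinement of each offset against the
#' partially composited canvas within `refine_px`.
#'
#' @param patches list of matrices.
#' @param offsets n x 2 integer matrix of top-left (row, col) positions
#'   (1-based).
#' @param blend `"linear"` or `"none"`.
#' @param refine_px search radius for offset refinement (0 = off).
#' @return stitched matrix covering the full extent.
#' @export
stitch <- function(patches, offsets, blend = c("linear", "none"),
                   refine_px = 0) {
  blend <- match.arg(blend)
  offsets <- matrix(as.integer(round(offsets)), ncol = 2)
  stopifnot(length(patches) == nrow(offsets))
  ext <- sapply(seq_along(patches), function(i)
    offsets[i, ] + dim(patches[[i]]) - 1)
  nr <- max(ext[1, ]); nc <- max(ext[2, ])
  acc <- matrix(0, nr, nc); wacc <- matrix(0, nr, nc)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    off <- offsets[i, ]
    if (refine_px > 0 && i > 1) {
      rows <- off[1]:(off[1] + nrow(p) - 1); cols <- off[2]:(off[2] + ncol(p) - 1)
      rows <- rows[rows <= nr]; cols <- cols[cols <= nc]
      sub_w <- wacc[rows, cols]
      if (!any(sub_w > 0))
        stop("patch does not overlap the composite; cannot refine", call. = FALSE)
      sub <- acc[rows, cols] / pmax(sub_w, 1e-12)
      sub[sub_w == 0] <- mean(p)
      pc <- phase_correlation(sub, p[seq_along(rows), seq_along(cols)])
      dr <- -round(pc$shift[1]); dc <- -round(pc$shift[2])
      if (abs(dr) <= refine_px && abs(dc) <= refine_px)
        off <- off + c(dr, dc)
    }
    w <- if (blend == "linear") {
      ramp <- function(n) pmin(seq_len(n), rev(seq_len(n)))
      outer(ramp(nrow(p)), ramp(ncol(p)))
    } else matrix(1, nrow(p), ncol(p))
    rows <- off[1]:(off[1] + nrow(p) - 1); cols <- off[2]:(off[2] + ncol(p) - 1)
    keep_r <- rows >= 1 & rows <= nr; keep_c <- cols >= 1 & cols <= nc
    if (blend == "none") {
      acc[rows[keep_r], cols[keep_c]] <- p[keep_r, keep_c]
      wacc[rows[keep_r], cols[keep_c]] <- 1
    } else {
      acc[rows[keep_r], cols[keep_c]] <- acc[rows[keep_r], cols[keep_c]] +
        p[keep_r, keep_c] * w[keep_r, keep_c]
      wacc[rows[keep_r], cols[keep_c]] <- wacc[rows[keep_r], cols[keep_c]] +
        w[keep_r, keep_c]
    }
  }
  out <- if (blend == "linear") acc / pmax(wacc, 1e-12) else acc
  # refinement may pull patches inward: drop trailing never-covered margins
  covered_r <- which(apply(wacc > 0, 1, any))
  covered_c <- which(apply(wacc > 0, 2, any))
  out[seq_len(max(covered_r)), seq_len(max(covered_c)), drop = FALSE]
}
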