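# Shared numerical helpers: unitary FFTs, centred frequency grids, bilinear
# sampling, Gaussian blur, and small image utilities used across modules.
#
# Coordinate convention (used everywhere): image arrays are indexed
# [row, col] = (-y, x); Fourier grids have their origin at the array centre
# (fftshift convention); pixel centres sit at integer coordinates with origin
# at the top-left pixel (1, 1) for spatial warps.

#' Unitary 2-D FFT
#'
#' Forward 2-D discrete Fourier transform with "ortho" normalisation
#' (divided by sqrt(M*N)), so that Parseval's identity holds without
#' extra factors.
#'
#' @param x numeric or complex matrix.
#' @return complex matrix of the same size.
#' @keywords internal
fft2 <- function(x) stats::fft(x) / sqrt(length(x))

#' Unitary inverse 2-D FFT
#' @param x complex matrix.
#' @return complex matrix of the same size.
#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Centre the zero-frequency component of a spectrum
#' @param x matrix.
#' @keywords internal
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
}

#' Undo [fftshift2()]
#' @param x matrix.
#' @keywords internal
ifftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((ceiling(nr / 2) + 1):nr, 1:ceiling(nr / 2)),
    c((ceiling(nc / 2) + 1):nc, 1:ceiling(nc / 2))]
}

#' Centred spatial-frequency grid
#'
#' Frequency coordinates (cycles per physical unit) for an n-point grid with
#' sample pitch `pitch`, arranged in fftshift (centre-origin) order.
#'
#' @param n grid length (pixels).
#' @param pitch sample pitch in physical units per pixel.
#' @return numeric vector of length `n`; zero frequency at index
#'   `floor(n/2) + 1`.
#' @keywords internal
freq_axis <- function(n, pitch = 1) {
  (seq_len(n) - 1 - floor(n / 2)) / (n * pitch)
}

#' Radial frequency magnitude grid
#'
#' @param nr,nc grid dimensions.
#' @param pitch pixel pitch (physical units).
#' @return matrix of |k| in centre-origin order, cycles per unit.
#' @keywords internal
freq_radius <- function(nr, nc, pitch = 1) {
  fy <- freq_axis(nr, pitch)
  fx <- freq_axis(nc, pitch)
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Bilinear image sampling at arbitrary coordinates
#'
#' Samples `img` at (row, col) positions given in pixel units (origin at pixel
#' (1,1), pixel centres at integers). Out-of-bounds positions return `fill`.
#'
#' @param img numeric matrix.
#' @param row,col numeric vectors of equal length.
#' @param fill value for samples outside the image.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;   fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp edge samples that sit exactly on the last row/col
  edge <- (row >= 1 & col >= 1 & row <= nr & col <= nc) & !ok
  out <- rep(fill, length(row))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i11] * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    out[edge] <- img[cbind(pmin(pmax(round(row[edge]), 1), nr),
                           pmin(pmax(round(col[edge]), 1), nc))]
  }
  out
}

#' Gaussian blur of a matrix
#'
#' Thin wrapper over EBImage's Gaussian filter operating on plain matrices.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix, same size.
#' @keywords internal
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Normalised root-mean-square error
#'
#' RMSE between `x` and `ref`, normalised by the RMS of `ref`.
#'
#' @param x,ref numeric (or complex) arrays of equal size.
#' @return scalar NRMSE.
#' @export
nrmse <- function(x, ref) {
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}

#' Fourier (sinc) upsampling of a real image
#'
#' Upsamples by zero-padding the centred spectrum — ideal band-limited
#' interpolation, introducing no new frequency content. Used to place
#' low-resolution images on the reconstruction grid for like-for-like
#' resolution comparisons.
#'
#' @param x numeric matrix.
#' @param f integer upsampling factor.
#' @return `f * nrow(x)` by `f * ncol(x)` matrix.
#' @export
fourier_upsample <- function(x, f) {
  n <- dim(x); N <- n * f
  S <- fftshift2(fft2(x))
  big <- matrix(0 + 0i, N[1], N[2])
  r0 <- floor(N[1] / 2) + 1 - floor(n[1] / 2)
  c0 <- floor(N[2] / 2) + 1 - floor(n[2] / 2)
  big[r0:(r0 + n[1] - 1), c0:(c0 + n[2] - 1)] <- S
  Re(stats::fft(ifftshift2(big), inverse = TRUE) / sqrt(length(big))) * f
}

#' Min-max scale a matrix to [0, 1]
#' @param x numeric array.
#' @return scaled array; a constant array maps to 0.
#' @keywords internal
minmax01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] <= r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Circular shift of a matrix
#' @param x matrix; `by` integer (row, col) shift.
#' @keywords internal
circshift2 <- function(x, by) {
  pracma::circshift(x, by)
}

#' 2-D Hann window
#' @param nr,nc dimensions.
#' @return matrix of the separable Hann window.
#' @keywords internal
hann2 <- function(nr, nc) {
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  outer(wy, wx)
}

#' Align one complex field to another over global phase and scale
#'
#' Reconstructions from intensity data carry an arbitrary global phase (and,
#' with unnormalised exposure, a global scale). This resolves the gauge by the
#' least-squares complex factor c = <ref, x> / <x, x>, so that c*x best
#' matches ref. All reconstruction comparisons in the package go through this.
#'
#' @param x complex array to align.
#' @param ref complex reference.
#' @return the aligned copy of `x`.
#' @export
align_global_phase <- function(x, ref) {
  c0 <- sum(Conj(x) * ref) / sum(Mod(x)^2)
  x * c0
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
}
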