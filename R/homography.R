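# Planar geometric transforms shared by the phantom, recon and register
# modules: homography application, perspective warping with bilinear
# resampling, and the Brown-Conrady lens distortion model.
#
# Convention: points are (x, y) with x = column, y = row; pixel centres at
# integer coordinates, origin at the top-left pixel (1, 1). A homography H
# maps moving-image coordinates to fixed-image coordinates.

#' Apply a homography to points
#'
#' @param H 3x3 matrix.
#' @param xy n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
hg_apply <- function(H, xy) {
  xy <- matrix(xy, ncol = 2)
  p <- cbind(xy, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Mean corner displacement between two homographies
#'
#' Maps the four corners of an image of the given size through both
#' transforms and returns the mean Euclidean distance between the results —
#' the standard registration-accuracy metric used throughout the package.
#'
#' @param H1,H2 3x3 homographies.
#' @param shape image size `c(rows, cols)`.
#' @return mean corner error in pixels.
#' @export
hg_corner_error <- function(H1, H2, shape) {
  corners <- cbind(x = c(1, shape[2], shape[2], 1),
                   y = c(1, 1, shape[1], shape[1]))
  d <- hg_apply(H1, corners) - hg_apply(H2, corners)
  mean(sqrt(rowSums(d^2)))
}

#' Warp an image by a homography
#'
#' Resamples `img` onto the fixed grid: for each output pixel p the value is
#' `img` sampled (bilinearly) at `solve(H) %*% p`, so the result is the
#' moving image as seen in the fixed frame.
#'
#' @param img numeric matrix (or 3-d array; warped per channel).
#' @param H 3x3 homography mapping moving to fixed coordinates.
#' @param output_shape `c(rows, cols)`; defaults to `dim(img)`.
#' @param fill fill value outside the source image.
#' @return warped image.
#' @export
warp_perspective <- function(img, H, output_shape = NULL, fill = 0) {
  if (length(dim(img)) == 3) {
    out <- vapply(seq_len(dim(img)[3]), function(ch)
      warp_perspective(img[, , ch], H, output_shape, fill),
      matrix(0, if (is.null(output_shape)) nrow(img) else output_shape[1],
             if (is.null(output_shape)) ncol(img) else output_shape[2]))
    return(out)
  }
  if (is.null(output_shape)) output_shape <- dim(img)
  if (abs(det(H)) < 1e-12) stop("homography is not invertible", call. = FALSE)
  nr <- output_shape[1]; nc <- output_shape[2]
  grid <- cbind(x = rep(seq_len(nc), each = nr),
                y = rep(seq_len(nr), times = nc))
  src <- hg_apply(solve(H), grid)
  matrix(bilinear_sample(img, row = src[, 2], col = src[, 1], fill = fill),
         nr, nc)
}

#' Brown-Conrady distortion of normalised coordinates
#'
#' Forward model: undistorted normalised coordinates (u, v) map to
#' distorted coordinates with radial terms k1, k2 and tangential terms
#' p1, p2.
#'
#' @param uv n x 2 matrix of normalised (u, v).
#' @param k1,k2 radial coefficients.
#' @param p1,p2 tangential coefficients.
#' @return n x 2 matrix of distorted coordinates.
#' @keywords internal
brown_conrady_forward <- function(uv, k1 = 0, k2 = 0, p1 = 0, p2 = 0) {
  u <- uv[, 1]; v <- uv[, 2]
  r2 <- u^2 + v^2
  rad <- 1 + k1 * r2 + k2 * r2^2
  cbind(u * rad + 2 * p1 * u * v + p2 * (r2 + 2 * u^2),
        v * rad + p1 * (r2 + 2 * v^2) + 2 * p2 * u * v)
}

brown_conrady_inverse <- function(uv_d, k1 = 0, k2 = 0, p1 = 0, p2 = 0,
                                  n_iter = 20) {
  # fixed-point inversion of the forward model
  uv <- uv_d
  for (i in seq_len(n_iter)) {
    d <- brown_conrady_forward(uv, k1, k2, p1, p2) - uv
    uv <- uv_d - d
  }
  uv
}

bc_normalise <- function(xy, shape) {
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  s <- max(shape) / 2
  list(uv = cbind((xy[, 1] - cx) / s, (xy[, 2] - cy) / s), cx = cx, cy = cy, s = s)
}

#' Correct Brown-Conrady lens distortion
#'
#' Maps each undistorted output pixel through the forward distortion model
#' and samples the distorted input there (bilinear). Coordinates are
#' normalised by half the larger image dimension about the image centre.
#'
#' @param img distorted image (matrix or 3-d array).
#' @param k1,k2 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return undistorted image of the same size.
#' @export
undistort <- function(img, k1 = 0, k2 = 0, p1 = 0, p2 = 0) {
  if (length(dim(img)) == 3) {
    out <- img
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- undistort(img[, , ch], k1, k2, p1, p2)
    return(out)
  }
  nr <- nrow(img); nc <- ncol(img)
  grid <- cbind(x = rep(seq_len(nc), each = nr),
                y = rep(seq_len(nr), times = nc))
  nz <- bc_normalise(grid, c(nr, nc))
  uv_d <- brown_conrady_forward(nz$uv, k1, k2, p1, p2)
  sx <- uv_d[, 1] * nz$s + nz$cx
  sy <- uv_d[, 2] * nz$s + nz$cy
  matrix(bilinear_sample(img, row = sy, col = sx, fill = 0), nr, nc)
}

#' Render Brown-Conrady lens distortion
#'
#' The inverse operation of [undistort()]: produces the image a camera with
#' the given distortion coefficients would record of `img`. Uses fixed-point
#' inversion of the forward model.
#'
#' @inheritParams undistort
#' @return distorted image of the same size.
#' @export
distort_brown_conrady <- function(img, k1 = 0, k2 = 0, p1 = 0, p2 = 0) {
  if (length(dim(img)) == 3) {
    out <- img
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- distort_brown_conrady(img[, , ch], k1, k2, p1, p2)
    return(out)
  }
  nr <- nrow(img); nc <- ncol(img)
  grid <- cbind(x = rep(seq_len(nc), each = nr),
                y = rep(seq_len(nr), times = nc))
  nz <- bc_normalise(grid, c(nr, nc))
  uv_u <- brown_conrady_inverse(nz$uv, k1, k2, p1, p2)
  sx <- uv_u[, 1] * nz$s + nz$cx
  sy <- uv_u[, 2] * nz$s + nz$cy
  matrix(bilinear_sample(img, row = sy, col = sx, fill = 0), nr, nc)
}
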