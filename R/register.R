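# Registration of unstained-phase to stained images: multi-scale
# difference-of-Gaussian keypoints with gradient-orientation descriptors,
# ratio-test matching, RANSAC perspective transforms, phase-correlation
# translation estimation, chromatic alignment, white balance and
# mutual-information curation of training patch pairs.
#
# The keypoint detector and descriptor are scale-invariant
# DoG blobs with 4x4x8 gradient-orientation-histogram descriptors (an
# upright variant: no dominant-orientation assignment, appropriate for
# slide-to-slide registration where rotation is small). Descriptors built
# from local gradient statistics are robust to the contrast reduction and
# blurring that chemical staining induces in phase images.

#' Subpixel translation by phase correlation
#'
#' Estimates the displacement `s = c(dy, dx)` of the moving image relative
#' to the fixed one, i.e. `moving(x) ~ fixed(x - s)`; warping the moving
#' image by a translation of `-s` aligns it to the fixed image. The
#' integer peak of the inverse cross-power spectrum is refined to subpixel
#' accuracy by evaluating the correlation on an upsampled local grid
#' (explicit DFT around the peak).
#'
#' @param fixed,moving numeric matrices of equal size.
#' @param upsample local refinement factor (peak located to 1/upsample px).
#' @param window apply a Hann window first (suppresses the edge bias of
#'   non-periodic content).
#' @return list with `shift` (dy, dx) and `response` (peak height).
#' @export
phase_correlation <- function(fixed, moving, upsample = 20, window = TRUE) {
  stopifnot(all(dim(fixed) == dim(moving)))
  w <- if (window) hann2(nrow(fixed), ncol(fixed)) else 1
  Fa <- stats::fft((fixed - mean(fixed)) * w)
  Fb <- stats::fft((moving - mean(moving)) * w)
  R <- Fa * Conj(Fb)
  R <- R / pmax(Mod(R), 1e-12)
  corr <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  nr <- nrow(corr); nc <- ncol(corr)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  p0 <- c(wrap(pk[1], nr), wrap(pk[2], nc))   # correlation peak = -shift
  ky <- wrap(seq_len(nr), nr) / nr
  kx <- wrap(seq_len(nc), nc) / nc
  uy <- p0[1] + seq(-1, 1, by = 1 / upsample)
  ux <- p0[2] + seq(-1, 1, by = 1 / upsample)
  Ey <- exp(2i * pi * outer(uy, ky))
  Ex <- exp(2i * pi * outer(kx, ux))
  C <- Re(Ey %*% R %*% Ex) / length(R)
  pk2 <- which(C == max(C), arr.ind = TRUE)[1, ]
  list(shift = c(dy = -uy[pk2[1]], dx = -ux[pk2[2]]), response = max(C))
}

#' Detect multi-scale blob keypoints
#'
#' Difference-of-Gaussian scale-space extrema with low-contrast and edge
#' rejection and subpixel spatial refinement.
#'
#' @param img numeric matrix.
#' @param n_scales DoG levels per octave set.
#' @param sigma0 base blur scale, px.
#' @param contrast_thresh minimum |DoG| response, as a fraction of the
#'   image dynamic range.
#' @param edge_ratio maximum principal-curvature ratio (edge rejection).
#' @param max_keypoints keep at most this many strongest keypoints.
#' @return data frame: `y`, `x` (subpixel), `sigma`, `response`.
#' @export
detect_keypoints <- function(img, n_scales = 6, sigma0 = 1.6,
                             contrast_thresh = 0.02, edge_ratio = 10,
                             max_keypoints = 1500) {
  img <- minmax01(img)
  k <- 2^(1 / 2)
  sigmas <- sigma0 * k^(0:n_scales)
  blurs <- lapply(sigmas, function(s) gauss_blur(img, s))
  dogs <- lapply(seq_len(n_scales), function(i) blurs[[i + 1]] - blurs[[i]])
  nr <- nrow(img); nc <- ncol(img)
  out <- list()
  for (s in 2:(n_scales - 1)) {
    d <- dogs[[s]]
    lo <- dogs[[s - 1]]; hi <- dogs[[s + 1]]
    # interior 3x3x3 extrema, vectorised over shifts
    ctr <- d[2:(nr - 1), 2:(nc - 1)]
    is_max <- abs(ctr) > contrast_thresh
    if (!any(is_max)) next
    mx <- ctr; mn <- ctr
    for (dr in -1:1) for (dc in -1:1) {
      for (lvl in list(lo, d, hi)) {
        sub <- lvl[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
        mx <- pmax(mx, sub); mn <- pmin(mn, sub)
      }
    }
    ext <- (ctr >= mx & ctr > 0) | (ctr <= mn & ctr < 0)
    ext <- ext & is_max
    idx <- which(ext, arr.ind = TRUE)
    if (!nrow(idx)) next
    r <- idx[, 1] + 1; cc <- idx[, 2] + 1
    # edge rejection via the 2x2 spatial Hessian
    dxx <- d[cbind(r, cc + 1)] + d[cbind(r, cc - 1)] - 2 * d[cbind(r, cc)]
    dyy <- d[cbind(r + 1, cc)] + d[cbind(r - 1, cc)] - 2 * d[cbind(r, cc)]
    dxy <- (d[cbind(r + 1, cc + 1)] - d[cbind(r + 1, cc - 1)] -
              d[cbind(r - 1, cc + 1)] + d[cbind(r - 1, cc - 1)]) / 4
    tr <- dxx + dyy; det <- dxx * dyy - dxy^2
    keep <- det > 0 & tr^2 / det < (edge_ratio + 1)^2 / edge_ratio
    r <- r[keep]; cc <- cc[keep]
    if (!length(r)) next
    # subpixel refinement: separable quadratic fit
    off_y <- (d[cbind(r - 1, cc)] - d[cbind(r + 1, cc)]) /
      (2 * (d[cbind(r - 1, cc)] - 2 * d[cbind(r, cc)] + d[cbind(r + 1, cc)]))
    off_x <- (d[cbind(r, cc - 1)] - d[cbind(r, cc + 1)]) /
      (2 * (d[cbind(r, cc - 1)] - 2 * d[cbind(r, cc)] + d[cbind(r, cc + 1)]))
    off_y[!is.finite(off_y) | abs(off_y) > 0.5] <- 0
    off_x[!is.finite(off_x) | abs(off_x) > 0.5] <- 0
    out[[length(out) + 1]] <- data.frame(
      y = r + off_y, x = cc + off_x, sigma = sigmas[s],
      response = abs(d[cbind(r, cc)]))
  }
  if (!length(out))
    return(data.frame(y = numeric(0), x = numeric(0), sigma = numeric(0),
                      response = numeric(0)))
  kp <- do.call(rbind, out)
  kp <- kp[order(-kp$response), ]
  kp[seq_len(min(nrow(kp), max_keypoints)), ]
}

#' Gradient-orientation descriptors for keypoints
#'
#' 4x4 spatial grid of 8-bin gradient-orientation histograms over a
#' Gaussian-weighted window scaled to each keypoint's sigma, normalised,
#' clipped at 0.2 and renormalised. Upright (no rotation assignment).
#'
#' @param img numeric matrix.
#' @param kp keypoints from [detect_keypoints()].
#' @return list with `desc` (n x 128 matrix, unit rows) and `kp` (the
#'   keypoints retained — those fully inside the image).
#' @export
describe_keypoints <- function(img, kp) {
  img <- minmax01(img)
  gy <- img * 0; gx <- img * 0
  nr <- nrow(img); nc <- ncol(img)
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  mag <- sqrt(gy^2 + gx^2)
  ang <- atan2(gy, gx)             # (-pi, pi]
  n_grid <- 4; n_bins <- 8
  desc <- matrix(0, nrow(kp), n_grid * n_grid * n_bins)
  ok <- logical(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    half <- max(6, round(3 * kp$sigma[i]))    # window = 2*half, 4x4 cells
    y0 <- round(kp$y[i]); x0 <- round(kp$x[i])
    if (y0 - half < 1 || x0 - half < 1 || y0 + half - 1 > nr ||
        x0 + half - 1 > nc) next
    rows <- (y0 - half):(y0 + half - 1); cols <- (x0 - half):(x0 + half - 1)
    m <- mag[rows, cols]; a <- ang[rows, cols]
    w <- 2 * half
    gw <- exp(-(((row(m) - 0.5 - half)^2 + (col(m) - 0.5 - half)^2) /
                  (2 * (0.6 * w)^2)))
    m <- m * gw
    cell_r <- pmin(ceiling(row(m) / (w / n_grid)), n_grid)
    cell_c <- pmin(ceiling(col(m) / (w / n_grid)), n_grid)
    bin <- pmin(floor((a + pi) / (2 * pi) * n_bins), n_bins - 1) + 1
    idx <- (cell_r - 1) * n_grid * n_bins + (cell_c - 1) * n_bins + bin
    v <- vapply(seq_len(n_grid * n_grid * n_bins),
                function(k) 0, numeric(1))
    tab <- tapply(as.vector(m), as.vector(idx), sum)
    v[as.integer(names(tab))] <- tab
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    v <- pmin(v / nv, 0.2)
    v <- v / sqrt(sum(v^2))
    desc[i, ] <- v
    ok[i] <- TRUE
  }
  list(desc = desc[ok, , drop = FALSE], kp = kp[ok, , drop = FALSE])
}

#' Match descriptors with Lowe's ratio test
#'
#' Nearest-neighbour matching of unit descriptors by correlation, keeping
#' matches whose nearest distance is below `ratio` times the second
#' nearest.
#'
#' @param d1,d2 descriptor matrices (rows = keypoints).
#' @param ratio ratio-test threshold.
#' @return two-column integer matrix of (index1, index2) matches.
#' @export
match_descriptors <- function(d1, d2, ratio = 0.75) {
  if (!nrow(d1) || !nrow(d2)) return(matrix(integer(0), 0, 2))
  sim <- d1 %*% t(d2)                         # unit rows: dist^2 = 2 - 2 sim
  best <- max.col(sim)
  n <- nrow(d1)
  b1 <- sim[cbind(seq_len(n), best)]
  sim[cbind(seq_len(n), best)] <- -Inf
  b2 <- sim[cbind(seq_len(n), max.col(sim))]
  dist1 <- sqrt(pmax(2 - 2 * b1, 0)); dist2 <- sqrt(pmax(2 - 2 * b2, 0))
  keep <- which(dist1 < ratio * dist2)
  cbind(keep, best[keep])
}

normalise_pts <- function(xy) {
  ctr <- colMeans(xy)
  d <- sqrt(rowSums(sweep(xy, 2, ctr)^2))
  s <- sqrt(2) / mean(d)
  T <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  list(T = T, xy = cbind(s * (xy[, 1] - ctr[1]), s * (xy[, 2] - ctr[2])))
}

homography_dlt <- function(src, dst) {
  ns <- normalise_pts(src); nd <- normalise_pts(dst)
  s <- ns$xy; d <- nd$xy
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  # null vector of A: smallest eigenvector of t(A) A (works for the 8x9
  # minimal-sample system too, where svd() returns only 8 right vectors)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

#' RANSAC homography estimation from point matches
#'
#' @param src,dst n x 2 matrices of (x, y) correspondences (src maps to
#'   dst).
#' @param thresh inlier reprojection threshold, px.
#' @param confidence early-stop confidence.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the minimal samples.
#' @return list with `H` (3x3), `inliers` (logical vector).
#' @export
estimate_homography_ransac <- function(src, dst, thresh = 3,
                                       confidence = 0.995, max_iter = 2000,
                                       seed = 1) {
  n <- nrow(src)
  if (n < 4) stop("need at least 4 matches", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best_inl <- rep(FALSE, n); best_cnt <- 0
  it <- 0; needed <- max_iter
  while (it < min(needed, max_iter)) {
    it <- it + 1
    s <- sample.int(n, 4)
    H <- tryCatch(homography_dlt(src[s, , drop = FALSE],
                                 dst[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(H) || !all(is.finite(H))) next
    proj <- hg_apply(H, src)
    err <- sqrt(rowSums((proj - dst)^2))
    inl <- err < thresh
    if (sum(inl) > best_cnt) {
      best_cnt <- sum(inl); best_inl <- inl
      w <- best_cnt / n
      needed <- if (w > 0) log(1 - confidence) / log(1 - w^4) else max_iter
    }
  }
  if (best_cnt < 4) stop("RANSAC failed to find a consensus", call. = FALSE)
  H <- homography_dlt(src[best_inl, , drop = FALSE],
                      dst[best_inl, , drop = FALSE])
  # one re-estimation pass over the refreshed inlier set
  err <- sqrt(rowSums((hg_apply(H, src) - dst)^2))
  inl <- err < thresh
  if (sum(inl) >= 4)
    H <- homography_dlt(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  list(H = H, inliers = inl)
}

#' Refine a homography by local phase correlation
#'
#' Given an initial homography, warps the moving image, measures residual
#' subpixel shifts between the warped and fixed images with windowed phase
#' correlation on a grid of patches, converts them into dense
#' correspondences and re-estimates the homography by least squares. Grid
#' positions with a weak correlation peak are dropped.
#'
#' @param moving,fixed images.
#' @param H initial 3x3 homography (moving -> fixed).
#' @param grid patches per axis.
#' @param patch patch size, px (shrunk automatically on small images;
#'   larger patches give phase correlation more texture to lock onto,
#'   which matters for blurred cross-modality content).
#' @param keep_frac fraction of strongest correlation peaks kept.
#' @return refined 3x3 homography (the input if too few reliable patches).
#' @export
refine_homography_ncc <- function(moving, fixed, H, grid = 8, patch = 64,
                                  keep_frac = 0.75) {
  W <- warp_perspective(moving, H, output_shape = dim(fixed))
  nr <- nrow(fixed); nc <- ncol(fixed)
  patch <- min(patch, floor(min(nr, nc) / 3))
  if (patch < 16) return(H)
  rs <- round(seq(1, nr - patch + 1, length.out = grid))
  cs <- round(seq(1, nc - patch + 1, length.out = grid))
  pts_w <- NULL; pts_f <- NULL; resp <- NULL
  for (r in rs) for (cc in cs) {
    ir <- r:(r + patch - 1); ic <- cc:(cc + patch - 1)
    fw <- W[ir, ic]; ff <- fixed[ir, ic]
    if (stats::sd(fw) < 1e-9 || stats::sd(ff) < 1e-9) next
    pc <- phase_correlation(ff, fw)
    if (max(abs(pc$shift)) > patch / 4) next      # implausible residual
    ctr <- c(x = cc + (patch - 1) / 2, y = r + (patch - 1) / 2)
    pts_w <- rbind(pts_w, ctr)
    pts_f <- rbind(pts_f, c(ctr[1] - pc$shift[["dx"]],
                            ctr[2] - pc$shift[["dy"]]))
    resp <- c(resp, pc$response)
  }
  if (is.null(resp) || length(resp) < 8) return(H)
  keep <- resp >= stats::quantile(resp, 1 - keep_frac)
  if (sum(keep) < 8) return(H)
  # correspondences in moving coordinates -> fixed coordinates
  src <- hg_apply(solve(H), pts_w[keep, , drop = FALSE])
  homography_dlt(src, pts_f[keep, , drop = FALSE])
}

#' Register a moving phase image to a fixed one by a perspective transform
#'
#' Detects multi-scale keypoints in both images, matches descriptors with
#' the ratio test, estimates a RANSAC homography (moving -> fixed), and
#' returns the transform with the warped moving image.
#'
#' @param moving,fixed numeric matrices sharing overlapping content.
#' @param ratio ratio-test threshold.
#' @param ransac_thresh RANSAC reprojection threshold, px.
#' @param confidence RANSAC confidence.
#' @param min_inliers registration fails below this inlier count.
#' @param refine run a local phase-correlation refinement pass
#'   ([refine_homography_ncc()]) after RANSAC.
#' @param ... passed to [detect_keypoints()].
#' @return list of class `registration`: `H`, `n_matches`, `n_inliers`,
#'   `warped`, `rms_error` (inlier reprojection RMS).
#' @export
register_perspective <- function(moving, fixed, ratio = 0.75,
                                 ransac_thresh = 3, confidence = 0.995,
                                 min_inliers = 8, refine = TRUE, ...) {
  kpm <- detect_keypoints(moving, ...)
  kpf <- detect_keypoints(fixed, ...)
  dm <- describe_keypoints(moving, kpm)
  df <- describe_keypoints(fixed, kpf)
  m <- match_descriptors(dm$desc, df$desc, ratio)
  if (nrow(m) < min_inliers)
    stop(sprintf("registration failure: only %d tentative matches (%d/%d keypoints)",
                 nrow(m), nrow(dm$kp), nrow(df$kp)), call. = FALSE)
  src <- cbind(dm$kp$x[m[, 1]], dm$kp$y[m[, 1]])
  dst <- cbind(df$kp$x[m[, 2]], df$kp$y[m[, 2]])
  fit <- estimate_homography_ransac(src, dst, ransac_thresh, confidence)
  if (sum(fit$inliers) < min_inliers)
    stop(sprintf("registration failure: %d inliers (< %d) of %d matches",
                 sum(fit$inliers), min_inliers, nrow(m)), call. = FALSE)
  if (refine) fit$H <- refine_homography_ncc(moving, fixed, fit$H)
  err <- sqrt(rowSums((hg_apply(fit$H, src) - dst)^2))
  structure(list(H = fit$H, n_matches = nrow(m),
                 n_inliers = sum(fit$inliers),
                 rms_error = sqrt(mean(err[fit$inliers]^2)),
                 warped = warp_perspective(moving, fit$H,
                                           output_shape = dim(fixed))),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> %d/%d inliers, RMS %.2f px\n",
              x$n_inliers, x$n_matches, x$rms_error))
  invisible(x)
}

#' Mutual information between two images
#'
#' MI in bits from the joint `n_bins` x `n_bins` histogram of the min-max
#' scaled images. A constant image carries no information: MI is 0 with
#' attribute `flagged = TRUE`.
#'
#' @param a,b numeric matrices of equal size.
#' @param n_bins histogram bins per axis.
#' @return MI >= 0, bits.
#' @export
mutual_information <- function(a, b, n_bins = 64) {
  stopifnot(all(dim(a) == dim(b)))
  if (diff(range(a)) == 0 || diff(range(b)) == 0) {
    out <- 0; attr(out, "flagged") <- TRUE
    return(out)
  }
  qa <- pmin(floor(minmax01(a) * n_bins), n_bins - 1) + 1
  qb <- pmin(floor(minmax01(b) * n_bins), n_bins - 1) + 1
  joint <- matrix(tabulate((qa - 1) * n_bins + qb, n_bins * n_bins),
                  n_bins, n_bins) / length(a)
  pa <- colSums(joint); pb <- rowSums(joint)
  outer_p <- outer(pb, pa)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Shannon entropy of an image, bits
#' @param a numeric matrix.
#' @param n_bins histogram bins.
#' @return entropy in bits.
#' @export
image_entropy <- function(a, n_bins = 64) {
  if (diff(range(a)) == 0) return(0)
  qa <- pmin(floor(minmax01(a) * n_bins), n_bins - 1) + 1
  p <- tabulate(qa, n_bins) / length(a)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Curate GAN training pairs by mutual information
#'
#' Tiles the registered unstained-phase field and the stained phase/RGB
#' fields into patches, scores each position by the mutual information
#' between the unstained and stained phase patches, and accepts positions
#' scoring at least `mi_cutoff` — rejecting misregistered patches,
#' reconstruction artefacts and tissue-free background.
#'
#' @param phase_unstained registered unstained phase field (matrix).
#' @param phase_stained stained phase field on the same grid.
#' @param rgb_stained rows x cols x 3 stained RGB field.
#' @param patch_size patch side, px.
#' @param mi_cutoff acceptance threshold, bits.
#' @param n_bins MI histogram bins; a non-default estimator warns that the
#'   default cutoff was calibrated for 64-bin MI in bits.
#' @return object of class `patch_pairs`: list with `manifest` (data frame:
#'   `id`, `row`, `col`, `mi_score`, `accepted`) and `pairs` (list of
#'   accepted pairs, each with `phase_patch`, `rgb_patch`, `mi_score`,
#'   `row`, `col`).
#' @export
curate_pairs <- function(phase_unstained, phase_stained, rgb_stained,
                         patch_size = 256, mi_cutoff = 0.4, n_bins = 64) {
  if (n_bins != 64 && mi_cutoff == 0.4)
    warning("default mi_cutoff = 0.4 was calibrated for 64-bin MI in bits")
  stopifnot(all(dim(phase_unstained) == dim(phase_stained)))
  rs <- seq(1, nrow(phase_unstained) - patch_size + 1, by = patch_size)
  cs <- seq(1, ncol(phase_unstained) - patch_size + 1, by = patch_size)
  manifest <- list(); pairs <- list()
  id <- 0
  for (r in rs) for (cc in cs) {
    id <- id + 1
    ir <- r:(r + patch_size - 1); ic <- cc:(cc + patch_size - 1)
    pu <- phase_unstained[ir, ic]; ps <- phase_stained[ir, ic]
    mi <- as.numeric(mutual_information(pu, ps, n_bins))
    acc <- mi >= mi_cutoff
    manifest[[id]] <- data.frame(id = id, row = r, col = cc,
                                 mi_score = mi, accepted = acc)
    if (acc)
      pairs[[length(pairs) + 1]] <- list(
        phase_patch = pu, rgb_patch = rgb_stained[ir, ic, , drop = FALSE],
        mi_score = mi, row = r, col = cc)
  }
  manifest <- do.call(rbind, manifest)
  structure(list(manifest = manifest, pairs = pairs,
                 patch_size = patch_size, mi_cutoff = mi_cutoff,
                 acceptance_fraction = mean(manifest$accepted)),
            class = "patch_pairs")
}

#' @export
print.patch_pairs <- function(x, ...) {
  cat(sprintf("<patch_pairs> %d/%d patches accepted (MI >= %.2f bits)\n",
              sum(x$manifest$accepted), nrow(x$manifest), x$mi_cutoff))
  invisible(x)
}

fit_linear_transform <- function(src, dst, mode) {
  # least-squares x' = A x + t with A restricted by mode
  n <- nrow(src)
  switch(mode,
    translation = {
      t0 <- colMeans(dst - src)
      rbind(c(1, 0, t0[1]), c(0, 1, t0[2]), c(0, 0, 1))
    },
    similarity = {
      sc <- scale(src, scale = FALSE); dc <- scale(dst, scale = FALSE)
      num <- sum(sc[, 1] * dc[, 1] + sc[, 2] * dc[, 2])
      cr <- sum(sc[, 1] * dc[, 2] - sc[, 2] * dc[, 1])
      den <- sum(sc^2)
      a <- num / den; b <- cr / den
      A <- rbind(c(a, -b), c(b, a))
      t0 <- colMeans(dst) - A %*% colMeans(src)
      rbind(cbind(A, t0), c(0, 0, 1))
    },
    affine = {
      X <- cbind(src, 1)
      B <- qr.solve(X, dst)              # 3 x 2
      rbind(t(B), c(0, 0, 1))
    })
}

#' Align colour channels of a sequentially captured RGB image
#'
#' Warps the red and blue amplitude channels onto the green channel to
#' correct lateral chromatic offsets. The transform is estimated either
#' from matched keypoints (least squares over RANSAC inliers; full affine
#' or restricted modes) or by subpixel phase correlation (translation
#' only). Falls back to the identity with a warning when too few matches
#' are found.
#'
#' @param r,g,b channel matrices of equal size.
#' @param mode `"affine"`, `"similarity"`, or `"translation"`.
#' @param method `"keypoints"` or `"phase"` (phase correlation implies
#'   translation).
#' @param min_matches fall back to identity below this count.
#' @return list with `rgb` (aligned rows x cols x 3 array) and
#'   `transforms` (list of 3x3 matrices for r and b).
#' @export
chromatic_align <- function(r, g, b,
                            mode = c("affine", "similarity", "translation"),
                            method = c("keypoints", "phase"),
                            min_matches = 8) {
  mode <- match.arg(mode); method <- match.arg(method)
  est <- function(mov) {
    if (method == "phase" || mode == "translation") {
      sh <- phase_correlation(g, mov)$shift
      # moving = fixed shifted by sh; translating by -sh aligns it
      return(rbind(c(1, 0, -sh[["dx"]]), c(0, 1, -sh[["dy"]]), c(0, 0, 1)))
    }
    km <- describe_keypoints(mov, detect_keypoints(mov))
    kf <- describe_keypoints(g, detect_keypoints(g))
    mt <- match_descriptors(km$desc, kf$desc)
    if (nrow(mt) < min_matches) {
      warning("insufficient matches for chromatic alignment; using identity")
      return(diag(3))
    }
    src <- cbind(km$kp$x[mt[, 1]], km$kp$y[mt[, 1]])
    dst <- cbind(kf$kp$x[mt[, 2]], kf$kp$y[mt[, 2]])
    fit <- estimate_homography_ransac(src, dst, thresh = 3)
    fit_linear_transform(src[fit$inliers, , drop = FALSE],
                         dst[fit$inliers, , drop = FALSE], mode)
  }
  Tr <- est(r); Tb <- est(b)
  out <- array(0, c(nrow(g), ncol(g), 3))
  out[, , 1] <- warp_perspective(r, Tr)
  out[, , 2] <- g
  out[, , 3] <- warp_perspective(b, Tb)
  list(rgb = out, transforms = list(r = Tr, b = Tb))
}

#' Self-white-balance an RGB image against a background region
#'
#' Divides each channel by its mean over the background region of
#' interest, then clips to `[0, 1]`; a white background is restored to
#' (1, 1, 1) and the operation is idempotent.
#'
#' @param rgb rows x cols x 3 array.
#' @param background_roi logical matrix, or list with `rows` and `cols`
#'   index vectors.
#' @return white-balanced array.
#' @export
white_balance <- function(rgb, background_roi) {
  msk <- if (is.list(background_roi)) {
    m <- matrix(FALSE, dim(rgb)[1], dim(rgb)[2])
    m[background_roi$rows, background_roi$cols] <- TRUE
    m
  } else background_roi
  if (!any(msk)) stop("background RoI is empty", call. = FALSE)
  out <- rgb
  for (ch in 1:3) {
    m <- mean(rgb[, , ch][msk])
    if (m <= .Machine$double.eps)
      stop("zero-mean channel in background RoI", call. = FALSE)
    out[, , ch] <- pmin(pmax(rgb[, , ch] / m, 0), 1)
  }
  out
}

#' Per-channel histogram matching of colour images
#'
#' Monotone remap of each channel of `src` to the corresponding channel
#' histogram of `ref` (see [match_histogram()]).
#'
#' @param src,ref rows x cols x 3 arrays.
#' @param n_bins quantisation levels.
#' @return remapped copy of `src`.
#' @export
histogram_match_color <- function(src, ref, n_bins = 256) {
  out <- src
  for (ch in 1:3)
    out[, , ch] <- match_histogram(src[, , ch], ref[, , ch], n_bins)
  out
}
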