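# Image evaluation suite: luma conversion, global SSIM/RMSE/PSNR/PCC on
# patches, CIE Lab colour histograms and Delta-E, decorrelation-analysis
# resolution estimation, and Welch's t test.

#' Convert RGB to grayscale luma
#'
#' Y = 0.299 R + 0.587 G + 0.114 B, applied channelwise to an
#' rows x cols x 3 array (values in `[0,1]` or `[0,255]`).
#'
#' @param rgb 3-d array.
#' @return matrix of the same spatial size.
#' @export
to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

img_stats <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  list(mx = mx, my = my, vx = vx, vy = vy, cxy = cxy)
}

#' Global structural similarity index
#'
#' Whole-patch SSIM with stability constants C1 = (0.01 R)^2 and
#' C2 = (0.03 R)^2, where R is the pixel-value range. Computed globally
#' over the patch (no sliding window), matching per-patch evaluation of
#' 256 x 256 tiles; see [ssim_windowed()] for the windowed variant.
#'
#' @param x,y numeric matrices of equal size.
#' @param R maximum pixel value (1 for unit-range images).
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_global <- function(x, y, R = 1) {
  s <- img_stats(x, y)
  C1 <- (0.01 * R)^2; C2 <- (0.03 * R)^2
  (2 * s$mx * s$my + C1) * (2 * s$cxy + C2) /
    ((s$mx^2 + s$my^2 + C1) * (s$vx + s$vy + C2))
}

#' Sliding-window SSIM (non-default variant)
#'
#' Mean of [ssim_global()] over a square sliding window; provided for
#' comparison with windowed SSIM conventions.
#'
#' @inheritParams ssim_global
#' @param window window size, px.
#' @param stride window stride, px.
#' @return mean windowed SSIM.
#' @export
ssim_windowed <- function(x, y, R = 1, window = 8, stride = 4) {
  rs <- seq(1, nrow(x) - window + 1, by = stride)
  cs <- seq(1, ncol(x) - window + 1, by = stride)
  vals <- vapply(rs, function(r) vapply(cs, function(cc)
    ssim_global(x[r:(r + window - 1), cc:(cc + window - 1)],
                y[r:(r + window - 1), cc:(cc + window - 1)], R),
    numeric(1)), numeric(length(cs)))
  mean(vals)
}

#' Root-mean-square error between two images
#' @param x,y numeric matrices of equal size.
#' @return RMSE (>= 0).
#' @export
rmse_img <- function(x, y) sqrt(mean((x - y)^2))

#' Peak signal-to-noise ratio
#' @inheritParams ssim_global
#' @return PSNR in dB: 10 log10(R^2 / RMSE^2).
#' @export
psnr_img <- function(x, y, R = 1) {
  r <- rmse_img(x, y)
  if (r == 0) return(Inf)
  10 * log10(R^2 / r^2)
}

#' Pearson correlation coefficient between two images
#'
#' sigma_xy / (sigma_x sigma_y); a zero-variance input gives `NA` with
#' attribute `flagged = TRUE`.
#'
#' @param x,y numeric matrices of equal size.
#' @return PCC in `[-1, 1]`, or flagged `NA`.
#' @export
pcc_img <- function(x, y) {
  s <- img_stats(x, y)
  if (s$vx <= 0 || s$vy <= 0) {
    out <- NA_real_; attr(out, "flagged") <- TRUE
    return(out)
  }
  s$cxy / sqrt(s$vx * s$vy)
}

#' Patchwise similarity report between two images
#'
#' Tiles both images into non-overlapping square patches, optionally drops
#' background patches (tissue mask by Otsu threshold on the grayscale mean
#' image), and computes the requested metrics per patch.
#'
#' @param a,b matrices or rows x cols x 3 RGB arrays (converted with
#'   [to_gray()]).
#' @param patch patch size, px.
#' @param metrics character subset of `c("ssim", "rmse", "psnr", "pcc")`.
#' @param R pixel-value range.
#' @param mask `"otsu"` to keep only patches with >= 25% tissue cover,
#'   `"none"`, or a logical matrix.
#' @return object of class `metric_report`: data frame of per-patch values
#'   with patch coordinates; `summary(report)` gives mean +/- sd.
#' @export
metric_report <- function(a, b, patch = 256,
                          metrics = c("ssim", "rmse", "psnr", "pcc"),
                          R = 1, mask = "otsu") {
  if (length(dim(a)) == 3) a <- to_gray(a)
  if (length(dim(b)) == 3) b <- to_gray(b)
  stopifnot(all(dim(a) == dim(b)))
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (identical(mask, "otsu")) {
    g <- minmax01((a + b) / 2)
    th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
    # tissue is the darker side for brightfield; pick the minority-bright side
    m <- g < th
    if (mean(m) < 0.05) m <- g >= th
    mask <- m
  } else if (identical(mask, "none")) {
    mask <- matrix(TRUE, nrow(a), ncol(a))
  }
  rs <- seq(1, nrow(a) - patch + 1, by = patch)
  cs <- seq(1, ncol(a) - patch + 1, by = patch)
  rows <- list()
  for (r in rs) for (cc in cs) {
    idx_r <- r:(r + patch - 1); idx_c <- cc:(cc + patch - 1)
    if (mean(mask[idx_r, idx_c]) < 0.25) next
    pa <- a[idx_r, idx_c]; pb <- b[idx_r, idx_c]
    vals <- c(row = r, col = cc,
              ssim = if ("ssim" %in% metrics) ssim_global(pa, pb, R) else NA,
              rmse = if ("rmse" %in% metrics) rmse_img(pa, pb) else NA,
              psnr = if ("psnr" %in% metrics) psnr_img(pa, pb, R) else NA,
              pcc = if ("pcc" %in% metrics) as.numeric(pcc_img(pa, pb)) else NA)
    rows[[length(rows) + 1]] <- vals
  }
  df <- as.data.frame(do.call(rbind, rows))
  df <- df[, c("row", "col", metrics)]
  attr(df, "params") <- list(patch = patch, R = R,
                             C1 = (0.01 * R)^2, C2 = (0.03 * R)^2)
  class(df) <- c("metric_report", "data.frame")
  df
}

#' @export
summary.metric_report <- function(object, ...) {
  num <- setdiff(names(object), c("row", "col"))
  out <- data.frame(metric = num,
                    mean = vapply(num, function(m) mean(object[[m]]), 0),
                    sd = vapply(num, function(m) stats::sd(object[[m]]), 0),
                    n = nrow(object))
  rownames(out) <- NULL
  out
}

rgb_to_lab <- function(rgb) {
  d <- dim(rgb)
  m <- matrix(rgb, ncol = 3)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, c(d[1], d[2], 3))
}

#' Mean CIE76 colour difference between two RGB images
#'
#' Converts both images from sRGB (D65) to CIE Lab and returns the mean
#' pixelwise Euclidean distance Delta-E, optionally restricted to a tissue
#' mask. The per-pixel map is attached as attribute `map`.
#'
#' @param rgb_a,rgb_b rows x cols x 3 arrays in `[0,1]`.
#' @param mask optional logical matrix.
#' @return mean Delta-E (scalar) with attribute `map`.
#' @export
delta_e <- function(rgb_a, rgb_b, mask = NULL) {
  la <- rgb_to_lab(rgb_a); lb <- rgb_to_lab(rgb_b)
  map <- sqrt((la[, , 1] - lb[, , 1])^2 + (la[, , 2] - lb[, , 2])^2 +
                (la[, , 3] - lb[, , 3])^2)
  val <- if (is.null(mask)) mean(map) else mean(map[mask])
  attr(val, "map") <- map
  val
}

#' CIE Lab channel histograms of an RGB image
#'
#' @param rgb rows x cols x 3 array in `[0,1]`.
#' @param bins number of histogram bins per channel.
#' @return list of three `hist` objects (`L`, `a`, `b`), with ranges
#'   L in `[0,100]`, a/b in `[-128, 127]`.
#' @export
lab_histograms <- function(rgb, bins = 64) {
  lab <- rgb_to_lab(rgb)
  list(L = graphics::hist(lab[, , 1], breaks = seq(0, 100, length.out = bins + 1),
                          plot = FALSE),
       a = graphics::hist(pmin(pmax(lab[, , 2], -128), 127),
                          breaks = seq(-128, 127, length.out = bins + 1),
                          plot = FALSE),
       b = graphics::hist(pmin(pmax(lab[, , 3], -128), 127),
                          breaks = seq(-128, 127, length.out = bins + 1),
                          plot = FALSE))
}

#' Resolution estimation by decorrelation analysis
#'
#' Estimates the spatial-frequency cutoff of a single image without a
#' reference: the decorrelation function d(r) is the normalised zero-lag
#' cross-correlation between the image spectrum I(k) and its
#' amplitude-normalised copy restricted to a circular mask of radius r;
#' the family of curves obtained by repeating the analysis on
#' Gaussian-high-pass-filtered copies of the image traces how far
#' signal dominates noise, and the cutoff is the highest frequency at
#' which a local maximum is detected in any curve.
#'
#' @param img numeric matrix (single channel), at least 64 x 64.
#' @param n_radii number of mask radii spanning (0, 1] Nyquist.
#' @param n_highpass number of Gaussian high-pass pre-filters.
#' @param sigma_range image-domain sigma range (px) of the high-pass
#'   filters, spaced geometrically.
#' @param apodize apply a Hann window before transforming (suppresses edge
#'   leakage).
#' @return object of class `resolution_estimate`: `cutoff` (fraction of
#'   Nyquist, `NA` and flagged for a structureless image), `radii`,
#'   `curves` (n_radii x (n_highpass + 1)), `peaks` (per-curve local-max
#'   frequency).
#' @export
decorrelation_cutoff <- function(img, n_radii = 50, n_highpass = 10,
                                 sigma_range = c(0.15, 5), apodize = TRUE) {
  stopifnot(is.matrix(img))
  img <- img - mean(img)
  if (max(abs(img)) < .Machine$double.eps) {
    out <- structure(list(cutoff = NA_real_, radii = NULL, curves = NULL,
                          peaks = NULL, flagged = TRUE),
                     class = "resolution_estimate")
    return(out)
  }
  if (apodize) img <- img * hann2(nrow(img), ncol(img))
  S <- fftshift2(fft2(img))
  absS <- Mod(S)
  Sn <- S / ifelse(absS > 0, absS, 1)
  Sn[absS == 0] <- 0
  # normalised radial frequency: 1 at the Nyquist of the shorter axis
  kr <- freq_radius(nrow(img), ncol(img), 1) / 0.5
  radii <- seq(1 / n_radii, 1, length.out = n_radii)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_highpass))
  hp_list <- c(list(NULL), lapply(sigmas, function(s)
    1 - exp(-2 * pi^2 * s^2 * (kr * 0.5)^2)))
  curves <- matrix(NA_real_, n_radii, length(hp_list))
  # order the radii computation once; masks are nested
  ord <- order(kr)
  kr_sorted <- kr[ord]
  for (j in seq_along(hp_list)) {
    Sj <- if (is.null(hp_list[[j]])) S else S * hp_list[[j]]
    Snj <- if (is.null(hp_list[[j]])) Sn else Sn * hp_list[[j]]
    num_all <- Re(Sj * Conj(Snj))[ord]
    den2_all <- (Mod(Snj)^2)[ord]
    tot1 <- sum(Mod(Sj)^2)
    cn <- cumsum(num_all); cd <- cumsum(den2_all)
    pos <- findInterval(radii, kr_sorted)
    d <- ifelse(pos > 0, cn[pmax(pos, 1)] / sqrt(tot1 * pmax(cd[pmax(pos, 1)],
                                                             1e-30)), 0)
    curves[, j] <- d
  }
  peaks <- apply(curves, 2, function(d) {
    n <- length(d)
    locs <- which(diff(sign(diff(d))) < 0) + 1      # interior local maxima
    # keep maxima with a minimal drop afterwards (prominence)
    keep <- vapply(locs, function(i) {
      later_min <- min(d[i:n])
      (d[i] - later_min) > 1e-3
    }, logical(1))
    locs <- locs[keep]
    if (d[n] > d[n - 1] + 1e-6) locs <- c(locs, n)   # still rising at Nyquist
    if (!length(locs)) return(NA_real_)
    radii[max(locs)]
  })
  cutoff <- if (all(is.na(peaks))) NA_real_ else max(peaks, na.rm = TRUE)
  structure(list(cutoff = cutoff, radii = radii, curves = curves,
                 peaks = peaks, flagged = all(is.na(peaks))),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  if (is.na(x$cutoff)) cat("<resolution_estimate> no local maxima (flagged)\n")
  else cat(sprintf("<resolution_estimate> cutoff %.3f of Nyquist\n", x$cutoff))
  invisible(x)
}

#' Patchwise resolution heatmap
#'
#' Decorrelation cutoff evaluated on a grid of patches, min-max normalised
#' over the field (patches without a detectable cutoff are `NA`).
#'
#' @param img numeric matrix.
#' @param patch patch size, px.
#' @param stride grid stride; defaults to `patch` (non-overlapping).
#' @param ... passed to [decorrelation_cutoff()].
#' @return matrix of normalised cutoffs (one cell per patch).
#' @export
resolution_heatmap <- function(img, patch = 128, stride = patch, ...) {
  rs <- seq(1, nrow(img) - patch + 1, by = stride)
  cs <- seq(1, ncol(img) - patch + 1, by = stride)
  out <- matrix(NA_real_, length(rs), length(cs))
  for (i in seq_along(rs)) for (j in seq_along(cs)) {
    est <- decorrelation_cutoff(img[rs[i]:(rs[i] + patch - 1),
                                    cs[j]:(cs[j] + patch - 1)], ...)
    out[i, j] <- est$cutoff
  }
  if (all(is.na(out))) return(out)
  rng <- range(out, na.rm = TRUE)
  if (diff(rng) == 0) out * 0 else (out - rng[1]) / diff(rng)
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test (Welch-Satterthwaite degrees of freedom),
#' delegated to [stats::t.test()].
#'
#' @param sample_a,sample_b numeric vectors, n >= 2 each.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("need at least 2 observations per sample", call. = FALSE)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    stop("both samples have zero variance", call. = FALSE)
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
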