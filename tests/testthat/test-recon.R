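# Gauss-Newton phase retrieval and the post-processing chain.

test_that("noiseless inverse-crime reconstruction recovers the object", {
  st <- small_stack_noiseless()
  cf <- gauss_newton_reconstruct(st, recon_config(patch_size_raw = 96,
                                                  n_iters = 15))
  truth <- phantom_field(small_phantom())
  cov <- spectral_coverage(st)
  expect_lt(band_nrmse(cf_complex(cf), truth, cov), 0.01)
  expect_equal(cf$na_limit, synthetic_na(ref_system(), small_plan()),
               tolerance = 1e-9)
  # data misfit is non-increasing on noiseless data
  mf <- attr(cf, "misfit")
  expect_true(all(diff(mf) <= 0))
})

test_that("uniform-object stack reconstructs to a uniform field", {
  n <- 96
  ph <- structure(list(amplitude = matrix(1, n, n), phase = matrix(0, n, n),
                       pixel_size = 0.319), class = "tissue_phantom")
  st <- capture_stack(ph, ref_system(), small_plan(),
                      noise_params = list(shot = FALSE, read_sigma = 0))
  cf <- gauss_newton_reconstruct(st, recon_config(patch_size_raw = 96,
                                                  n_iters = 5))
  expect_lt(stats::sd(cf$phase), 1e-3)
  expect_lt(stats::sd(cf$amplitude) / mean(cf$amplitude), 1e-3)
})

test_that("mismatched frame count is rejected", {
  st <- small_stack_noiseless()
  st$frames <- st$frames[-1]
  expect_error(gauss_newton_reconstruct(
    st, recon_config(patch_size_raw = 96)), "frame count")
})

test_that("pupil recovery identifies a simulated astigmatic pupil", {
  ph <- small_phantom()
  pup_true <- make_pupil(ref_system(), 530, c(32, 32), 0.319 * 3,
                         zernike = c("Z2,2" = 0.5))
  st <- capture_stack(ph, ref_system(), small_plan(), pupil = pup_true,
                      noise_params = list(shot = FALSE, read_sigma = 0))
  # solver starts from an ideal (flat) pupil; joint recovery converges
  # slowly (object and pupil trade off), so give it a long run
  st$pupil <- make_pupil(ref_system(), 530, c(32, 32), 0.319 * 3)
  cf <- gauss_newton_reconstruct(
    st, recon_config(patch_size_raw = 96, n_iters = 80,
                     pupil_recovery = TRUE))
  P_rec <- attr(cf, "pupil")
  inside <- Mod(pup_true$grid) > 0
  expect_gt(stats::cor(Arg(P_rec[inside]), Arg(pup_true$grid[inside])), 0.9)
})

test_that("digital refocusing is unitary and additive in z", {
  st <- small_stack_noiseless()
  cf <- gauss_newton_reconstruct(st, recon_config(patch_size_raw = 96,
                                                  n_iters = 8))
  expect_identical(digital_refocus(cf, 0, 530), cf)
  f0 <- cf_complex(cf)
  f1 <- cf_complex(digital_refocus(digital_refocus(cf, 7, 530), -7, 530))
  expect_lt(vsfpm::nrmse(f1, f0), 1e-10)
  a <- digital_refocus(digital_refocus(cf, 3, 530), 4, 530)
  b <- digital_refocus(cf, 7, 530)
  expect_lt(vsfpm::nrmse(cf_complex(a), cf_complex(b)), 1e-10)
})

test_that("defocused capture is restored by opposite refocusing", {
  ph <- small_phantom()
  z <- 10
  # sample-side defocus: the section sits 10 um from the focal plane, so
  # the in-focus field propagates by +z before being imaged
  cf_obj <- complex_field(phantom_field(ph), ph$pixel_size, na_limit = 0.46)
  defoc <- digital_refocus(cf_obj, z, 530, warn_beyond_dof = FALSE)
  ph_z <- ph
  ph_z$amplitude <- defoc$amplitude; ph_z$phase <- defoc$phase
  st_z <- capture_stack(ph_z, ref_system(), small_plan(),
                        noise_params = list(shot = FALSE, read_sigma = 0))
  st_0 <- small_stack_noiseless()
  cfg <- recon_config(patch_size_raw = 96, n_iters = 12)
  cf_z <- gauss_newton_reconstruct(st_z, cfg)
  cf_0 <- gauss_newton_reconstruct(st_0, cfg)
  refoc <- digital_refocus(cf_z, -z, 530, warn_beyond_dof = FALSE)
  # compare within the sampled band after gauge alignment
  cov <- spectral_coverage(st_0)
  expect_lt(band_nrmse(cf_complex(refoc), cf_complex(cf_0), cov), 0.05)
})

test_that("phase flattening zeroes offsets, ramps and background", {
  flat <- phase_flatten(matrix(2.5, 64, 64))
  expect_true(all(flat == 0))
  expect_true(isTRUE(attr(flat, "flagged")))
  # pure linear ramp is removed in the interior
  ramp <- outer(seq(0, 4, length.out = 96), rep(1, 96))
  out <- phase_flatten(ramp)
  interior <- 20:76
  # normalised input ramp spans ~3.4 sd units; residual must be < 5% of it
  in_norm <- (ramp - mean(ramp)) / stats::sd(ramp)
  expect_lt(max(abs(out[interior, interior])),
            0.05 * diff(range(in_norm)))
  # output mean ~ 0 by construction
  set.seed(3)
  x <- matrix(stats::rnorm(96 * 96), 96, 96)
  out2 <- phase_flatten(x)
  expect_lt(abs(mean(out2)), 1e-6 * stats::sd(out2))
})

test_that("histogram matching aligns CDFs, is idempotent and near-identity", {
  set.seed(4)
  src <- matrix(stats::rbeta(96 * 96, 2, 5), 96, 96)
  ref <- matrix(stats::rbeta(96 * 96, 5, 2), 96, 96)
  out <- match_histogram(src, ref)
  # CDF sup-distance on the 256-level quantisation of the ref range
  qs <- function(x) stats::ecdf(x)(seq(min(ref), max(ref), length.out = 256))
  expect_lt(max(abs(qs(out) - qs(ref))), 2 / 256)
  out2 <- match_histogram(out, ref)
  expect_equal(out2, out, tolerance = 1 / 256)
  # identical histograms: output stays close to the input
  same <- match_histogram(src, src)
  expect_lt(max(abs(same - src)), diff(range(src)) / 256)
})

test_that("amplitude matching follows the brightfield reference", {
  st <- small_stack_noiseless()
  cf <- gauss_newton_reconstruct(st, recon_config(patch_size_raw = 96,
                                                  n_iters = 5))
  bf <- brightfield_sum(st)
  out <- amplitude_match(cf$amplitude, bf)
  expect_equal(dim(out), dim(cf$amplitude))
  expect_equal(stats::median(out), stats::median(bf), tolerance = 0.05 * diff(range(bf)))
})

test_that("stitching round-trips a 3x3 overlapping tiling", {
  ph <- reg_phantom()
  img <- ph$phase[1:300, 1:300]
  size <- 120; step <- 90
  offs <- expand.grid(r = c(1, 91, 181), c = c(1, 91, 181))
  patches <- lapply(seq_len(nrow(offs)), function(i)
    img[offs$r[i]:(offs$r[i] + size - 1), offs$c[i]:(offs$c[i] + size - 1)])
  ord <- c(5, 3, 8, 1, 9, 2, 7, 4, 6)           # shuffled placement order
  out <- stitch(patches[ord], as.matrix(offs)[ord, ])
  expect_equal(dim(out), dim(img))
  expect_lt(vsfpm::nrmse(out, img), 1e-3)
  # constant patches blend to a constant
  cpatch <- lapply(1:4, function(i) matrix(3.3, 64, 64))
  coffs <- rbind(c(1, 1), c(1, 49), c(49, 1), c(49, 49))
  cout <- stitch(cpatch, coffs)
  expect_equal(range(cout), c(3.3, 3.3), tolerance = 1e-12)
  # single patch is the identity
  expect_equal(stitch(patches[1], rbind(c(1, 1))), patches[[1]])
})

test_that("stitch offset refinement corrects a deliberate placement error", {
  ph <- reg_phantom()
  img <- ph$phase[1:200, 1:200]
  p1 <- img[1:200, 1:120]; p2 <- img[1:200, 81:200]
  out <- stitch(list(p1, p2), rbind(c(1, 1), c(1, 84)), refine_px = 5)
  expect_lt(vsfpm::nrmse(out, img), 0.02)
  expect_error(stitch(list(p1, p2), rbind(c(1, 1), c(300, 300)),
                      refine_px = 5), "overlap")
})

test_that("lens undistortion corrects synthetic grid targets", {
  # grid target: smooth bumps at lattice points
  n <- 200
  xs <- seq_len(n)
  bump <- function(c0) exp(-((xs - c0)^2) / 18)
  img <- outer(rowSums(sapply(seq(20, 180, by = 40), bump)),
               rowSums(sapply(seq(20, 180, by = 40), bump)))
  expect_equal(undistort(img), img)                    # zero coefficients
  dist <- distort_brown_conrady(img, k1 = 0.08, k2 = 0.01)
  und <- undistort(dist, k1 = 0.08, k2 = 0.01)
  # corner lattice points (worst case) must return within 0.2 px:
  # locate the outermost bump by centroid in a window
  centroid <- function(im, r0, c0, w = 9) {
    rs <- (r0 - w):(r0 + w); cs <- (c0 - w):(c0 + w)
    sub <- im[rs, cs]; sub <- sub - min(sub)
    c(sum(rs * rowSums(sub)) / sum(sub), sum(cs * colSums(sub)) / sum(sub))
  }
  for (pt in list(c(20, 20), c(180, 180), c(20, 180))) {
    p_true <- centroid(img, pt[1], pt[2])
    p_corr <- centroid(und, pt[1], pt[2])
    expect_lt(sqrt(sum((p_true - p_corr)^2)), 0.2)
  }
})

test_that("barrel-distorted lines straighten at least tenfold", {
  n <- 200
  img <- matrix(0, n, n)
  img[40, ] <- 1                      # a straight line off-centre
  img <- vsfpm:::gauss_blur(img, 1.5)
  dist <- distort_brown_conrady(img, k1 = 0.1)
  und <- undistort(dist, k1 = 0.1)
  line_dev <- function(im) {
    rows <- apply(im[20:60, 40:160], 2, function(col)
      sum(seq(20, 60) * col) / sum(col))
    fit <- stats::lm(rows ~ seq_along(rows))
    max(abs(stats::residuals(fit)))
  }
  expect_gt(line_dev(dist) / line_dev(und), 10)
})
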