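# FPM capture simulation: forward model, exposure/noise, brightfield sum,
# autofocus.

uniform_phantom <- function(n = 96) {
  structure(list(amplitude = matrix(1, n, n), phase = matrix(0, n, n),
                 nucleus_mask = matrix(FALSE, n, n),
                 tissue_mask = matrix(FALSE, n, n),
                 crypt_lumen = matrix(FALSE, n, n),
                 pixel_size = 0.319, seed = 0, params = list()),
            class = "tissue_phantom")
}

test_that("uniform object gives constant brightfield and dark darkfield frames", {
  st <- capture_stack(uniform_phantom(), ref_system(), small_plan(),
                      noise_params = list(shot = FALSE, read_sigma = 0))
  on_axis <- st$frames[[1]]
  expect_lt(diff(range(on_axis)), 1e-6 * mean(on_axis))
  expect_equal(mean(on_axis), 5000, tolerance = 1e-6)
  dfi <- which(!st$plan$is_brightfield)
  for (i in dfi[1:3]) expect_lt(max(st$frames[[i]]), 1e-12)
})

test_that("band-limited object under on-axis light reproduces its intensity", {
  ph <- small_phantom()
  # band-limit the complex transmission inside the objective passband
  fld <- lowpass_field(phantom_field(ph), 0.9 * 0.16 / 0.53, ph$pixel_size)
  ph2 <- ph
  ph2$amplitude <- Mod(fld); ph2$phase <- Arg(fld)
  plan1 <- build_led_plan(ref_array(), ref_system(), max_illum_na = 1e-6)
  st <- capture_stack(ph2, ref_system(), plan1,
                      noise_params = list(shot = FALSE, read_sigma = 0))
  frame <- st$frames[[1]] / st$photons_bf
  # oracle: ideally downsampled field intensity
  S <- vsfpm:::fftshift2(vsfpm:::fft2(phantom_field(ph2)))
  n <- st$sensor_shape; N <- st$object_shape
  r0 <- floor(N[1] / 2) + 1 - floor(n[1] / 2)
  c0 <- floor(N[2] / 2) + 1 - floor(n[2] / 2)
  sub <- S[r0:(r0 + n[1] - 1), c0:(c0 + n[2] - 1)]
  fld_lr <- stats::fft(vsfpm:::ifftshift2(sub), inverse = TRUE) /
    sqrt(length(sub)) * sqrt(prod(n) / prod(N))
  expect_lt(vsfpm::nrmse(frame, Mod(fld_lr)^2), 1e-6)
})

test_that("noiseless capture is deterministic and linear in exposure", {
  ph <- small_phantom()
  a <- capture_stack(ph, ref_system(), small_plan(),
                     noise_params = list(shot = FALSE, read_sigma = 0))
  b <- capture_stack(ph, ref_system(), small_plan(),
                     noise_params = list(shot = FALSE, read_sigma = 0))
  expect_identical(a$frames, b$frames)
  c2 <- capture_stack(ph, ref_system(), small_plan(), photons_bf = 10000,
                      noise_params = list(shot = FALSE, read_sigma = 0))
  expect_equal(c2$frames[[5]], 2 * a$frames[[5]], tolerance = 1e-12)
  # noisy capture is deterministic given the seed
  n1 <- capture_stack(ph, ref_system(), small_plan(), seed = 42)
  n2 <- capture_stack(ph, ref_system(), small_plan(), seed = 42)
  expect_identical(n1$frames, n2$frames)
  n3 <- capture_stack(ph, ref_system(), small_plan(), seed = 43)
  expect_false(identical(n1$frames, n3$frames))
})

test_that("phase-only object conserves energy through a covering pupil", {
  ph <- small_phantom()
  ph$amplitude <- matrix(1, 96, 96)
  # band-limit the phase well inside the pupil so the aperture passes all
  fld <- lowpass_field(phantom_field(ph), 0.5 * 0.16 / 0.53, ph$pixel_size)
  ph$amplitude <- Mod(fld); ph$phase <- Arg(fld)
  plan1 <- build_led_plan(ref_array(), ref_system(), max_illum_na = 1e-6)
  st <- capture_stack(ph, ref_system(), plan1,
                      noise_params = list(shot = FALSE, read_sigma = 0))
  total_in <- sum(ph$amplitude^2) / st$downsample_factor^2 * st$photons_bf
  expect_equal(sum(st$frames[[1]]), total_in, tolerance = 1e-6)
})

test_that("opposite illumination angles mirror for a real-amplitude object", {
  n <- 48
  set.seed(9)
  amp <- 0.8 + 0.2 * vsfpm:::gauss_blur(matrix(stats::runif(n * n), n, n), 2)
  ph <- structure(list(amplitude = amp, phase = matrix(0, n, n),
                       pixel_size = 0.319), class = "tissue_phantom")
  plan <- build_led_plan(ref_array(), ref_system(), max_illum_na = 0.25)
  st <- capture_stack(ph, ref_system(), plan, downsample_factor = 2,
                      noise_params = list(shot = FALSE, read_sigma = 0))
  # find an LED and its point reflection
  i <- which(st$plan$d > 0)[1]
  j <- which(abs(st$plan$x + st$plan$x[i]) < 1e-9 &
               abs(st$plan$y + st$plan$y[i]) < 1e-9)
  # Hermitian object spectrum + symmetric pupil: the low-res fields for
  # opposite illumination angles are complex conjugates, so the recorded
  # intensities coincide
  expect_lt(vsfpm::nrmse(st$frames[[i]], st$frames[[j]]), 1e-8)
})

test_that("brightfield sum rescales exposures and is permutation invariant", {
  st <- small_stack_noiseless()
  bs <- brightfield_sum(st)
  expect_equal(dim(bs), unname(st$sensor_shape))
  perm <- st
  ord <- rev(seq_along(st$frames))
  perm$frames <- st$frames[ord]
  perm$plan <- st$plan[ord, ]
  expect_equal(brightfield_sum(perm), bs, tolerance = 1e-12)
  # uniform phantom: sum of rescaled frames = n_brightfield * constant
  stu <- capture_stack(uniform_phantom(), ref_system(), small_plan(),
                       noise_params = list(shot = FALSE, read_sigma = 0))
  bsu <- brightfield_sum(stu)
  n_bf <- sum(stu$plan$is_brightfield)
  expect_equal(mean(bsu) / stu$photons_bf, n_bf, tolerance = 1e-6)
})

test_that("single-frame stack sums to itself", {
  plan1 <- build_led_plan(ref_array(), ref_system(), max_illum_na = 1e-6)
  st <- capture_stack(small_phantom(), ref_system(), plan1,
                      noise_params = list(shot = FALSE, read_sigma = 0))
  expect_equal(brightfield_sum(st), st$frames[[1]])
})

test_that("normalised variance is scale-invariant and zero for flat images", {
  expect_equal(autofocus_metric(matrix(3, 32, 32)), 0)
  set.seed(1)
  img <- matrix(stats::runif(1024), 32, 32)
  expect_equal(autofocus_metric(img), autofocus_metric(7 * img),
               tolerance = 1e-12)
  expect_error(autofocus_metric(matrix(0, 8, 8)), "zero-mean")
})

test_that("autofocus locates the true focal plane from darkfield frames", {
  ph <- small_phantom()
  ring_plan <- small_plan()[darkfield_ring_indices(small_plan()), ]
  class(ring_plan) <- c("led_plan", "data.frame")
  attr(ring_plan, "wavelength") <- 530
  zs <- seq(-20, 20, by = 5)
  frames_by_z <- lapply(zs, function(z) {
    pup <- make_pupil(ref_system(), 530, c(32, 32), 0.319 * 3, defocus = z)
    st <- capture_stack(ph, ref_system(), ring_plan, pupil = pup,
                        noise_params = list(shot = FALSE, read_sigma = 0))
    st$frames
  })
  af <- autofocus(frames_by_z, zs)
  expect_lte(abs(af$z_grid_star), 5)     # within one z-step of true focus
  expect_lte(abs(af$z_star), 5)
})
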