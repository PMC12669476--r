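# Optical-design geometry: magnification, LED selection, synthetic NA,
# depth of field, field of view, pupils, exposure scheduling.

test_that("effective magnification follows the tube-lens ratio", {
  expect_equal(effective_magnification(ref_system()), 4 * 200 / 180)
  expect_equal(round(effective_magnification(ref_system()), 2), 4.44)
  expect_equal(effective_magnification(optical_system(f_tube = 180)), 4)
  expect_equal(effective_magnification(
    optical_system(mag_nominal = 20)), 20 * 200 / 180)
  expect_error(optical_system(f_tube = -1), "focal")
})

test_that("LED plan selection by NA ceiling reproduces the 177-LED circle", {
  plan <- ref_plan()
  expect_equal(nrow(plan), 177)
  expect_true(all(diff(plan$d) >= 0))
  expect_true(all(abs(plan$illum_na - plan$d / sqrt(plan$d^2 + 81^2)) < 1e-12))
  # brute-force enumeration oracle: grid points with d/sqrt(d^2+h^2) <= NA
  off <- (-10):11
  g <- expand.grid(i = off, j = off)
  d <- 7 * sqrt(g$i^2 + g$j^2)
  expect_equal(sum(d / sqrt(d^2 + 81^2) <= 0.54), 177)
})

test_that("LED plan selection by count matches the sort-by-radius oracle", {
  plan <- build_led_plan(ref_array(), ref_system(), n_leds = 177)
  expect_equal(nrow(plan), 177)
  expect_equal(max(plan$d), sqrt(53) * 7, tolerance = 1e-12)
  # count inside an equal-radius shell snaps to the nearest attainable
  expect_warning(p2 <- build_led_plan(ref_array(), ref_system(), n_leds = 2),
                 "shell")
  expect_true(nrow(p2) %in% c(1, 5))
  expect_error(build_led_plan(ref_array(), ref_system(), n_leds = 1e5),
               "extent")
  expect_error(build_led_plan(ref_array(), ref_system()), "exactly one")
})

test_that("count and NA selection criteria agree on the same set", {
  plan_na <- ref_plan()
  plan_n <- build_led_plan(ref_array(), ref_system(), n_leds = 177)
  expect_equal(plan_n$x, plan_na$x)
  expect_equal(plan_n$y, plan_na$y)
  # and the NA of the outermost LED of the count-selected set round-trips
  plan_rt <- build_led_plan(ref_array(), ref_system(),
                            max_illum_na = max(plan_n$illum_na))
  expect_equal(nrow(plan_rt), 177)
})

test_that("synthetic NA is NAobj plus the outermost illumination sine", {
  plan <- ref_plan()
  expect_equal(synthetic_na(ref_system(), plan),
               0.16 + 50.96077 / sqrt(50.96077^2 + 81^2), tolerance = 1e-5)
  expect_equal(round(synthetic_na(ref_system(), plan), 1), 0.7)
  on_axis <- build_led_plan(ref_array(), ref_system(), max_illum_na = 1e-6)
  expect_equal(nrow(on_axis), 1)
  expect_equal(synthetic_na(ref_system(), on_axis), 0.16)
  expect_equal(on_axis$kx, 0)
  expect_equal(on_axis$ky, 0)
  # single LED at 45 degrees
  arr1 <- led_array(n_rows = 1, n_cols = 2, pitch = 81, height = 81)
  p45 <- build_led_plan(arr1, ref_system(), n_leds = 2)
  expect_equal(synthetic_na(ref_system(), p45), 0.16 + sin(pi / 4),
               tolerance = 1e-12)
})

test_that("synthetic NA is monotone in the number of selected LEDs", {
  nas <- vapply(c(9, 45, 97, 177), function(n)
    synthetic_na(ref_system(),
                 build_led_plan(ref_array(), ref_system(), n_leds = n)),
    numeric(1))
  expect_true(all(diff(nas) >= 0))
})

test_that("brightfield flags and wavevector magnitudes are consistent", {
  plan <- ref_plan()
  lam_um <- 0.53
  kmag <- sqrt(plan$kx^2 + plan$ky^2)
  expect_true(all(kmag <= max(plan$illum_na) / lam_um + 1e-9))
  expect_equal(plan$is_brightfield, kmag * lam_um <= 0.16 + 1e-12)
  expect_equal(sum(plan$is_brightfield), 9)
})

test_that("depth of field follows lambda over NA squared", {
  expect_equal(depth_of_field(ref_system(), 530), 0.53 / 0.16^2)
  expect_equal(round(depth_of_field(ref_system(), 530)), 21)
  expect_equal(depth_of_field(optical_system(na_obj = 0.73), 530),
               0.53 / 0.73^2, tolerance = 1e-12)
  # doubling NA quarters the DOF
  expect_equal(depth_of_field(optical_system(na_obj = 0.32), 530),
               depth_of_field(ref_system(), 530) / 4)
})

test_that("field of view is the demagnified sensor extent", {
  fov <- field_of_view(ref_system())
  expect_equal(round(fov[["x"]], 1), 4.8)
  expect_equal(round(fov[["y"]], 1), 2.8)
  sys1 <- optical_system(mag_nominal = 1, f_tube = 180,
                         pixel_pitch_camera = 1, sensor_shape = c(1000, 1000))
  expect_equal(unname(field_of_view(sys1)), c(1, 1))
  sys2 <- optical_system(mag_nominal = 8)
  expect_equal(field_of_view(sys2) * 2, field_of_view(optical_system()))
})

test_that("pupil is a unit disk with invertible defocus phase", {
  pup <- make_pupil(ref_system(), 530, c(64, 64), 0.957)
  expect_true(all(Mod(pup$grid) %in% c(0, 1)))
  expect_true(all(Arg(pup$grid[Mod(pup$grid) > 0]) == 0))
  # energy equals the pixel count of the disk
  expect_equal(sum(Mod(pup$grid)^2), sum(pup$kr <= pup$cutoff))
  pz <- make_pupil(ref_system(), 530, c(64, 64), 0.957, defocus = 10)
  pm <- make_pupil(ref_system(), 530, c(64, 64), 0.957, defocus = -10)
  expect_equal(pz$grid * pm$grid, pup$grid * pup$grid, tolerance = 1e-12)
  expect_error(make_pupil(optical_system(na_obj = 0.9), 530, c(64, 64), 0.957),
               "Nyquist")
})

test_that("exposure schedule scales darkfield frames by squared distance", {
  plan <- ref_plan()
  expo <- exposure_schedule(plan, t_bf = 2)
  expect_equal(expo[1], 2)                     # on-axis LED gets TBF
  expect_true(all(expo[plan$is_brightfield] == 2))
  df <- !plan$is_brightfield
  d_edge <- 81 * 0.16 / sqrt(1 - 0.16^2)
  expect_equal(expo[df], pmax(2, 2 * (plan$d[df] / d_edge)^2))
  # dn doubled -> exposure x4 (darkfield regime)
  i1 <- which(df & abs(plan$d - 21) < 0.5)[1]
  i2 <- which(df & abs(plan$d - 42) < 0.5)[1]
  expect_equal(expo[i2] / expo[i1], (plan$d[i2] / plan$d[i1])^2,
               tolerance = 1e-12)
})

test_that("intensity rescaling inverts the exposure schedule", {
  plan <- ref_plan()
  frames <- lapply(plan$exposure_scale, function(s) matrix(s, 4, 4))
  rs <- rescale_intensity(frames, plan)
  for (f in rs) expect_equal(f, matrix(1, 4, 4))
  expect_error(rescale_intensity(frames[1:3], plan), "match")
})
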