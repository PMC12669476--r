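# Shared fixtures, generated in code and cached per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- fn()
  fixture_cache[[key]]
}

ref_system <- function() optical_system()
ref_array <- function() led_array()

ref_plan <- function() {
  cached("ref_plan", function()
    build_led_plan(ref_array(), ref_system(), max_illum_na = 0.54))
}

# small LED plan + phantom + noiseless stack for solver tests
small_plan <- function() {
  cached("small_plan", function()
    build_led_plan(ref_array(), ref_system(), max_illum_na = 0.3))
}

small_phantom <- function() {
  cached("small_phantom", function()
    generate_phantom(shape = c(96, 96), seed = 2))
}

small_stack_noiseless <- function() {
  cached("small_stack_noiseless", function()
    capture_stack(small_phantom(), ref_system(), small_plan(),
                  noise_params = list(shot = FALSE, read_sigma = 0),
                  seed = 3))
}

reg_phantom <- function() {
  cached("reg_phantom", function() generate_phantom(shape = c(320, 320), seed = 5))
}

# low-pass filter a (possibly complex) field to a hard circular band
lowpass_field <- function(x, cutoff_cycles_um, pixel_size) {
  kr <- vsfpm:::freq_radius(nrow(x), ncol(x), pixel_size)
  S <- vsfpm:::fftshift2(vsfpm:::fft2(x))
  S[kr > cutoff_cycles_um] <- 0
  stats::fft(vsfpm:::ifftshift2(S), inverse = TRUE) / sqrt(length(S))
}

# white noise band-limited at `frac` of Nyquist (pixel units)
bandlimited_noise <- function(n, frac, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * n), n, n)
  kr <- vsfpm:::freq_radius(n, n, 1) / 0.5
  S <- vsfpm:::fftshift2(vsfpm:::fft2(x))
  S[kr > frac] <- 0
  Re(stats::fft(vsfpm:::ifftshift2(S), inverse = TRUE) / sqrt(n * n))
}

smoke_pairs <- function(n = 16, size = 32) {
  cached(paste0("smoke_pairs_", n, "_", size), function() {
    lapply(seq_len(n), function(s) {
      ph <- generate_phantom(shape = c(64, 64), seed = s)
      hne <- render_hne(ph)
      list(phase_patch = ph$phase[seq_len(size), seq_len(size)],
           rgb_patch = hne$rgb[seq_len(size), seq_len(size), , drop = FALSE])
    })
  })
}

smoke_cfg <- function(epochs = 50, seed = 7) {
  vs_config(width = 8, depth = 4, disc_width = 8, disc_strides = c(2, 2, 1),
            epochs = epochs, jitter_px = 2, tile_size = 32, seed = seed,
            lr = 1e-3)
}
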