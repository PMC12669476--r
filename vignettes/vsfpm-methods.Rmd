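---
title: "Models and methods behind vsfpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vsfpm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vsfpm simulates and analyses a virtual-staining Fourier-ptychography
pipeline end to end on synthetic tissue phantoms. This vignette documents
the models it implements, the defaults it ships, the numerical choices
behind them, and what its passing tests do — and do not — say about real
data.

## Optical geometry

The instrument model is an LED-array transmission microscope: a low-NA
objective (default 4×/0.16, designed for a 180 mm tube lens but used with
a 200 mm one, so the effective magnification is 4 × 200/180 = 4.44) and a
planar LED array (default 22 × 22 LEDs at 7 mm pitch, 81 mm below the
sample). An LED at in-plane distance d illuminates the sample at
sin θ = d/√(d² + h²), contributing the spatial-frequency offset
(sin θ)/λ in cycles/µm. The synthetic aperture is NA_syn = NA_obj +
sin θ_max. We write the coherent cutoff of an aperture as NA/λ throughout
— the dimensionally consistent form of the resolution limit.

Two conventions are fixed once and used everywhere: image arrays are
indexed (row, col) = (−y, x); Fourier grids are kept in centre-origin
(fftshift) order with unitary FFTs, so Parseval's identity holds without
bookkeeping factors.

**LED-grid centering.** With one LED on the optical axis (`on_led`), the
selection of all LEDs whose illumination NA is at most 0.54 contains
exactly 177 LEDs and yields NA_syn ≈ 0.69 — matching the reference
instrument; this is therefore the default, with `between_leds` available.
Equal-radius LED shells are treated as indivisible: a count criterion that
lands inside a shell snaps to the nearest attainable count with a warning,
which keeps count- and NA-based selection exactly consistent.

**Exposure scheduling.** Darkfield frames are weak, so their exposure
grows with the squared LED distance, T_n = T_BF · (d_n/d_edge)², where
d_edge is the radius at which the illumination NA equals the objective NA;
brightfield frames stay at T_BF and darkfield exposures are clamped to at
least T_BF. Only the proportionality is physically mandated; the
normalisation by d_edge is the package's choice of where the darkfield
regime begins. Captured intensities are divided by T_n/T_BF before use.

## Tissue phantom

The generator emulates the features a colonic-polyp section presents to a
phase microscope: a tissue blob with band-limited stromal texture,
crypt-like annuli lined with ellipsoidal nuclei, and scattered stromal
nuclei. Nuclei receive **lower** phase than cytoplasm (factor 0.55),
reflecting the lower refractive index of nuclei relative to cytoplasm that
makes them visible in quantitative phase images. The peak cytoplasm phase
defaults to 1.5 rad so the section stays in the thin-object regime the
forward model assumes. Background outside the tissue mask is exactly
(amplitude 1, phase 0).

The chemically stained twin uses a Beer–Lambert model: per-channel optical
density is hematoxylin concentration on the (slightly blurred) nucleus
mask plus eosin on the remaining tissue, with standard H&E absorbance unit
vectors (hematoxylin (0.650, 0.704, 0.286), eosin (0.072, 0.990, 0.105) in
RGB); transmittance is exp(−OD), so densities add across stains and the
image can never exceed white. Staining also perturbs the *phase* of a real
section; this is modelled phenomenologically as a Gaussian blur (σ = 2 px)
plus contrast reduction (×0.6) of the unstained phase. These two
parameters are exposed and make no claim to be physical — they exist so
that cross-modality registration and pair curation face a realistic
difficulty (blurred, contrast-reduced counterpart) with known ground
truth.

What the phantom does **not** emulate: 3-D thickness, real staining
chemistry and its variability, scanner colour gamuts, mounting artefacts,
or histological diversity. Tests passing on phantoms validate the
*computational pipeline*, not tissue-level image quality; the package
deliberately makes no claim about SSIM or resolution of real virtually
stained tissue.

## Forward capture model

Per LED n the sensor sees |IFT{P(k) · Ô(k − k_n)}|²: the object spectrum
shifted by the illumination wavevector, clipped by the pupil, and
propagated to the sensor grid. Two design choices matter:

* **Integer spectrum shifts.** k_n is rounded to whole pixels of the
  object Fourier grid (residuals are stored in metadata). This matches
  common FPM practice and makes the forward model *exactly* invertible by
  the reconstruction — the inverse-crime tests rely on it.
* **Fourier-cropping downsampling.** The sensor image is formed by taking
  the central sensor-band window of the object spectrum, i.e. ideal
  anti-aliased sampling, which is exactly the operation the solver
  inverts.

Noise defaults: Poisson shot noise on (5 000 mean brightfield
photoelectrons per pixel for a transparent sample), Gaussian read noise
σ = 2 e⁻, full well 30 000 e⁻. These are generic sCMOS figures, chosen
once; the noiseless switch (`shot = FALSE, read_sigma = 0`) gives the
deterministic model used by solver-accuracy tests.

Autofocus uses the normalised variance var(I)/mean(I)² of the summed
darkfield-ring image over a focus series, with parabolic peak refinement.
The ring is the innermost fully-darkfield LED shell by default — the
choice is configurable because nothing pins it down physically.

## Reconstruction

The solver is a sequential (per-LED) second-order phase-retrieval
iteration: forward-model the low-resolution field, replace its modulus
with √I keeping phase, and back-propagate the spectral residual with
magnitude-adaptive regularised steps

    O ← O + |P| P̄ / ( max|P| (|P|² + α max|P|²) ) · Δ
    P ← P + |O| Ō / ( max|O| (|O|² + β max|O|²) ) · Δ     (optional)

with α = β = 10⁻³. For the ideal unit-modulus pupil the object step
reduces to the familiar P̄·Δ. LEDs are visited from low to high |k_n| (the
brightfield frames anchor the low-frequency estimate first); 10 epochs by
default; the per-epoch data misfit Σ(√I_model − √I_obs)² is recorded, and
three consecutive increases trigger a warning and return of the best
iterate.

**What "in-band accuracy" means.** The acquisition only measures
frequencies inside the union of pupil disks shifted to each LED position.
That union's outer envelope reaches NA_syn, but thin gaps remain between
the outermost pupil positions (about 9 % of the NA_syn disk for the
45-LED test geometry). No solver can recover what was never measured, so
all reconstruction-accuracy statements are made on the sampled passband
(`spectral_coverage()`), after resolving the global phase/scale gauge by
least squares (`align_global_phase()` / `band_nrmse()`). On noiseless
inverse-crime data the solver is then accurate to ~10⁻⁶; the <1 %
acceptance bound is passed with two orders of magnitude to spare.

**Joint pupil recovery** converges much more slowly than object-only
reconstruction because object and pupil updates initially trade off; the
astigmatism-recovery test runs 80 epochs and requires phase correlation
with the true aberration above 0.9.

**Defocus.** Two distinct defocus mechanisms exist and are kept separate:
camera-side defocus (the focus scanner) enters as a pupil phase
exp(i·2π/λ·z·√(1 − λ²k²)) on image-space frequencies and is what the
autofocus scan varies; sample-side defocus (section not at the focal
plane) propagates the object field itself and is what `digital_refocus()`
inverts after reconstruction. The refocus transfer is phase-only inside
the propagating band and identity outside, so refocusing is exactly
unitary and additive in z.

Post-processing follows the patchwise recipe: phase patches are
normalised (mean 0, SD 1) and a Gaussian-blurred copy (31 px kernel,
σ = 31/6 — the size-only specification is interpreted as the usual
kernel ≈ 6σ truncation) is subtracted, zeroing offsets, ramps and
background; with circular filtering boundaries the flattened patch is
mean-zero by construction. Amplitude patches are histogram-matched to the
upsampled brightfield sum of the same region. Histogram matching maps
each pixel through its mid-rank empirical CDF to the linearly
interpolated reference quantile — chosen over per-bin lookup because it
makes self-matching the exact identity and bounds the CDF mismatch by
1/n rather than by the largest histogram bin. Patches are stitched with
separable linear edge ramps (optional integer phase-correlation offset
refinement); Brown–Conrady radial/tangential distortion is corrected by
forward-mapping each undistorted pixel (the simulation side inverts the
model by fixed-point iteration, so round trips are testable).

## Registration and pair curation

Keypoints are multi-scale difference-of-Gaussian extrema (6 scales from
σ = 1.6, step √2) with low-contrast and edge rejection and subpixel
quadratic refinement; descriptors are the classic 4 × 4 × 8
gradient-orientation histograms (Gaussian-weighted, clipped at 0.2,
renormalised) in an *upright* variant — no dominant-orientation
assignment, appropriate for slide remounting where rotation is small and
implemented entirely in-package. Matching uses Lowe's 0.75 ratio test;
the perspective transform comes from RANSAC (3 px reprojection threshold,
0.995 confidence, normalised DLT via the 9 × 9 normal-matrix null space)
followed by least squares on the inliers, and registration fails loudly
below 8 inliers. A final refinement pass measures residual subpixel
shifts between the warped moving image and the fixed image with windowed
phase correlation on an 8 × 8 grid of 64 px patches and re-estimates the
homography from those dense correspondences; 64 px patches are the
default because blurred cross-modality content gives smaller patches too
little texture to lock onto. Same-modality recovery lands near 0.05 px
mean corner error, cross-stain-model recovery near 0.3 px.

Mutual information is computed in **bits** from the 64 × 64 joint
histogram of min–max-scaled patches; the 0.4 acceptance cutoff is
interpreted on that estimator, and configuring a different one warns that
the default cutoff was calibrated for it. Tissue-free background patches
are constant-to-near-constant, carry no mutual information, and fall
below any positive cutoff, which is what makes MI curation double as a
background filter. Acceptance is monotone in the cutoff by construction.

Chromatic alignment warps red and blue onto green via keypoint least
squares (full affine, or restricted similarity/translation modes) or
subpixel phase correlation (translation); white balance divides each
channel by its background-RoI mean and clips to [0, 1], making it
idempotent.

## Virtual staining

The stainer is a pix2pix-style conditional GAN, implemented on a compact
in-package conv-net framework (im2col convolutions,
nearest-neighbour-upsample decoding — a standard checkerboard-free
alternative to strided transposed convolutions — batch-size-1
normalisation with momentum-tracked running statistics, Adam). Generator:
U-Net, channels w·min(2^(i−1), 8) per level; discriminator: 70 × 70
receptive-field patch critic (strides 2,2,2,1 plus a 1-stride output
layer). The objective is the non-saturating adversarial term plus
λ · L1 with λ = 100; Adam defaults are lr 2 × 10⁻⁴, β = (0.5, 0.999).
Phase inputs are robustly scaled to [−1, 1] by the pooled 1st/99th
training percentiles (stored with the model, and checked at inference —
a field far outside the training range raises a normalisation-mismatch
error); targets map linearly to [−1, 1]; augmentation is reflect-padded
random crop-jitter plus horizontal/vertical mirroring. Training is
deterministic given the config seed.

At inference the running normalisation statistics are frozen
(batch-size-1 training with eval-time running statistics — the behaviour
of the classic architecture), which is what makes tiled and untiled
inference agree: without it, per-tile statistics couple every output
pixel to the tile content. Tiles overlap by 64 px and blend through the
stitcher. Exact tile-interior equality is unattainable for a U-Net whose
bottleneck sees the whole tile, so the equivalence contract is a
tolerance (interior max difference below 0.05 for the trained smoke
model), not bit-equality.

**Desk-scale surface.** The GAN tests run a smoke configuration — width
8, depth 4, 16 pairs of 32 × 32 patches, 50 epochs, lr 10⁻³ — sized so
the overfit oracle (epoch-1 L1 must drop at least 4×; it drops ~15×)
and the tiling equivalence run in about a minute. The higher smoke
learning rate is a property of the tiny-problem optimisation landscape,
not of the full-scale defaults, which remain the classic ones. Nothing at
this scale supports claims about staining fidelity on real tissue; that
is exactly why tissue-level similarity numbers are out of the test
surface.

## Evaluation metrics

SSIM is computed **globally per patch** exactly as the single-window
formula is written, with C1 = (0.01 R)², C2 = (0.03 R)² and population
moments — per-patch evaluation of 256² tiles is the use case, and a
sliding-window variant is provided but non-default. RMSE, PSNR
(10·log₁₀(R²/RMSE²)) and PCC follow their definitions; all four agree
with independent brute-force oracles to 10⁻¹². Grayscale conversion is
the fixed luma combination Y = 0.299 R + 0.587 G + 0.114 B. Colour
differences use CIE76 ΔE (Euclidean distance in Lab), with sRGB/D65
conversion delegated to `grDevices::convertColor`; the ΔE formula version
is the package's choice since nothing pins it down.

Resolution is estimated by decorrelation analysis: d(r) is the
normalised zero-lag correlation between the image spectrum and its
amplitude-normalised copy restricted to a circular mask of radius r;
repeating over Gaussian high-pass pre-filters (10 filters, image-domain
σ geometric from 0.15 to 5 px) traces where signal beats noise, and the
cutoff is the highest-frequency local maximum across all curves (Hann
apodisation; 50 radii; interior maxima need a 10⁻³ prominence, and a
curve still rising at Nyquist counts as peaking there, which is what
full-band noise produces). Constructed band limits are recovered within
10 % across seeds; a structureless image has no maxima and returns a
flagged `NA`. Patch grids for similarity statistics exclude background
by Otsu thresholding on the mean grayscale image.

Welch's t test delegates to `stats::t.test(var.equal = FALSE)`; an
independent hand-coded Welch–Satterthwaite oracle lives in the tests.

## Problem sizes and runtime

The suite runs at deliberately small scale: 96² phantoms for solver
tests (45-LED plan), 320² for registration, 510² with the full 177-LED
plan for the resolution-gain experiment, and the smoke GAN configuration
above — the full test suite takes on the order of 1–2 minutes, and the
acceptance script a few minutes, on one CPU. All randomness is seeded;
generators restore the global RNG state on exit.

## Known limitations

* The phantom is a caricature of tissue; none of its parameters are fitted
  to histology.
* The forward model is thin-object and fully coherent per LED: no partial
  coherence from finite LED extent, no sensor PRNU/dark current, no
  vignetting or stray light.
* Keypoint description is upright; registration robustness is untested
  beyond a few degrees of rotation.
* The stained-phase model (blur + contrast scale) is phenomenological.
* Joint pupil recovery is slow to converge and was validated only on
  noiseless data with a single low-order aberration.
* LPIPS-style learned perceptual metrics require pretrained external
  networks and are deliberately absent.
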