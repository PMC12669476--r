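Package: vsfpm
Title: Fourier Ptychographic Microscopy Simulation and Virtual Staining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for virtual histological staining
    with Fourier ptychographic microscopy (FPM). Models the LED-array
    illumination geometry and exposure scheduling of an FPM platform, generates
    seeded synthetic tissue phantoms with Beer-Lambert H&E rendering, simulates
    raw multi-LED intensity stacks with shot and read noise, reconstructs
    high-resolution complex fields by sequential Gauss-Newton phase retrieval
    with optional pupil recovery, registers unstained-phase to stained images
    with multi-scale keypoint matching and RANSAC homographies, curates
    conditional-GAN training pairs by mutual information, trains a compact
    pix2pix-style U-Net generator with a patch discriminator, and evaluates
    results with SSIM/RMSE/PSNR/PCC, CIE Lab colour differences and
    decorrelation-analysis resolution estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
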