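# Keypoint registration, mutual information, pair curation, chromatic
# alignment, white balance and colour histogram matching.

test_that("an image registers to itself with a near-identity homography", {
  img <- reg_phantom()$phase
  reg <- register_perspective(img, img, contrast_thresh = 0.005)
  expect_lt(hg_corner_error(reg$H, diag(3), dim(img)), 0.1)
  expect_gte(reg$n_inliers, 8)
})

test_that("known same-modality homographies are recovered within 0.5 px", {
  img <- reg_phantom()$phase
  for (s in c(11, 31)) {
    Ht <- random_homography(dim(img), seed = s)
    fixed <- misalign(img, Ht)$image
    reg <- register_perspective(img, fixed, contrast_thresh = 0.005)
    expect_lt(hg_corner_error(reg$H, Ht, dim(img)), 0.5)
  }
})

test_that("cross-stain-model registration recovers the transform within 1 px", {
  ph <- reg_phantom()
  stained <- render_hne(ph)
  Ht <- random_homography(dim(ph$phase), seed = 12)
  fixed <- misalign(stained$phase_stained, Ht)$image
  reg <- register_perspective(ph$phase, fixed, contrast_thresh = 0.005)
  expect_lt(hg_corner_error(reg$H, Ht, dim(ph$phase)), 1)
})

test_that("registration failure raises a diagnostic error", {
  set.seed(6)
  a <- matrix(stats::runif(128 * 128), 128, 128)
  b <- matrix(stats::runif(128 * 128), 128, 128)
  expect_error(register_perspective(a, b), "registration failure|consensus")
})

test_that("mutual information has the identity and independence properties", {
  img <- small_phantom()$phase
  mi_self <- mutual_information(img, img)
  ent <- image_entropy(img)
  expect_equal(mi_self, ent, tolerance = 1e-9)
  # MI(a, b) <= H(a) for any b
  other <- render_hne(small_phantom())$phase_stained
  expect_lte(mutual_information(img, other), ent + 1e-9)
  # independent noise: MI is only the sampling bias, < 0.1 bits at 256^2/64
  set.seed(8)
  n1 <- matrix(stats::runif(256 * 256), 256, 256)
  n2 <- matrix(stats::runif(256 * 256), 256, 256)
  expect_lt(mutual_information(n1, n2, 64), 0.1)
  # invariance to monotone remapping (within binning error)
  expect_equal(mutual_information(img, other),
               mutual_information(img^3, other), tolerance = 0.05)
  # constant image flags MI = 0
  flat <- mutual_information(img, img * 0)
  expect_equal(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "flagged")))
})

test_that("pair curation accepts tissue and rejects background", {
  ph <- cached("curate_phantom", function()
    generate_phantom(shape = c(512, 512), n_crypts = 6,
                     nucleus_density = 8, seed = 13))
  hne <- render_hne(ph)
  pp <- curate_pairs(ph$phase, hne$phase_stained, hne$rgb, patch_size = 128)
  # tissue-covered patches: fraction of tissue >= 60%
  tissue_frac <- vapply(seq_len(nrow(pp$manifest)), function(i) {
    r <- pp$manifest$row[i]; cc <- pp$manifest$col[i]
    mean(ph$tissue_mask[r:(r + 127), cc:(cc + 127)])
  }, numeric(1))
  expect_gte(mean(pp$manifest$accepted[tissue_frac >= 0.6]), 0.9)
  # a background-only patch scores 0 and is rejected
  bg <- matrix(0, 128, 128)
  mi_bg <- mutual_information(bg, bg)
  expect_equal(as.numeric(mi_bg), 0)
  # cutoff 0 accepts everything; acceptance is monotone in the cutoff
  pp0 <- curate_pairs(ph$phase, hne$phase_stained, hne$rgb,
                      patch_size = 128, mi_cutoff = 0)
  expect_true(all(pp0$manifest$accepted))
  pp_hi <- curate_pairs(ph$phase, hne$phase_stained, hne$rgb,
                        patch_size = 128, mi_cutoff = 0.8)
  expect_lte(sum(pp_hi$manifest$accepted), sum(pp$manifest$accepted))
  expect_lte(sum(pp$manifest$accepted), sum(pp0$manifest$accepted))
})

test_that("recovered homographies are gauge-consistent with the truth", {
  img <- reg_phantom()$phase
  Ht <- random_homography(dim(img), seed = 41)
  fixed <- misalign(img, Ht)$image
  reg <- register_perspective(img, fixed, contrast_thresh = 0.005)
  comp <- solve(Ht) %*% reg$H          # should be ~identity
  comp <- comp / comp[3, 3]
  expect_lt(hg_corner_error(comp, diag(3), dim(img)), 0.5)
})

test_that("chromatic alignment recovers identity, shifts and scales", {
  img <- reg_phantom()$phase
  # identical channels: identity transform
  ca0 <- chromatic_align(img, img, img, mode = "translation")
  expect_equal(ca0$transforms$r, diag(3), tolerance = 0.05)
  # known (2.0, -1.5) px offset recovered within 0.2 px
  Hs <- rbind(c(1, 0, 2), c(0, 1, -1.5), c(0, 0, 1))
  r_ch <- misalign(img, Hs)$image
  ca <- chromatic_align(r_ch, img, img, mode = "translation")
  expect_equal(ca$transforms$r[1, 3], -2, tolerance = 0.2)
  expect_equal(ca$transforms$r[2, 3], 1.5, tolerance = 0.2)
  # restricted similarity mode recovers a pure 1.002 chromatic scale
  ctr <- (dim(img)[1] + 1) / 2
  Hsc <- rbind(c(1.002, 0, (1 - 1.002) * ctr),
               c(0, 1.002, (1 - 1.002) * ctr), c(0, 0, 1))
  r_sc <- misalign(img, Hsc)$image
  ca2 <- chromatic_align(r_sc, img, img, mode = "similarity")
  s_rec <- sqrt(abs(det(ca2$transforms$r[1:2, 1:2])))
  expect_equal(s_rec, 1 / 1.002, tolerance = 1e-3)
})

test_that("white balance restores cast backgrounds and is idempotent", {
  set.seed(10)
  rgb <- array(0.95, c(64, 64, 3))
  rgb[20:40, 20:40, ] <- 0.3          # some tissue
  roi <- list(rows = 1:10, cols = 1:10)
  # already white: identity up to clipping
  wb0 <- white_balance(rgb / 0.95, roi)
  expect_equal(wb0[1, 1, ], c(1, 1, 1))
  # uniform colour cast removed
  cast <- rgb
  for (ch in 1:3) cast[, , ch] <- rgb[, , ch] * c(0.9, 0.8, 0.7)[ch] / 0.95
  wb <- white_balance(cast, roi)
  expect_equal(as.numeric(wb[1, 1, ]), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(white_balance(wb, roi), wb, tolerance = 1e-12)
  expect_error(white_balance(array(0, c(8, 8, 3)), list(rows = 1:4, cols = 1:4)),
               "zero-mean")
})

test_that("colour histogram matching is per-channel and idempotent", {
  set.seed(11)
  src <- array(stats::rbeta(48 * 48 * 3, 2, 4), c(48, 48, 3))
  ref <- array(stats::rbeta(48 * 48 * 3, 4, 2), c(48, 48, 3))
  out <- histogram_match_color(src, ref)
  for (ch in 1:3) {
    qs <- function(x) stats::ecdf(x)(seq(min(ref[, , ch]), max(ref[, , ch]),
                                         length.out = 256))
    expect_lt(max(abs(qs(out[, , ch]) - qs(ref[, , ch]))), 2 / 256)
  }
  out2 <- histogram_match_color(out, ref)
  expect_equal(out2, out, tolerance = 1 / 256)
  same <- histogram_match_color(src, src)
  expect_lt(max(abs(same - src)), 1 / 256 * 2)
})
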