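test_that("kernel tiling enumerates exactly the fully contained windows", {
  cfg <- sfa_config()
  expect_equal(nrow(tile_kernels(rect_roi(0, 0, 31, 31), c(64, 64), cfg)), 1L)
  o <- tile_kernels(rect_roi(0, 0, 39, 39), c(64, 64), cfg)
  expect_equal(nrow(o), 81L)  # 9 x 9 grid, brute-force enumeration
  expect_equal(o[1, ], c(row = 0L, col = 0L))
  # row-major order
  expect_true(all(diff(o[, "row"]) >= 0))
  tri <- rbind(c(0, 0), c(20, 0), c(0, 20))
  expect_warning(o2 <- tile_kernels(tri, c(64, 64), cfg), "no kernel")
  expect_equal(nrow(o2), 0L)
})

test_that("the radial high-pass hits -3 dB at the cutoff and kills DC", {
  expect_identical(butterworth_highpass(1.0, cutoff = 1.0, order = 2L),
                   2^(-1 / 2))
  expect_equal(butterworth_highpass(0, 1, 2), 0)
  expect_lt(butterworth_highpass(0.5, 1, 2), 0.07)
  expect_gt(butterworth_highpass(2.0, 1, 2), 0.99)
})

test_that("constant kernels carry no peak; gratings peak at their frequency", {
  img <- us_image(matrix(100, 64, 64))
  ks <- kernel_spectrum(img, c(0, 0))
  expect_true(all(ks$magnitude == 0))
  expect_true(is.na(psfr_from_spectrum(ks)))

  # axial cosine grating with period 0.5 mm: peak radius exactly 16 bins
  g <- make_grating_image(0.5)
  expect_equal(psfr_from_spectrum(kernel_spectrum(g, c(8, 8))), 2.0)
})

test_that("peak selection follows the stated tie and no-peak rules", {
  m <- matrix(0, 128, 128)
  sp <- fake_spectrum(m)
  expect_true(is.na(psfr_from_spectrum(sp)))       # all-zero spectrum

  m1 <- m; m1[17, 1] <- 5                          # (f_ax = 2.0, f_lat = 0)
  expect_equal(psfr_from_spectrum(fake_spectrum(m1)), 2.0)

  m2 <- m; m2[13, 1] <- 5; m2[21, 1] <- 5          # radii 1.5 and 2.5
  expect_equal(psfr_from_spectrum(fake_spectrum(m2)), 1.5)

  # equal radius, different angle: the more axial bin wins
  m3 <- m; m3[1, 17] <- 5; m3[17, 1] <- 5          # angles 90 and 0 deg
  sp3 <- fake_spectrum(m3)
  expect_equal(psfr_from_spectrum(sp3), 2.0)
})

test_that("filtered spectra match a brute-force O(N^4) DFT oracle", {
  set.seed(31)
  cfg <- sfa_config(kernel_px = 8L, pad_px = 16L)
  pix <- matrix(stats::runif(24 * 24, 0, 255), 24, 24)
  img <- us_image(pix)
  ks <- kernel_spectrum(img, c(3, 5), cfg)
  oracle <- brute_filtered_spectrum(pix[4:11, 6:13], 16, 0.0625)
  expect_lt(max(abs(ks$magnitude - oracle)), 1e-9)
})

test_that("transform plumbing conserves energy (Parseval)", {
  set.seed(8)
  img <- us_image(matrix(stats::runif(64 * 64, 0, 255), 64, 64))
  ks <- kernel_spectrum(img, c(10, 10))
  expect_equal(sum(ks$magnitude_raw^2) / 128^2, ks$kernel_energy,
               tolerance = 1e-6)
})

test_that("PSFR is invariant to gain and offset changes", {
  set.seed(12)
  spec <- phantom_spec(seed = 21)
  ph <- generate_tendon_phantom(spec, "above2cm")
  img1 <- ph$image
  img2 <- us_image(0.5 * img1$pixels + 20, img1$pixel_size_mm)
  cfg <- sfa_config(stride_px = 8L)
  r1 <- roi_psfr(img1, ph$annotations, cfg)
  r2 <- roi_psfr(img2, ph$annotations, cfg)
  expect_identical(r1$per_kernel_psfr, r2$per_kernel_psfr)
})

test_that("rotating a grating changes the ROI PSFR by at most 2 frequency bins", {
  ann <- function(img) annotation_set(
    roi = rect_roi(8, 8, nrow(img$pixels) - 9, ncol(img$pixels) - 9),
    superficial_border = cbind(row = c(2, 2), col = c(0, 95)),
    deep_border = cbind(row = c(90, 90), col = c(0, 95)))
  g0 <- make_grating_image(0.5, rows = 96, cols = 96)
  g10 <- make_grating_image(0.5, rows = 96, cols = 96, angle_deg = 10)
  cfg <- sfa_config(stride_px = 8L)
  p0 <- roi_psfr(g0, ann(g0), cfg)$roi_psfr
  p10 <- roi_psfr(g10, ann(g10), cfg)$roi_psfr
  expect_lte(abs(p0 - p10), 2 * 0.125 + 1e-12)
})

test_that("ROI aggregation is the mean of per-kernel values", {
  g <- make_grating_image(0.5, rows = 64, cols = 64)
  ann <- annotation_set(roi = rect_roi(0, 0, 63, 63),
                        superficial_border = cbind(row = c(0, 0), col = c(0, 63)),
                        deep_border = cbind(row = c(63, 63), col = c(0, 63)))
  res <- roi_psfr(g, ann, sfa_config(stride_px = 16L))
  single <- psfr_from_spectrum(kernel_spectrum(g, c(0, 0)))
  expect_equal(res$roi_psfr, single)   # identical gratings in every kernel
  expect_equal(res$n_valid, res$n_kernels)
  expect_equal(res$roi_psfr,
               mean(res$per_kernel_psfr[!is.na(res$per_kernel_psfr)]))
})

test_that("healthy-like phantoms rank above degenerated-like ones in every seed", {
  cfg <- sfa_config(stride_px = 8L)
  wins <- logical(20)
  for (s in 1:20) {
    healthy <- generate_tendon_phantom(
      phantom_spec(band_period_mm = 1 / 2.07, jitter_sd_mm = 0.02, seed = s),
      "above2cm")
    degen <- generate_tendon_phantom(
      phantom_spec(band_period_mm = 1 / 1.55, jitter_sd_mm = 0.02, seed = s),
      "above2cm")
    wins[s] <- roi_psfr(healthy$image, healthy$annotations, cfg)$roi_psfr >
      roi_psfr(degen$image, degen$annotations, cfg)$roi_psfr
  }
  expect_true(all(wins))
})

test_that("out-of-bounds kernels and empty ROIs raise errors", {
  img <- us_image(matrix(1:100 %% 256, 10, 10))
  expect_error(kernel_spectrum(img, c(0, 0)), "bounds")
  ph_img <- make_grating_image(0.5, rows = 40, cols = 40)
  tiny <- annotation_set(roi = rbind(c(0, 0), c(5, 0), c(0, 5)),
                         superficial_border = cbind(row = c(0, 0), col = c(0, 39)),
                         deep_border = cbind(row = c(39, 39), col = c(0, 39)))
  expect_error(suppressWarnings(roi_psfr(ph_img, tiny)), "no kernel")
})
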