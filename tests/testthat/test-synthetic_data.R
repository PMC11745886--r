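test_that("band positions are arithmetic without jitter and periodic in autocorrelation", {
  # pure band field (no diffuse background) at p = 0.5 mm, 0.0625 mm/px
  spec <- phantom_spec(band_period_mm = 0.5, jitter_sd_mm = 0,
                       scatterer_density = 0, seed = 5)
  field <- generate_fibrillar_scatterers(spec, extent = c(128, 96))
  profile <- rowMeans(field)
  hit <- which(profile > 0)
  # occupied rows come in runs separated by the band period (8 px)
  centers <- sort(unique(round(hit)))
  lag_px <- round(0.5 / 0.0625)
  ac <- stats::acf(profile, lag.max = 24, plot = FALSE)$acf[-1]
  # first prominent off-zero autocorrelation peak at the band period
  expect_equal(which.max(ac[4:24]) + 3L, lag_px)
})

test_that("scatterer fields and phantoms are deterministic under a fixed seed", {
  spec <- phantom_spec(jitter_sd_mm = 0.1, seed = 123)
  f1 <- generate_fibrillar_scatterers(spec)
  f2 <- generate_fibrillar_scatterers(spec)
  expect_identical(f1, f2)
  p1 <- generate_tendon_phantom(spec, "above2cm")
  p2 <- generate_tendon_phantom(spec, "above2cm")
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$annotations$roi, p2$annotations$roi)
  # a different seed yields a different speckle realisation
  p3 <- generate_tendon_phantom(phantom_spec(jitter_sd_mm = 0.1, seed = 124),
                                "above2cm")
  expect_false(identical(p1$image$pixels, p3$image$pixels))
})

test_that("aliasing and degenerate-field inputs are rejected", {
  expect_error(phantom_spec(band_period_mm = 0.1),
               "Nyquist")
  spec <- phantom_spec(seed = 1)
  spec$band_period_mm <- 0.12  # below 2 px after construction
  expect_error(generate_fibrillar_scatterers(spec), "alias")
  expect_error(render_bmode(matrix(0, 32, 32), phantom_spec()), "all-zero")
})

test_that("rendering is normalisation-invariant and always lands in [0, 255]", {
  spec <- phantom_spec(seed = 9)
  field <- generate_fibrillar_scatterers(spec, extent = c(64, 64))
  i1 <- render_bmode(field, spec)
  i2 <- render_bmode(2 * field, spec)
  expect_identical(i1$pixels, i2$pixels)
  for (s in 1:20) {
    sp <- phantom_spec(jitter_sd_mm = stats::runif(1, 0, 0.3), seed = s)
    img <- render_bmode(generate_fibrillar_scatterers(sp, extent = c(48, 48)),
                        sp)
    expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  }
})

test_that("rendered periodic bands peak at 1/p in the column-mean axial power spectrum", {
  spec <- phantom_spec(band_period_mm = 0.5, jitter_sd_mm = 0,
                       scatterer_density = 0, seed = 2)
  field <- generate_fibrillar_scatterers(spec, extent = c(128, 96))
  img <- render_bmode(field, spec)
  x <- img$pixels - mean(img$pixels)
  pw <- rowMeans(Mod(stats::mvfft(x))^2)
  f <- (0:127) / (128 * 0.0625)
  keep <- f > 0.5 & f < 8          # away from DC and the mirrored half
  fpeak <- f[keep][which.max(pw[keep])]
  expect_lt(abs(fpeak - 2.0), 0.125 + 1e-12)
})

test_that("phantom geometry encodes the requested thickness and insertion wedge", {
  spec <- phantom_spec(thickness_mm = 4.92, seed = 3)
  ph <- generate_tendon_phantom(spec, "above2cm")
  ctr <- (ncol(ph$image$pixels) - 1) / 2
  sep <- diff(range(ph$annotations$deep_border[1, "row"],
                    ph$annotations$superficial_border[1, "row"]))
  expect_equal(sep, 4.92 / 0.0625)
  expect_equal(ph$ground_truth$thickness_mm, 4.92)

  ins <- generate_tendon_phantom(spec, "insertion")
  expect_false(is.null(ins$annotations$calcaneus_trace))
  # the calcaneal line crosses the deep border exactly once
  deep_row <- ins$annotations$deep_border[1, "row"]
  gaps <- sign(ins$annotations$calcaneus_trace[, "row"] - deep_row)
  gaps <- gaps[gaps != 0]
  expect_equal(sum(diff(gaps) != 0), 1L)
  # ROI is inset at least 2 px from the borders
  roi <- ins$annotations$roi
  expect_true(min(roi[, "row"]) >= ins$annotations$superficial_border[1, "row"] + 2)
  expect_true(max(roi[, "row"]) <= deep_row - 2)
  # geometry that cannot host a kernel is rejected
  expect_error(generate_tendon_phantom(phantom_spec(thickness_mm = 1.5),
                                       "above2cm"),
               "kernel")
})

test_that("cohort generation writes a reproducible, correctly shaped dataset", {
  dir1 <- tempfile("coh"); dir2 <- tempfile("coh")
  c1 <- generate_cohort(2, 2, seed = 11, dir = dir1,
                        image_rows = 128L, image_cols = 96L)
  c2 <- generate_cohort(2, 2, seed = 11, dir = dir2,
                        image_rows = 128L, image_cols = 96L)
  m1 <- read_manifest(c1$manifest)
  expect_equal(nrow(m1), 2 * 2 * 3 + 2 * 3)
  expect_true(all(m1$limb[m1$group == "control"] == "control"))
  expect_true(all(file.exists(file.path(dir1, m1$image))))
  # same seed: identical manifest and identical pixels
  expect_identical(readLines(c1$manifest), readLines(c2$manifest))
  expect_identical(unname(tools::md5sum(file.path(dir1, m1$image[1]))),
                   unname(tools::md5sum(file.path(dir2, m1$image[1]))))
  # the full study design yields 15*2*3 + 19*3 = 147 image rows
  expect_equal(nrow(draw_cohort_params(15, 19, seed = 1)), 147L)
  expect_error(generate_cohort(1, 5, seed = 1), "at least 2")
})

test_that("the designed group contrast is detectable by ANOVA in most cohorts", {
  es <- data.frame(limb = c("control", "non_paretic", "paretic"),
                   site = "insertion",
                   psfr_mean = c(1.94, 1.78, 1.70), psfr_sd = 0.2,
                   thickness_mean = 4.5, thickness_sd = 0.1)
  reject <- logical(100)
  for (r in 1:100) {
    par <- draw_cohort_params(50, 50, effect_spec = es, seed = 1000 + r)
    grp <- split(par$psfr_true, par$limb)
    reject[r] <- anova_oneway(grp)$p <= 0.05
  }
  expect_gte(mean(reject), 0.80)
})
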