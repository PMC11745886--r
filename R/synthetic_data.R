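#' Specification of a synthetic tendon speckle phantom
#'
#' Defines a B-mode-like phantom of fibrillar (tendon) tissue: quasi-periodic
#' hyperechoic fascicle bands with controllable axial spacing and positional
#' jitter, embedded in diffuse background speckle, imaged through a separable
#' point-spread function and log-compressed. The band spacing sets the
#' ground-truth dominant spatial frequency (`1 / band_period_mm`); the jitter
#' standard deviation is the organization control — zero jitter emulates
#' well-organized collagen, large jitter emulates collagen disarray.
#'
#' @param band_period_mm Axial fascicle band spacing `p` in mm; the expected
#'   PSFR is `1/p`. Default 0.5 mm (expected peak at 2.0 mm^-1).
#' @param jitter_sd_mm SD of the per-band axial position noise in mm
#'   (organization knob; per-column phase noise uses half this SD).
#' @param undulation_amp_mm,undulation_period_mm Amplitude and lateral period
#'   of sinusoidal band undulation (waviness), mm.
#' @param thickness_mm Tendon thickness (border separation), mm.
#' @param insertion_wedge_deg Angle between the calcaneal line and the deep
#'   border at the insertion site, degrees.
#' @param scatterer_density Diffuse scatterers per mm^2.
#' @param band_amplitude Mean amplitude of band scatterers relative to the
#'   unit-mean diffuse background.
#' @param psf_axial_sigma_mm,psf_lateral_sigma_mm Gaussian widths of the
#'   point-spread function, mm.
#' @param psf_center_freq Axial center frequency of the PSF carrier, mm^-1.
#' @param dynamic_range_db Log-compression dynamic range, dB.
#' @param pixel_size_mm Pixel pitch, mm (isotropic).
#' @param image_rows,image_cols Rendered image size in pixels.
#' @param depth_offset_mm Depth of the superficial border below the top of
#'   the image, mm.
#' @param seed Integer seed; all phantom outputs are pure functions of
#'   (spec, seed).
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(band_period_mm = 0.5, jitter_sd_mm = 0,
                         undulation_amp_mm = 0, undulation_period_mm = 4,
                         thickness_mm = 4.9, insertion_wedge_deg = 25,
                         scatterer_density = 60, band_amplitude = 3,
                         psf_axial_sigma_mm = 0.15,
                         psf_lateral_sigma_mm = 0.3,
                         psf_center_freq = 3.0, dynamic_range_db = 60,
                         pixel_size_mm = 0.0625,
                         image_rows = 128L, image_cols = 160L,
                         depth_offset_mm = 1.0, seed = 1L) {
  spec <- list(band_period_mm = band_period_mm, jitter_sd_mm = jitter_sd_mm,
               undulation_amp_mm = undulation_amp_mm,
               undulation_period_mm = undulation_period_mm,
               thickness_mm = thickness_mm,
               insertion_wedge_deg = insertion_wedge_deg,
               scatterer_density = scatterer_density,
               band_amplitude = band_amplitude,
               psf_axial_sigma_mm = psf_axial_sigma_mm,
               psf_lateral_sigma_mm = psf_lateral_sigma_mm,
               psf_center_freq = psf_center_freq,
               dynamic_range_db = dynamic_range_db,
               pixel_size_mm = pixel_size_mm,
               image_rows = as.integer(image_rows),
               image_cols = as.integer(image_cols),
               depth_offset_mm = depth_offset_mm, seed = as.integer(seed))
  if (band_period_mm <= 0) stop("band_period_mm must be > 0")
  if (1 / band_period_mm >= 1 / (2 * pixel_size_mm)) {
    stop("band frequency 1/band_period_mm must be below Nyquist ",
         1 / (2 * pixel_size_mm), " mm^-1")
  }
  if (jitter_sd_mm < 0) stop("jitter_sd_mm must be >= 0")
  if (thickness_mm <= 0 ||
      thickness_mm + depth_offset_mm >= image_rows * pixel_size_mm) {
    stop("thickness_mm must be positive and fit within the image depth")
  }
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
  structure(spec, class = "phantom_spec")
}

# Diffuse background: unit-mean exponential amplitudes at scatterer_density
# per mm^2, deposited at uniform sub-pixel positions (nearest-pixel bin).
scatter_background <- function(spec, rows, cols) {
  px <- spec$pixel_size_mm
  n <- round(spec$scatterer_density * rows * cols * px^2)
  field <- matrix(0, rows, cols)
  if (n > 0) {
    r <- floor(stats::runif(n, 0, rows)) + 1L
    c <- floor(stats::runif(n, 0, cols)) + 1L
    a <- stats::rexp(n)
    for (i in seq_len(n)) field[r[i], c[i]] <- field[r[i], c[i]] + a[i]
  }
  field
}

# Hyperechoic band scatterers: bands at z_k = z0 + k*p + eps_k with
# eps_k ~ N(0, jitter_sd_mm), per-column phase noise ~ N(0, jitter_sd_mm/2),
# and sinusoidal lateral undulation. Sub-pixel axial positions are split
# linearly across the two adjacent rows.
scatter_bands <- function(spec, rows, cols, row_range = c(0, rows)) {
  px <- spec$pixel_size_mm
  p <- spec$band_period_mm
  depth_mm <- rows * px
  field <- matrix(0, rows, cols)
  z0 <- stats::runif(1, 0, p)
  centers <- seq(z0, depth_mm, by = p)
  eps <- stats::rnorm(length(centers), 0, spec$jitter_sd_mm)
  x_mm <- (0:(cols - 1)) * px
  und <- if (spec$undulation_amp_mm > 0) {
    spec$undulation_amp_mm * sin(2 * pi * x_mm / spec$undulation_period_mm)
  } else rep(0, cols)
  for (k in seq_along(centers)) {
    eta <- stats::rnorm(cols, 0, spec$jitter_sd_mm / 2)
    amp <- spec$band_amplitude * stats::rexp(cols)
    z <- centers[k] + eps[k] + und + eta
    zr <- z / px
    lo <- floor(zr); w <- zr - lo
    for (x in seq_len(cols)) {
      if (zr[x] < row_range[1] || zr[x] >= row_range[2]) next
      i0 <- lo[x] + 1L
      if (i0 >= 1L && i0 <= rows) {
        field[i0, x] <- field[i0, x] + amp[x] * (1 - w[x])
      }
      if (i0 + 1L >= 1L && i0 + 1L <= rows) {
        field[i0 + 1L, x] <- field[i0 + 1L, x] + amp[x] * w[x]
      }
    }
  }
  field
}

#' Generate a fibrillar scatterer field
#'
#' Diffuse background scatterers plus quasi-periodic hyperechoic band
#' scatterers across the full extent. Deterministic under the spec's seed.
#'
#' @param spec A [phantom_spec].
#' @param extent `c(rows, cols)` of the field in pixels.
#' @return Numeric amplitude matrix.
#' @export
generate_fibrillar_scatterers <- function(spec, extent = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(extent)) extent <- c(spec$image_rows, spec$image_cols)
  if (spec$band_period_mm / spec$pixel_size_mm < 2) {
    stop("band period below 2 pixels would alias")
  }
  set.seed(spec$seed)
  scatter_background(spec, extent[1], extent[2]) +
    scatter_bands(spec, extent[1], extent[2])
}

# Linear 'same' 2D convolution with a separable kernel, via zero-padded FFT.
conv2_same <- function(field, h_ax, h_lat) {
  nr <- nrow(field); nc <- ncol(field)
  la <- (length(h_ax) - 1L) %/% 2L; ll <- (length(h_lat) - 1L) %/% 2L
  pr <- nr + 2L * la; pc <- nc + 2L * ll
  fp <- matrix(0, pr, pc); fp[1:nr, 1:nc] <- field
  kp <- matrix(0, pr, pc)
  kp[1:length(h_ax), 1:length(h_lat)] <- outer(h_ax, h_lat)
  out <- Re(stats::fft(stats::fft(fp) * stats::fft(kp), inverse = TRUE)) /
    (pr * pc)
  out[(la + 1):(la + nr), (ll + 1):(ll + nc)]
}

# Per-column envelope via the analytic signal along the axial (row) axis.
axial_envelope <- function(rf) {
  n <- nrow(rf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Y <- stats::mvfft(rf) * h
  Mod(stats::mvfft(Y, inverse = TRUE) / n)
}

#' Render a scatterer field as a B-mode image
#'
#' Convolves the field with the separable point-spread function
#' `h(z, x) = exp(-z^2 / 2 s_ax^2) cos(2 pi f_c z) exp(-x^2 / 2 s_lat^2)`,
#' detects the envelope as the magnitude of the analytic signal along the
#' axial axis, and log-compresses to 8 bits:
#' `I = 255 * clip(1 + 20 log10(env / env_max) / DR, 0, 1)`.
#' Rendering is deterministic (all randomness lives in the scatterer field)
#' and invariant to positive rescaling of the field.
#'
#' @param field Scatterer amplitude matrix.
#' @param spec A [phantom_spec] (PSF and compression parameters).
#' @param id Image identifier.
#' @return A [us_image].
#' @export
render_bmode <- function(field, spec, id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(!is.finite(field))) stop("scatterer field must be finite")
  if (all(field == 0)) stop("all-zero scatterer field cannot be rendered")
  px <- spec$pixel_size_mm
  la <- max(1L, ceiling(3 * spec$psf_axial_sigma_mm / px))
  ll <- max(1L, ceiling(3 * spec$psf_lateral_sigma_mm / px))
  z <- (-la:la) * px
  x <- (-ll:ll) * px
  h_ax <- exp(-z^2 / (2 * spec$psf_axial_sigma_mm^2)) *
    cos(2 * pi * spec$psf_center_freq * z)
  h_lat <- exp(-x^2 / (2 * spec$psf_lateral_sigma_mm^2))
  rf <- conv2_same(field, h_ax, h_lat)
  env <- axial_envelope(rf)
  env_max <- max(env)
  if (env_max <= 0) stop("zero envelope: nothing to render")
  db <- 20 * log10(pmax(env, .Machine$double.xmin) / env_max)
  I <- 255 * pmin(pmax(1 + db / spec$dynamic_range_db, 0), 1)
  us_image(round(I), pixel_size_mm = px, id = id)
}

#' Generate a complete tendon phantom with annotations and ground truth
#'
#' Lays down two tendon borders `thickness_mm` apart (parallel horizontal
#' lines for the mid-tendon sites; at the insertion site the deep border is
#' crossed once by a bright calcaneal line at the wedge angle), confines the
#' fascicle bands between the borders over diffuse background speckle,
#' renders the B-mode image, and returns the laid-down annotations (ROI
#' inset 2 px from the borders) plus the ground truth the phantom encodes.
#'
#' @param spec A [phantom_spec].
#' @param site One of `"insertion"`, `"above2cm"`, `"above4cm"`.
#' @return A list of class `tendon_phantom` with elements `image`
#'   ([us_image]), `annotations` ([annotation_set]) and `ground_truth`
#'   (list: `expected_psfr`, `organization_level`, `thickness_mm`,
#'   `superficial_border`, `deep_border`, `insertion_point` or `NULL`).
#' @export
generate_tendon_phantom <- function(spec, site = "above2cm") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!site %in% valid_sites) {
    stop("site must be one of: ", paste(valid_sites, collapse = ", "))
  }
  rows <- spec$image_rows; cols <- spec$image_cols
  px <- spec$pixel_size_mm
  r_s <- spec$depth_offset_mm / px
  r_d <- r_s + spec$thickness_mm / px
  if (r_d >= rows - 2) stop("tendon does not fit within the image depth")

  set.seed(spec$seed)
  field <- scatter_background(spec, rows, cols)
  field <- field + scatter_bands(spec, rows, cols, row_range = c(r_s, r_d))
  # hyperechoic peritenon lines along both borders
  border_amp <- 1.5 * spec$band_amplitude
  for (rr in c(r_s, r_d)) {
    i0 <- floor(rr) + 1L; w <- rr - floor(rr)
    if (i0 >= 1 && i0 <= rows) {
      field[i0, ] <- field[i0, ] + border_amp * (1 - w) * stats::rexp(cols)
    }
    if (i0 + 1L <= rows) {
      field[i0 + 1L, ] <- field[i0 + 1L, ] + border_amp * w * stats::rexp(cols)
    }
  }

  xs <- c(0, cols - 1)
  sup <- cbind(row = c(r_s, r_s), col = xs)
  deep <- cbind(row = c(r_d, r_d), col = xs)
  calc <- NULL
  roi_right <- cols - 3
  if (site == "insertion") {
    slope <- tan(spec$insertion_wedge_deg * pi / 180)
    x_int <- round(0.65 * cols)
    x0 <- max(0, x_int - round(1.0 / px))
    cx <- seq(x0, cols - 1)
    cr <- r_d - (cx - x_int) * slope
    keep <- cr >= 2 & cr <= rows - 2
    cx <- cx[keep]; cr <- cr[keep]
    calc <- cbind(row = cr, col = cx)
    # bright calcaneal cortex line in the field
    for (i in seq_along(cx)) {
      i0 <- floor(cr[i]) + 1L; w <- cr[i] - floor(cr[i])
      a <- 2.5 * spec$band_amplitude * stats::rexp(1)
      if (i0 >= 1 && i0 <= rows) field[i0, cx[i] + 1L] <- field[i0, cx[i] + 1L] + a * (1 - w)
      if (i0 + 1L <= rows) field[i0 + 1L, cx[i] + 1L] <- field[i0 + 1L, cx[i] + 1L] + a * w
    }
    roi_right <- x0 - 2
  }
  roi <- rbind(c(ceiling(r_s) + 2, 2),
               c(ceiling(r_s) + 2, roi_right),
               c(floor(r_d) - 2, roi_right),
               c(floor(r_d) - 2, 2))
  k <- 32L
  if (diff(range(roi[, 1])) + 1 < k || diff(range(roi[, 2])) + 1 < k) {
    stop("phantom geometry leaves an ROI smaller than one kernel")
  }
  ann <- annotation_set(roi = roi, superficial_border = sup,
                        deep_border = deep, calcaneus_trace = calc,
                        site_label = site)
  img <- render_bmode(field, spec, id = paste0("phantom_", site))
  gt <- list(expected_psfr = 1 / spec$band_period_mm,
             organization_level = spec$jitter_sd_mm,
             thickness_mm = (r_d - r_s) * px,
             superficial_border = sup, deep_border = deep,
             insertion_point = if (site == "insertion") {
               c(row = r_d, col = round(0.65 * cols))
             } else NULL,
             site = site)
  structure(list(image = img, annotations = ann, ground_truth = gt),
            class = "tendon_phantom")
}

#' Table of per-limb, per-site generating parameters for a cohort
#'
#' The default effect specification mirrors the published group structure of
#' post-stroke Achilles tendon morphometry: per-limb PSFR and thickness
#' means/SDs at each of the three sites (insertion, 2 cm and 4 cm above).
#'
#' @return A data.frame with columns `limb`, `site`, `psfr_mean`, `psfr_sd`,
#'   `thickness_mean`, `thickness_sd`.
#' @export
default_effect_spec <- function() {
  data.frame(
    limb = rep(c("control", "non_paretic", "paretic"), each = 3),
    site = rep(c("above4cm", "above2cm", "insertion"), times = 3),
    psfr_mean = c(1.95, 1.91, 1.94, 1.81, 1.87, 1.78, 1.89, 1.85, 1.70),
    psfr_sd = c(0.24, 0.27, 0.32, 0.19, 0.37, 0.26, 0.20, 0.20, 0.21),
    thickness_mean = c(4.58, 4.37, 4.08, 5.00, 4.73, 4.36, 5.10, 4.93, 4.92),
    thickness_sd = c(0.07, 0.06, 0.07, 0.13, 0.07, 0.07, 0.07, 0.07, 0.08),
    stringsAsFactors = FALSE)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > lo && v < hi) break
    }
    out[i] <- v
  }
  out
}

#' Draw per-image generating parameters for a synthetic cohort
#'
#' The distributional layer of [generate_cohort()]: draws each limb's true
#' PSFR (mapped to band period `1/PSFR`) and thickness per site from the
#' effect specification, without rendering images. Exposed so that
#' statistical properties of the design can be studied at scale.
#'
#' @param n_stroke,n_control Subjects per group (each `>= 2`).
#' @param effect_spec Data.frame as returned by [default_effect_spec()].
#' @param seed Integer master seed.
#' @param pixel_size_mm Pixel pitch used for the Nyquist validity check.
#' @return Data.frame with one row per image: `subject_id`, `group`, `limb`,
#'   `site`, `psfr_true`, `thickness_true`, `child_seed`.
#' @export
draw_cohort_params <- function(n_stroke, n_control,
                               effect_spec = default_effect_spec(),
                               seed = 1L, pixel_size_mm = 0.0625) {
  if (n_stroke < 2 || n_control < 2) stop("need at least 2 subjects per group")
  nyq <- 1 / (2 * pixel_size_mm)
  if (any(effect_spec$psfr_mean >= nyq)) {
    stop("effect_spec implies PSFR at or above Nyquist (", nyq, " mm^-1)")
  }
  set.seed(seed)
  subj <- data.frame(
    subject_id = c(sprintf("S%02d", seq_len(n_stroke)),
                   sprintf("C%02d", seq_len(n_control))),
    group = c(rep("stroke", n_stroke), rep("control", n_control)),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(subj))) {
    limbs <- if (subj$group[i] == "stroke") c("paretic", "non_paretic")
             else "control"
    for (limb in limbs) {
      es <- effect_spec[effect_spec$limb == limb, ]
      for (j in seq_len(nrow(es))) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj$subject_id[i], group = subj$group[i],
          limb = limb, site = es$site[j],
          psfr_true = rnorm_trunc(1, es$psfr_mean[j], es$psfr_sd[j],
                                  1.1, 0.9 * nyq),
          thickness_true = rnorm_trunc(1, es$thickness_mean[j],
                                       es$thickness_sd[j], 2.0, 6.2),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$child_seed <- sample.int(.Machine$integer.max - 1L, nrow(out))
  out
}

#' Generate a synthetic cohort on disk
#'
#' Writes a complete dataset emulating the study design: stroke subjects
#' contribute paretic and non-paretic limbs, controls contribute the control
#' limb only, each imaged at three sites. Per-limb band period and thickness
#' are drawn from `effect_spec`; each image gets its own child seed derived
#' from the master seed, so the whole cohort is reproducible.
#'
#' @inheritParams draw_cohort_params
#' @param dir Output directory (created if needed).
#' @param jitter_sd_mm Organization jitter applied to every phantom.
#' @param image_rows,image_cols Phantom size in pixels.
#' @return A list with `manifest` (path to `manifest.csv`), `params` (the
#'   drawn parameter table, also written as `ground_truth.csv`), and `dir`.
#' @export
generate_cohort <- function(n_stroke, n_control,
                            effect_spec = default_effect_spec(),
                            seed = 1L, dir = tempfile("cohort"),
                            jitter_sd_mm = 0.05,
                            image_rows = 128L, image_cols = 160L) {
  params <- draw_cohort_params(n_stroke, n_control, effect_spec, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- params[, c("subject_id", "group", "limb", "site")]
  manifest$image <- sprintf("%s_%s_%s.png", params$subject_id, params$limb,
                            params$site)
  manifest$annotations <- sub("\\.png$", ".json", manifest$image)
  for (i in seq_len(nrow(params))) {
    spec <- phantom_spec(band_period_mm = 1 / params$psfr_true[i],
                         thickness_mm = params$thickness_true[i],
                         jitter_sd_mm = jitter_sd_mm,
                         image_rows = image_rows, image_cols = image_cols,
                         seed = params$child_seed[i])
    ph <- generate_tendon_phantom(spec, site = params$site[i])
    write_image(ph$image, file.path(dir, manifest$image[i]))
    write_annotations(ph$annotations, file.path(dir, manifest$annotations[i]))
  }
  names(manifest)[1] <- "subject_id"
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  write_results(params, file.path(dir, "ground_truth.csv"))
  list(manifest = mpath, params = params, dir = dir)
}
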