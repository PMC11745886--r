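# Shared fixtures: analytic gratings, rectangular ROIs, constructed border
# traces, and an independent brute-force DFT oracle.

# Axial cosine grating (optionally rotated), intensities in [0, 255].
make_grating_image <- function(period_mm, rows = 64, cols = 64,
                               pixel_size_mm = 0.0625, angle_deg = 0,
                               id = "grating") {
  th <- angle_deg * pi / 180
  r <- matrix(0:(rows - 1), rows, cols)
  c <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
  z <- (r * cos(th) + c * sin(th)) * pixel_size_mm
  us_image(127 + 120 * cos(2 * pi * z / period_mm),
           pixel_size_mm = pixel_size_mm, id = id)
}

# Closed rectangle polygon covering pixel rows r0..r1, cols c0..c1.
rect_roi <- function(r0, c0, r1, c1) {
  rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
}

# Annotation set with straight parallel borders separated by `sep_px` rows.
parallel_ann <- function(sep_px, cols = 400, top_row = 50,
                         site = "above2cm", slope = 0) {
  xs <- c(0, cols - 1)
  sup <- cbind(row = top_row + slope * xs, col = xs)
  deep <- cbind(row = top_row + sep_px + slope * xs, col = xs)
  annotation_set(roi = rect_roi(top_row + 2, 2, top_row + sep_px - 2,
                                cols - 3),
                 superficial_border = sup, deep_border = deep,
                 site_label = site)
}

# Rigid rotation of (row, col) coordinate matrices about a center point.
rotate_coords <- function(m, theta_deg, center) {
  th <- theta_deg * pi / 180
  dr <- m[, 1] - center[1]; dc <- m[, 2] - center[2]
  cbind(row = center[1] + dr * cos(th) - dc * sin(th),
        col = center[2] + dr * sin(th) + dc * cos(th))
}

# Independent O(N^4) DFT + radial Butterworth oracle for the SFA transform.
brute_filtered_spectrum <- function(kernel, pad, pixel_size_mm,
                                    cutoff = 1.0, order = 2) {
  k <- kernel - mean(kernel)
  N <- pad
  mag <- matrix(0, N, N)
  xs <- 0:(nrow(k) - 1); ys <- 0:(ncol(k) - 1)
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) {
    s <- 0
    for (x in xs) for (y in ys) {
      s <- s + k[x + 1, y + 1] * exp(-2i * pi * (u * x + v * y) / N)
    }
    mag[u + 1, v + 1] <- Mod(s)
  }
  fr <- c(0:(N / 2 - 1), -(N / 2):-1) / (N * pixel_size_mm)
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  H <- (rad / cutoff)^(2 * order) / sqrt(1 + (rad / cutoff)^(4 * order))
  mag * H
}

# Minimal hand-built kernel_spectrum for peak-rule tests.
fake_spectrum <- function(magnitude, pixel_size_mm = 0.0625, energy = 1) {
  n <- nrow(magnitude)
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * pixel_size_mm)
  structure(list(magnitude = magnitude, magnitude_raw = magnitude,
                 f_axial = f, f_lateral = f, kernel_energy = energy,
                 origin_px = c(0L, 0L), pixel_size_mm = pixel_size_mm,
                 config = sfa_config(kernel_px = n %/% 4L, pad_px = n)),
            class = "kernel_spectrum")
}

table2_psfr_rows <- function() {
  list(
    insertion = list(group_summary("control", 1.94, 0.32, 19),
                     group_summary("non_paretic", 1.78, 0.26, 15),
                     group_summary("paretic", 1.70, 0.21, 15)),
    above2cm = list(group_summary("control", 1.91, 0.27, 19),
                    group_summary("non_paretic", 1.87, 0.37, 15),
                    group_summary("paretic", 1.85, 0.20, 15)),
    above4cm = list(group_summary("control", 1.95, 0.24, 19),
                    group_summary("non_paretic", 1.81, 0.19, 15),
                    group_summary("paretic", 1.89, 0.20, 15)))
}
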