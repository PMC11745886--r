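# Internal geometry helpers shared by the annotation, tiling and thickness code.
# All coordinates are 0-based (row, col); row index increases with depth.

#' @importFrom pracma polyarea inpolygon
NULL

# Coerce a list-of-pairs / data.frame / matrix to an n x 2 numeric matrix with
# columns (row, col).
as_coords <- function(x, what = "coordinates") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  if (!is.matrix(x) || ncol(x) != 2L || nrow(x) < 1L || !is.numeric(x) ||
      any(!is.finite(x))) {
    stop(what, " must be a non-empty n x 2 numeric matrix of (row, col)")
  }
  colnames(x) <- c("row", "col")
  x
}

polygon_area <- function(poly) {
  abs(pracma::polyarea(poly[, "col"], poly[, "row"]))
}

# Proper + improper intersection test for two closed segments, used for the
# ROI self-intersection check. Shared endpoints of adjacent edges are handled
# by the caller (adjacent edges are skipped).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (abs(d1) < 1e-12 && on_seg(p3, p4, p1)) ||
    (abs(d2) < 1e-12 && on_seg(p3, p4, p2)) ||
    (abs(d3) < 1e-12 && on_seg(p1, p2, p3)) ||
    (abs(d4) < 1e-12 && on_seg(p1, p2, p4))
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  for (i in seq_len(n)) {
    a1 <- poly[i, ]; a2 <- poly[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip edges sharing a vertex with edge i
      if (j == i + 1L || (i == 1L && j == n)) next
      b1 <- poly[j, ]; b2 <- poly[if (j == n) 1L else j + 1L, ]
      if (segments_intersect(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

points_in_polygon <- function(rows, cols, poly) {
  pracma::inpolygon(cols, rows, poly[, "col"], poly[, "row"], boundary = TRUE)
}

# Evaluate a border polyline (single-valued in the column index) at arbitrary
# column positions by linear interpolation; NA outside the traced span.
border_eval <- function(border, at_cols) {
  stats::approx(border[, "col"], border[, "row"], xout = at_cols,
                method = "linear", rule = 1)$y
}

# Intersection point of two open segments; NULL if they do not cross.
segment_intersection_point <- function(p1, p2, p3, p4) {
  r <- p2 - p1; s <- p4 - p3
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-14) return(NULL)
  q <- p3 - p1
  t <- (q[1] * s[2] - q[2] * s[1]) / denom
  u <- (q[1] * r[2] - q[2] * r[1]) / denom
  if (t < -1e-12 || t > 1 + 1e-12 || u < -1e-12 || u > 1 + 1e-12) return(NULL)
  p1 + t * r
}

# First intersection of the ray origin + s * dir (s > 0) with a polyline;
# returns the smallest positive s, or NA if the ray misses every segment.
ray_polyline_distance <- function(origin, dir, polyline) {
  best <- NA_real_
  for (i in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[i, ]; b <- polyline[i + 1L, ]
    e <- b - a
    denom <- dir[1] * (-e[2]) + dir[2] * e[1]
    if (abs(denom) < 1e-14) next
    q <- a - origin
    s <- (q[1] * (-e[2]) + q[2] * e[1]) / denom
    u <- (dir[1] * q[2] - dir[2] * q[1]) / denom
    if (u >= -1e-9 && u <= 1 + 1e-9 && s > 1e-9) {
      if (is.na(best) || s < best) best <- s
    }
  }
  best
}
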