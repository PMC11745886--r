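#' Tendon thickness from traced borders
#'
#' Thickness is the perpendicular distance between the superficial and deep
#' border traces. "Perpendicular" is taken as normal to the superficial
#' border: the local tangent is estimated by a central difference over +/- 5
#' columns, and the normal ray is cast from the superficial anchor point
#' toward depth until it meets the deep border (linear interpolation along
#' the polyline). At the mid-tendon sites the anchor is the image's center
#' column; at the insertion it is the column of the tendon-calcaneus
#' intersection.
#'
#' @name thickness
NULL

# Perpendicular distance (mm) from the superficial border at column x_c to
# the deep border, along the superficial-border normal.
thickness_at_column <- function(ann, image, x_c, method) {
  px <- image$pixel_size_mm
  sup <- ann$superficial_border
  span <- range(sup[, "col"])
  if (x_c < span[1] || x_c > span[2]) {
    stop("superficial border does not span column ", x_c)
  }
  h <- min(5, x_c - span[1], span[2] - x_c)
  if (h < 1) stop("superficial border too short around column ", x_c,
                  " to estimate a tangent")
  y0 <- border_eval(sup, x_c)
  yp <- border_eval(sup, x_c + h)
  ym <- border_eval(sup, x_c - h)
  if (any(is.na(c(y0, yp, ym)))) {
    stop("superficial border does not span column ", x_c)
  }
  m <- (yp - ym) / (2 * h)           # d(row)/d(col) slope of the border
  nvec <- c(1, -m) / sqrt(1 + m^2)   # unit normal pointing toward depth
  origin <- c(y0, x_c)
  dspan <- range(ann$deep_border[, "col"])
  s <- ray_polyline_distance(origin, nvec, ann$deep_border)
  if (is.na(s)) {
    stop("normal ray from the superficial border misses the deep border ",
         "(deep trace spans columns ", dspan[1], "-", dspan[2], ")")
  }
  structure(list(site_label = ann$site_label,
                 value_mm = unname(s * px),
                 anchor_point = c(row = unname(y0), col = unname(x_c)),
                 method = method),
            class = "thickness_measurement")
}

#' @export
print.thickness_measurement <- function(x, ...) {
  cat(sprintf("<thickness %s/%s> %.3f mm at (row %.1f, col %.1f)\n",
              x$site_label, x$method, x$value_mm,
              x$anchor_point["row"], x$anchor_point["col"]))
  invisible(x)
}

#' Tendon thickness at the image center column
#'
#' Used at the 2 cm and 4 cm sites: perpendicular border distance at the
#' longitudinal image's center column.
#'
#' @param ann An [annotation_set] whose borders span the center column.
#' @param image The [us_image] (provides the calibration and center column).
#' @return A `thickness_measurement`: `site_label`, `value_mm`,
#'   `anchor_point` (on the superficial border), `method`.
#' @export
thickness_at_center <- function(ann, image) {
  stopifnot(inherits(ann, "annotation_set"), inherits(image, "us_image"))
  x_c <- (ncol(image$pixels) - 1) / 2
  thickness_at_column(ann, image, x_c, method = "center_column")
}

#' Tendon-calcaneus intersection point
#'
#' Intersection of the deep border polyline with the calcaneus trace. If the
#' traces cross more than once the shallowest crossing (smallest row) is
#' returned; if they do not touch, a near-miss within 1 px is accepted as
#' the closest-approach point.
#'
#' @param ann An [annotation_set] with a `calcaneus_trace`.
#' @return Named numeric `c(row, col)` in pixel coordinates.
#' @export
insertion_point <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(ann$calcaneus_trace)) {
    stop("annotation has no calcaneus trace; cannot locate the insertion")
  }
  deep <- ann$deep_border; calc <- ann$calcaneus_trace
  hits <- list()
  for (i in seq_len(nrow(deep) - 1L)) {
    for (j in seq_len(nrow(calc) - 1L)) {
      p <- segment_intersection_point(deep[i, ], deep[i + 1L, ],
                                      calc[j, ], calc[j + 1L, ])
      if (!is.null(p)) hits[[length(hits) + 1L]] <- p
    }
  }
  if (length(hits) == 0L) {
    # closest approach between trace vertices and the deep border
    d_at <- border_eval(deep, calc[, "col"])
    gap <- abs(calc[, "row"] - d_at)
    if (all(is.na(gap)) || min(gap, na.rm = TRUE) > 1) {
      stop("deep border and calcaneus trace do not intersect (within 1 px)")
    }
    k <- which.min(gap)
    return(c(row = unname((calc[k, "row"] + d_at[k]) / 2),
             col = unname(calc[k, "col"])))
  }
  pts <- do.call(rbind, hits)
  best <- pts[which.min(pts[, 1]), ]
  c(row = unname(best[1]), col = unname(best[2]))
}

#' Tendon thickness at the calcaneal insertion
#'
#' As [thickness_at_center()] but anchored at the column of the
#' tendon-calcaneus intersection.
#'
#' @inheritParams thickness_at_center
#' @return A `thickness_measurement` with method `insertion_intersection`.
#' @export
thickness_at_insertion <- function(ann, image) {
  stopifnot(inherits(ann, "annotation_set"), inherits(image, "us_image"))
  ip <- insertion_point(ann)
  thickness_at_column(ann, image, ip["col"], method = "insertion_intersection")
}
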