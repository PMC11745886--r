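#' Calibrated B-mode ultrasound image
#'
#' Container for an 8-bit grayscale B-mode image together with its spatial
#' calibration. The axial (depth) direction maps to the row index: row 0 is
#' the transducer face, rows increase with depth. Pixels are assumed
#' isotropic, so a single `pixel_size_mm` converts both axes to millimetres.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`; rows are depth.
#' @param pixel_size_mm Side length of one pixel in mm (scalar `> 0`). The
#'   default `0.0625` corresponds to a 32-pixel kernel spanning 2.0 mm.
#' @param id Character identifier carried through result tables.
#'
#' @return An object of class `us_image` with fields `pixels`,
#'   `pixel_size_mm` and `id`.
#' @export
us_image <- function(pixels, pixel_size_mm = 0.0625, id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) == 0L)) {
    stop("pixels must be a non-empty numeric matrix")
  }
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must be finite and within [0, 255]")
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    stop("pixel_size_mm must be a positive scalar")
  }
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 id = as.character(id)[1]),
            class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image '%s'> %d x %d px, %.4f mm/px (%.1f x %.1f mm)\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm,
              nrow(x$pixels) * x$pixel_size_mm,
              ncol(x$pixels) * x$pixel_size_mm))
  invisible(x)
}

#' Read an ultrasound image from a PNG or TIFF file
#'
#' Reads an 8-bit grayscale image. Multi-channel files are collapsed to
#' luminance (Rec. 709 weights), which is the identity for gray RGB files.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams us_image
#' @return A [us_image].
#' @export
read_image <- function(path, pixel_size_mm = 0.0625, id = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)"))
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    w <- if (nc >= 3L) c(0.2126, 0.7152, 0.0722) else rep(1 / nc, nc)
    gray <- matrix(0, nrow(raw), ncol(raw))
    for (k in seq_along(w)) gray <- gray + w[k] * raw[, , k]
    raw <- gray
  }
  if (any(dim(raw) == 0L)) stop("zero-sized image: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  us_image(round(raw * 255), pixel_size_mm = pixel_size_mm, id = id)
}

#' Write an ultrasound image to PNG or TIFF
#'
#' Written and re-read images round-trip bit-identically.
#'
#' @param image A [us_image].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "us_image"))
  x <- round(image$pixels) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'"))
  invisible(path)
}

valid_sites <- c("insertion", "above2cm", "above4cm")

#' Annotation set for one image
#'
#' Holds the analyst-drawn region of interest (ROI) polygon used for spatial
#' frequency analysis, the superficial and deep tendon border polylines used
#' for thickness measurement, and (at the insertion site) the calcaneus
#' trace. All coordinates are 0-based `(row, col)` pixel positions; border
#' polylines must be single-valued functions of the column index.
#'
#' @param roi Closed polygon, n x 2 matrix of `(row, col)` vertices (at least
#'   3, positive area, no self-intersection). The closing edge is implicit.
#' @param superficial_border,deep_border Border polylines, n x 2 matrices.
#' @param calcaneus_trace Optional polyline marking the calcaneal cortex.
#' @param site_label One of `"insertion"`, `"above2cm"`, `"above4cm"`.
#'
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(roi, superficial_border, deep_border,
                           calcaneus_trace = NULL,
                           site_label = "above2cm") {
  roi <- as_coords(roi, "roi")
  if (nrow(roi) < 3L) stop("roi must have at least 3 vertices")
  if (polygon_area(roi) <= 0) stop("roi must have positive area")
  if (polygon_self_intersects(roi)) stop("roi polygon is self-intersecting")
  check_border <- function(b, what) {
    b <- as_coords(b, what)
    if (nrow(b) < 2L) stop(what, " must have at least 2 points")
    b <- b[order(b[, "col"]), , drop = FALSE]
    if (anyDuplicated(b[, "col"])) {
      stop(what, " has duplicate column positions (must be single-valued)")
    }
    b
  }
  superficial_border <- check_border(superficial_border, "superficial_border")
  deep_border <- check_border(deep_border, "deep_border")
  if (!is.null(calcaneus_trace)) {
    calcaneus_trace <- as_coords(calcaneus_trace, "calcaneus_trace")
  }
  if (!site_label %in% valid_sites) {
    stop("site_label must be one of: ", paste(valid_sites, collapse = ", "))
  }
  structure(list(roi = roi, superficial_border = superficial_border,
                 deep_border = deep_border,
                 calcaneus_trace = calcaneus_trace,
                 site_label = site_label),
            class = "annotation_set")
}

annotation_schema <- "tendon-sfa/1"

#' Read an annotation sidecar (JSON)
#'
#' Sidecars use the versioned `tendon-sfa/1` schema: keys `roi`,
#' `superficial_border`, `deep_border`, optional `calcaneus_trace`, and
#' `site_label`, with coordinates as `[row, col]` pairs.
#'
#' @param path Path to the JSON sidecar.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation sidecar not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("roi", "superficial_border", "deep_border", "site_label")) {
    if (is.null(j[[key]])) stop("annotation sidecar missing key '", key, "'")
  }
  annotation_set(roi = j$roi,
                 superficial_border = j$superficial_border,
                 deep_border = j$deep_border,
                 calcaneus_trace = j$calcaneus_trace,
                 site_label = j$site_label)
}

#' Write an annotation sidecar (JSON)
#' @param ann An [annotation_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  obj <- list(schema = annotation_schema,
              site_label = ann$site_label,
              roi = unname(ann$roi),
              superficial_border = unname(ann$superficial_border),
              deep_border = unname(ann$deep_border))
  if (!is.null(ann$calcaneus_trace)) {
    obj$calcaneus_trace <- unname(ann$calcaneus_trace)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort manifest (CSV)
#'
#' The manifest maps each image to its subject, group, limb and site:
#' columns `subject_id, group, limb, site, image, annotations`. Control-group
#' rows carry `limb = "control"` (the right limb of neurologically intact
#' participants); stroke rows carry `paretic` or `non_paretic`.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with the columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "limb", "site", "image", "annotations")
  missing <- setdiff(req, names(m))
  if (length(missing)) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(m$group %in% c("stroke", "control"))) {
    stop("manifest group must be 'stroke' or 'control'")
  }
  bad <- (m$group == "control" & m$limb != "control") |
    (m$group == "stroke" & !m$limb %in% c("paretic", "non_paretic"))
  if (any(bad)) stop("manifest limb labels inconsistent with group in row(s) ",
                     paste(which(bad), collapse = ", "))
  if (anyDuplicated(m[, c("subject_id", "limb", "site")])) {
    stop("manifest (subject, limb, site) rows must be unique")
  }
  m
}

#' Write a result table (CSV)
#'
#' Writes records with a stable column order and floats rounded to 6
#' significant digits, so that write -> read -> write is byte-identical.
#'
#' @param records A data.frame (possibly with zero rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
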