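# Coordinate and manifest I/O.
#
# Cone coordinate files are plain delimited text with two numeric columns
# (x, y), comma- or tab-separated, with an optional single header line.
# Units are declared by the caller (the manifest), never inside the file.
# Coordinate convention: origin at the ROI top-left corner, x rightward,
# y downward, continuous micrometre coordinates.

.MERIDIANS <- c("unspecified", "superior", "inferior", "nasal", "temporal")

#' ROI metadata
#'
#' Describes one square-ish region of interest cropped from an AOSLO montage:
#' its physical size, the pixel scale used to convert click coordinates to
#' micrometres, the eye's axial length and the ROI's retinal eccentricity.
#'
#' @param subject_id,roi_id Character identifiers.
#' @param width_um,height_um ROI dimensions in micrometres (> 0).
#' @param scale_um_per_px Image scale in micrometres per pixel (> 0).
#' @param axial_length_mm Axial length of the imaged eye in millimetres;
#'   must lie in the plausible human range 15--35 mm.
#' @param eccentricity_um Retinal distance of the ROI centre from fixation,
#'   in micrometres (>= 0).
#' @param meridian Retinal meridian of the ROI, one of `"superior"`,
#'   `"inferior"`, `"nasal"`, `"temporal"` or `"unspecified"`.
#'
#' @return An object of class `roi_meta`.
#' @examples
#' roi_meta("s01", "r01", 70, 70, 0.45, 23.7, 450, "nasal")
#' @export
roi_meta <- function(subject_id, roi_id, width_um, height_um, scale_um_per_px,
                     axial_length_mm, eccentricity_um,
                     meridian = "unspecified") {
  stopifnot(length(subject_id) == 1L, length(roi_id) == 1L)
  meridian <- match.arg(meridian, .MERIDIANS)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  width_um <- num1(width_um, "width_um")
  height_um <- num1(height_um, "height_um")
  scale_um_per_px <- num1(scale_um_per_px, "scale_um_per_px")
  axial_length_mm <- num1(axial_length_mm, "axial_length_mm")
  eccentricity_um <- num1(eccentricity_um, "eccentricity_um")
  if (width_um <= 0 || height_um <= 0)
    stop("ROI width_um and height_um must be positive", call. = FALSE)
  if (scale_um_per_px <= 0)
    stop("scale_um_per_px must be positive", call. = FALSE)
  if (axial_length_mm < 15 || axial_length_mm > 35)
    stop("axial_length_mm must lie in [15, 35] mm", call. = FALSE)
  if (eccentricity_um < 0)
    stop("eccentricity_um must be non-negative", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id),
         roi_id = as.character(roi_id),
         width_um = width_um, height_um = height_um,
         scale_um_per_px = scale_um_per_px,
         axial_length_mm = axial_length_mm,
         eccentricity_um = eccentricity_um,
         meridian = meridian),
    class = "roi_meta")
}

#' @export
print.roi_meta <- function(x, ...) {
  cat(sprintf("ROI %s/%s: %.1f x %.1f um, %.4f um/px, AL %.2f mm, ecc %.0f um (%s)\n",
              x$subject_id, x$roi_id, x$width_um, x$height_um,
              x$scale_um_per_px, x$axial_length_mm, x$eccentricity_um,
              x$meridian))
  invisible(x)
}

#' Cone coordinate set for one ROI and one annotator
#'
#' Holds an ordered list of cone centre coordinates, in micrometres, tied to
#' one ROI and one annotator label (a human grader or automated detector).
#' Coordinates outside the ROI rectangle are dropped with a warning, and
#' bit-identical duplicate rows (double-click artefacts) are collapsed to a
#' single point, also with a warning. The numbers of dropped and collapsed
#' rows are kept in attributes `n_dropped` and `n_duplicates`.
#'
#' @param coords A two-column numeric matrix or data frame of (x, y)
#'   coordinates in micrometres; zero rows are allowed.
#' @param roi A [roi_meta()] object.
#' @param annotator Single character label, e.g. `"grader1A"`.
#'
#' @return An object of class `cone_points`: a list with elements `roi`,
#'   `annotator` and `coords` (an n x 2 numeric matrix with columns
#'   `x`, `y`).
#' @examples
#' roi <- roi_meta("s01", "r01", 100, 100, 0.45, 24, 500)
#' cone_points(cbind(c(10, 30), c(20, 40)), roi, "grader1A")
#' @export
cone_points <- function(coords, roi, annotator) {
  if (!inherits(roi, "roi_meta")) stop("'roi' must be a roi_meta object", call. = FALSE)
  stopifnot(is.character(annotator), length(annotator) == 1L)
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), ncol = 2L)
  if (ncol(coords) != 2L)
    stop("'coords' must have exactly two columns (x, y)", call. = FALSE)
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  inb <- coords[, 1L] >= 0 & coords[, 1L] <= roi$width_um &
         coords[, 2L] >= 0 & coords[, 2L] <= roi$height_um
  n_dropped <- sum(!inb)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d point(s) outside ROI bounds", n_dropped),
            call. = FALSE)
    coords <- coords[inb, , drop = FALSE]
  }
  dup <- duplicated(coords)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning(sprintf("collapsed %d duplicate coordinate(s)", n_dup),
            call. = FALSE)
    coords <- coords[!dup, , drop = FALSE]
  }
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(roi = roi, annotator = annotator, coords = coords),
            class = "cone_points",
            n_dropped = n_dropped, n_duplicates = n_dup)
}

#' @export
print.cone_points <- function(x, ...) {
  cat(sprintf("<cone_points> %s, ROI %s/%s: %d cones\n", x$annotator,
              x$roi$subject_id, x$roi$roi_id, nrow(x$coords)))
  invisible(x)
}

#' Number of cones in a cone_points set
#' @param x A `cone_points` object.
#' @return Integer count.
#' @export
n_cones <- function(x) {
  stopifnot(inherits(x, "cone_points"))
  nrow(x$coords)
}

# Extract a bare coordinate matrix from cone_points or matrix-like input.
.as_coords <- function(x) {
  if (inherits(x, "cone_points")) return(x$coords)
  m <- as.matrix(x)
  if (length(m) == 0L) m <- matrix(numeric(0), ncol = 2L)
  if (ncol(m) != 2L) stop("coordinates must have two columns", call. = FALSE)
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' Axial-length-proportional image scale
#'
#' AOSLO image scales are set for a reference eye; the retinal magnification
#' of an individual eye scales (to first order) linearly with its axial
#' length, so the micrometre-per-pixel scale is adjusted proportionally.
#'
#' @param axial_length_mm Axial length of the imaged eye, mm (> 0).
#' @param reference_axial_length_mm Axial length the base scale was calibrated
#'   for, mm (> 0); 24 mm is a conventional emmetropic reference.
#' @param base_um_per_px Scale at the reference axial length, um/px (> 0).
#'
#' @return The adjusted scale in micrometres per pixel:
#'   `base_um_per_px * axial_length_mm / reference_axial_length_mm`.
#' @examples
#' scale_factor(25.23, 24, 0.45)
#' @export
scale_factor <- function(axial_length_mm, reference_axial_length_mm = 24,
                         base_um_per_px = 1) {
  vals <- c(axial_length_mm, reference_axial_length_mm, base_um_per_px)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments to scale_factor() must be positive finite numbers",
         call. = FALSE)
  base_um_per_px * axial_length_mm / reference_axial_length_mm
}

# Split one line of a delimited coordinate file. Delimiter is auto-detected
# per file (comma if any comma present, else tab, else whitespace).
.detect_sep <- function(lines) {
  if (any(grepl(",", lines, fixed = TRUE))) return(",")
  if (any(grepl("\t", lines, fixed = TRUE))) return("\t")
  " "
}

#' Read a cone coordinate file
#'
#' Reads a two-column delimited text file of cone centre coordinates
#' (comma-, tab- or whitespace-separated; one optional header line is
#' auto-detected and skipped) and returns a [cone_points()] set in
#' micrometres. When `units = "pixels"` the coordinates are multiplied by
#' `roi$scale_um_per_px`.
#'
#' @param path Path to the coordinate file.
#' @param roi A [roi_meta()] object the coordinates belong to.
#' @param units Either `"microns"` (default) or `"pixels"`.
#' @param annotator Annotator label stored in the result; defaults to the
#'   file name without extension.
#'
#' @return A `cone_points` object. Rows outside the ROI bounds are dropped
#'   with a warning (count in attribute `n_dropped`).
#' @export
read_cone_coordinates <- function(path, roi, units = c("microns", "pixels"),
                                  annotator = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(annotator))
    annotator <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L)
    return(cone_points(matrix(numeric(0), ncol = 2L), roi, annotator))
  sep <- .detect_sep(lines[lines_keep])
  parse_line <- function(ln) {
    parts <- if (sep == " ") strsplit(trimws(ln), "[[:space:]]+")[[1L]]
             else trimws(strsplit(ln, sep, fixed = TRUE)[[1L]])
    suppressWarnings(as.numeric(parts))
  }
  first <- parse_line(lines[lines_keep[1L]])
  start <- 1L
  if (any(is.na(first))) start <- 2L  # header line
  rows <- lines_keep[seq.int(start, length.out = length(lines_keep) - start + 1L)]
  if (length(rows) == 0L)
    return(cone_points(matrix(numeric(0), ncol = 2L), roi, annotator))
  out <- matrix(NA_real_, nrow = length(rows), ncol = 2L)
  for (k in seq_along(rows)) {
    v <- parse_line(lines[rows[k]])
    if (length(v) < 2L || any(is.na(v[1:2])))
      stop(sprintf("malformed coordinate row at line %d of %s",
                   rows[k], path), call. = FALSE)
    out[k, ] <- v[1:2]
  }
  if (units == "pixels") out <- out * roi$scale_um_per_px
  cone_points(out, roi, annotator)
}

#' Write a cone coordinate file
#'
#' Writes coordinates as comma-separated text with an `x,y` header, at a
#' precision that makes read-after-write reproduce the coordinates to within
#' 1e-9 um.
#'
#' @param points A [cone_points()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cone_coordinates <- function(points, path) {
  stopifnot(inherits(points, "cone_points"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y", con)
  if (nrow(points$coords) > 0L)
    writeLines(sprintf("%.12f,%.12f",
                       points$coords[, 1L], points$coords[, 2L]), con)
  invisible(path)
}

.MANIFEST_COLS <- c("subject_id", "roi_id", "width_um", "height_um",
                    "scale_um_per_px", "axial_length_mm", "eccentricity_um",
                    "meridian")

#' Read an ROI manifest
#'
#' The manifest is a delimited text table (comma or tab separated, header
#' required) with one row per ROI and columns `subject_id`, `roi_id`,
#' `width_um`, `height_um`, `scale_um_per_px`, `axial_length_mm`,
#' `eccentricity_um` and `meridian`. Every row is validated through
#' [roi_meta()]; a violated invariant reports the offending row.
#'
#' @param path Path to the manifest file.
#' @return A list of `roi_meta` objects (possibly empty), named
#'   `"<subject_id>/<roi_id>"`.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  missing_cols <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      roi_meta(df$subject_id[i], df$roi_id[i], df$width_um[i], df$height_um[i],
               df$scale_um_per_px[i], df$axial_length_mm[i],
               df$eccentricity_um[i], df$meridian[i]),
      error = function(e)
        stop(sprintf("manifest row %d invalid: %s", i, conditionMessage(e)),
             call. = FALSE))
  }
  names(out) <- vapply(out, function(r) paste(r$subject_id, r$roi_id, sep = "/"), "")
  out
}

#' Write an ROI manifest
#'
#' @param rois A list of [roi_meta()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_manifest <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(subject_id = r$subject_id, roi_id = r$roi_id,
               width_um = sprintf("%.6f", r$width_um),
               height_um = sprintf("%.6f", r$height_um),
               scale_um_per_px = sprintf("%.8f", r$scale_um_per_px),
               axial_length_mm = sprintf("%.4f", r$axial_length_mm),
               eccentricity_um = sprintf("%.4f", r$eccentricity_um),
               meridian = r$meridian, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- as.data.frame(setNames(rep(list(character(0)), length(.MANIFEST_COLS)),
                                 .MANIFEST_COLS))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
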