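# Synthetic cone mosaics, annotator noise, and whole-study generation.
#
# Mosaics are jittered lattices: lattice spacing is chosen so the lattice
# density equals the target (hexagonal s = sqrt(2 / (sqrt(3) d)), square
# s = 1 / sqrt(d)), every point gets isotropic Gaussian jitter, and points
# that land outside the ROI are dropped. Annotators are modelled with three
# parameters: a miss rate (independent Bernoulli deletion of true cones),
# a false-mark rate (Poisson count of spurious marks placed uniformly, kept
# outside a half-spacing exclusion radius of true cones so they cannot be
# absorbed into true matches), and a localisation jitter SD.

#' Generate a lattice cone mosaic at a target density
#'
#' @param roi A [roi_meta()] object defining the region.
#' @param target_density_cones_per_mm2 Target bound density, cones/mm2 (> 0).
#' @param lattice `"hexagonal"` (default; the natural cone packing) or
#'   `"square"`.
#' @param jitter_sd_um SD of the isotropic Gaussian positional jitter, um.
#' @param seed Integer seed; the result is a deterministic function of the
#'   spec. Ignored (no RNG touched) when `jitter_sd_um = 0`.
#' @param annotator Label for the resulting set (default `"truth"`).
#' @return A [cone_points()] object.
#' @examples
#' roi <- roi_meta("s", "r", 200, 200, 0.5, 24, 0)
#' m <- generate_mosaic(roi, 10000, "square", jitter_sd_um = 0)
#' bound_density(m)$density_cones_per_mm2  # exactly 1e4
#' @export
generate_mosaic <- function(roi, target_density_cones_per_mm2,
                            lattice = c("hexagonal", "square"),
                            jitter_sd_um = 0, seed = 1L,
                            annotator = "truth") {
  stopifnot(inherits(roi, "roi_meta"))
  lattice <- match.arg(lattice)
  d <- target_density_cones_per_mm2
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("target density must be a positive number", call. = FALSE)
  if (jitter_sd_um < 0) stop("jitter_sd_um must be >= 0", call. = FALSE)
  d_um2 <- d / 1e6
  s <- if (lattice == "hexagonal") sqrt(2 / (sqrt(3) * d_um2))
       else 1 / sqrt(d_um2)
  dy <- if (lattice == "hexagonal") s * sqrt(3) / 2 else s
  w <- roi$width_um; h <- roi$height_um
  ny <- max(1L, floor(h / dy))
  y0 <- (h - (ny - 1) * dy) / 2
  pts <- list()
  for (r in seq_len(ny)) {
    off <- if (lattice == "hexagonal" && r %% 2L == 0L) s / 2 else 0
    nx <- max(1L, floor((w - off) / s))
    x0 <- (w - off - (nx - 1) * s) / 2 + off
    pts[[r]] <- cbind(x0 + (seq_len(nx) - 1L) * s,
                      rep(y0 + (r - 1L) * dy, nx))
  }
  coords <- do.call(rbind, pts)
  if (jitter_sd_um > 0) {
    set.seed(as.integer(seed))
    coords <- coords + matrix(rnorm(length(coords), sd = jitter_sd_um),
                              ncol = 2L)
    inb <- coords[, 1L] >= 0 & coords[, 1L] <= w &
           coords[, 2L] >= 0 & coords[, 2L] <= h
    coords <- coords[inb, , drop = FALSE]
  }
  if (nrow(coords) < 4L)
    stop("infeasible mosaic spec: fewer than 4 points fit the ROI", call. = FALSE)
  cone_points(coords, roi, annotator)
}

#' Simulate an imperfect annotator from a true mosaic
#'
#' Each true cone is retained with probability `1 - miss_rate` and displaced
#' by isotropic Gaussian localisation noise (clamped into the ROI). Spurious
#' marks are added as a Poisson count with mean
#' `false_rate / (1 - false_rate) * n_retained` — so that on average a
#' fraction `false_rate` of the annotator's marks is spurious — placed
#' uniformly in the ROI but outside an exclusion radius of half the median
#' nearest-neighbour spacing around every true cone.
#'
#' @param truth A [cone_points()] object (the true mosaic).
#' @param miss_rate Probability in `[0, 1)` of missing a true cone.
#' @param false_rate Expected fraction of the annotator's marks that are
#'   spurious, in `[0, 1)`.
#' @param localization_sd_um SD of the Gaussian localisation noise, um.
#' @param seed Integer seed (deterministic output per seed).
#' @param annotator Label for the simulated set.
#' @return A [cone_points()] object (retained marks first, spurious last).
#' @export
simulate_annotator <- function(truth, miss_rate = 0, false_rate = 0,
                               localization_sd_um = 0, seed = 1L,
                               annotator = "sim") {
  stopifnot(inherits(truth, "cone_points"))
  if (miss_rate < 0 || miss_rate >= 1 || false_rate < 0 || false_rate >= 1)
    stop("miss_rate and false_rate must lie in [0, 1)", call. = FALSE)
  if (localization_sd_um < 0)
    stop("localization_sd_um must be >= 0", call. = FALSE)
  roi <- truth$roi
  coords <- truth$coords
  n <- nrow(coords)
  set.seed(as.integer(seed))
  keep <- if (miss_rate > 0) runif(n) >= miss_rate else rep(TRUE, n)
  out <- coords[keep, , drop = FALSE]
  if (localization_sd_um > 0 && nrow(out) > 0L) {
    out <- out + matrix(rnorm(length(out), sd = localization_sd_um), ncol = 2L)
    out[, 1L] <- pmin(pmax(out[, 1L], 0), roi$width_um)
    out[, 2L] <- pmin(pmax(out[, 2L], 0), roi$height_um)
  }
  if (false_rate > 0 && nrow(out) > 0L) {
    n_false <- rpois(1L, false_rate / (1 - false_rate) * nrow(out))
    if (n_false > 0L) {
      excl <- if (n >= 2L) median(.nn_distances(coords)) / 2 else 0
      placed <- matrix(numeric(0), ncol = 2L)
      tries <- 0L
      while (nrow(placed) < n_false && tries < 200L) {
        tries <- tries + 1L
        m <- 4L * (n_false - nrow(placed))
        cand <- cbind(runif(m, 0, roi$width_um), runif(m, 0, roi$height_um))
        if (excl > 0) {
          dmin <- apply(cand, 1L, function(p)
            min(sqrt((coords[, 1L] - p[1L])^2 + (coords[, 2L] - p[2L])^2)))
          cand <- cand[dmin > excl, , drop = FALSE]
        }
        placed <- rbind(placed, cand)
      }
      out <- rbind(out, placed[seq_len(min(n_false, nrow(placed))), ,
                               drop = FALSE])
    }
  }
  suppressWarnings(cone_points(out, roi, annotator))
}

#' Study specification
#'
#' Bundles the distributional parameters of a multi-subject annotation
#' study: subject and ROI counts, ROI geometry, the across-ROI density
#' distribution (log-normal, parameterised by its natural-scale mean and
#' SD), the eccentricity range carried as metadata, and the roster of
#' simulated annotators. Defaults emulate a 17-subject AOSLO study: 5--16
#' square ROIs per subject with 70 +/- 22 um sides, eccentricities
#' 135--2210 um, densities with mean 30,600 and SD 14,200 cones/mm2, and
#' three graders with miss/false/jitter noise in the range reported for
#' experienced human graders.
#'
#' @param n_subjects Number of subjects.
#' @param rois_per_subject Integer range `c(min, max)` of ROIs per subject.
#' @param density_mean,density_sd Natural-scale mean and SD of the
#'   across-ROI bound-density distribution (log-normal), cones/mm2.
#' @param roi_side_mean,roi_side_sd Normal parameters of the square ROI side
#'   length, um (truncated below at `roi_side_min`).
#' @param roi_side_min Lower truncation of the ROI side, um.
#' @param eccentricity_range Range `c(min, max)` of ROI eccentricities, um.
#' @param axial_length_mean,axial_length_sd Normal parameters of the
#'   subjects' axial length, mm (truncated to `[15, 35]`).
#' @param base_um_per_px,reference_axial_length_mm Scale calibration passed
#'   to [scale_factor()].
#' @param annotators Named list: for each annotator label a list with
#'   `miss_rate`, `false_rate`, `localization_sd_um`.
#' @param lattice Lattice type for the true mosaics.
#' @param mosaic_jitter_frac Positional jitter of the true mosaic as a
#'   fraction of the lattice spacing.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(n_subjects = 17L,
                       rois_per_subject = c(5L, 16L),
                       density_mean = 30600, density_sd = 14200,
                       roi_side_mean = 70, roi_side_sd = 22,
                       roi_side_min = 30,
                       eccentricity_range = c(135, 2210),
                       axial_length_mean = 23.71, axial_length_sd = 0.98,
                       base_um_per_px = 0.45,
                       reference_axial_length_mm = 24,
                       annotators = list(
                         grader1B = list(miss_rate = 0.06, false_rate = 0.18,
                                         localization_sd_um = 1),
                         grader2 = list(miss_rate = 0.12, false_rate = 0.16,
                                        localization_sd_um = 1),
                         grader3 = list(miss_rate = 0.12, false_rate = 0.23,
                                        localization_sd_um = 1)),
                       lattice = "hexagonal",
                       mosaic_jitter_frac = 0.10) {
  stopifnot(n_subjects >= 1L, length(rois_per_subject) == 2L,
            rois_per_subject[1L] >= 1L,
            rois_per_subject[2L] >= rois_per_subject[1L],
            density_mean > 0, density_sd >= 0, roi_side_mean > 0,
            roi_side_min > 0, length(eccentricity_range) == 2L,
            eccentricity_range[1L] >= 0,
            eccentricity_range[2L] >= eccentricity_range[1L],
            mosaic_jitter_frac >= 0)
  structure(as.list(environment()), class = "study_spec")
}

# log-normal parameters from natural-scale mean and SD
.lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a full synthetic annotation study on disk
#'
#' Draws per-subject axial lengths and ROI counts, per-ROI sides, densities
#' and eccentricities from the spec's distributions, generates a true mosaic
#' and every annotator's simulated marking for each ROI, and writes them in
#' the package's coordinate-file format together with the ROI manifest. All
#' randomness derives from `seed`; the same seed reproduces byte-identical
#' files.
#'
#' @param spec A [study_spec()].
#' @param output_dir Directory to write into (created if needed).
#' @param seed Integer master seed.
#' @return The manifest path, invisibly, with attribute `rois` (the list of
#'   `roi_meta`) and `annotators` (labels including `"truth"`).
#' @export
generate_study <- function(spec = study_spec(), output_dir, seed = 1L) {
  stopifnot(inherits(spec, "study_spec"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  lp <- .lnorm_pars(spec$density_mean, spec$density_sd)
  rois <- list()
  files <- character(0)
  for (si in seq_len(spec$n_subjects)) {
    subject <- sprintf("s%02d", si)
    al <- round(min(35, max(15, rnorm(1L, spec$axial_length_mean,
                                      spec$axial_length_sd))), 4L)
    scale <- scale_factor(al, spec$reference_axial_length_mm,
                          spec$base_um_per_px)
    n_roi <- sample(seq.int(spec$rois_per_subject[1L],
                            spec$rois_per_subject[2L]), 1L)
    for (ri in seq_len(n_roi)) {
      dens <- rlnorm(1L, lp$meanlog, lp$sdlog)
      d_um2 <- dens / 1e6
      spacing <- if (spec$lattice == "hexagonal") sqrt(2 / (sqrt(3) * d_um2))
                 else 1 / sqrt(d_um2)
      # sides quantised to nm so the manifest represents them exactly, and
      # floored at 4.5 lattice spacings so every ROI supports bound Voronoi
      # cells for every (noisy) annotator
      side <- round(max(spec$roi_side_min, 4.5 * spacing,
                        rnorm(1L, spec$roi_side_mean, spec$roi_side_sd)), 3L)
      ecc <- round(runif(1L, spec$eccentricity_range[1L],
                         spec$eccentricity_range[2L]), 4L)
      mer <- sample(c("superior", "inferior", "nasal", "temporal"), 1L)
      roi <- roi_meta(subject, sprintf("r%02d", ri), side, side, scale, al,
                      ecc, mer)
      seeds <- sample.int(.Machine$integer.max - 1L,
                          1L + length(spec$annotators))
      truth <- generate_mosaic(roi, dens, spec$lattice,
                               jitter_sd_um = spec$mosaic_jitter_frac * spacing,
                               seed = seeds[1L], annotator = "truth")
      sets <- list(truth)
      for (ai in seq_along(spec$annotators)) {
        a <- spec$annotators[[ai]]
        sets[[ai + 1L]] <- simulate_annotator(
          truth, miss_rate = a$miss_rate, false_rate = a$false_rate,
          localization_sd_um = a$localization_sd_um, seed = seeds[ai + 1L],
          annotator = names(spec$annotators)[ai])
      }
      for (s in sets) {
        f <- file.path(output_dir, sprintf("%s_%s_%s.csv", subject,
                                           roi$roi_id, s$annotator))
        write_cone_coordinates(s, f)
        files <- c(files, f)
      }
      rois[[length(rois) + 1L]] <- roi
    }
  }
  manifest <- file.path(output_dir, "manifest.csv")
  write_roi_manifest(rois, manifest)
  invisible(structure(manifest, rois = rois,
                      annotators = c("truth", names(spec$annotators))))
}

#' Path of one annotator's coordinate file inside a generated study
#'
#' @param output_dir The study directory.
#' @param roi A `roi_meta` from the study manifest.
#' @param annotator Annotator label (including `"truth"`).
#' @return The file path.
#' @export
study_file <- function(output_dir, roi, annotator) {
  file.path(output_dir, sprintf("%s_%s_%s.csv", roi$subject_id, roi$roi_id,
                                annotator))
}
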