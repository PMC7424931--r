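# Voronoi tessellation and bound cone density.
#
# Bound cone density divides the number of cones whose Voronoi cells lie
# completely inside the ROI by the summed area of those cells, which removes
# the bias that partially visible border cells would otherwise introduce.
# Cells are computed exactly by intersecting perpendicular-bisector
# half-planes, visiting neighbours in ascending distance with a
# security-radius stop: once half the distance to the next neighbour exceeds
# the farthest current cell vertex, no further neighbour can cut the cell.

# Clip a convex polygon (m x 2 matrix, counter-clockwise or clockwise) by the
# half-plane {v : (v - m0) . u <= 0}. Sutherland-Hodgman, one plane.
.clip_halfplane <- function(poly, m0, u) {
  s <- (poly[, 1L] - m0[1L]) * u[1L] + (poly[, 2L] - m0[2L]) * u[2L]
  if (all(s <= 0)) return(poly)
  np <- nrow(poly)
  out <- matrix(NA_real_, nrow = 2L * np, ncol = 2L)
  cnt <- 0L
  for (k in seq_len(np)) {
    k2 <- if (k == np) 1L else k + 1L
    in1 <- s[k] <= 0
    in2 <- s[k2] <= 0
    if (in1) {
      cnt <- cnt + 1L
      out[cnt, ] <- poly[k, ]
    }
    if (in1 != in2) {
      t <- s[k] / (s[k] - s[k2])
      cnt <- cnt + 1L
      out[cnt, ] <- poly[k, ] + t * (poly[k2, ] - poly[k, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

# Shoelace area of a simple polygon.
.polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

.is_collinear <- function(coords, tol = 1e-9) {
  ctr <- sweep(coords, 2L, colMeans(coords))
  sv <- svd(ctr, nu = 0L, nv = 0L)$d
  sv[2L] <= tol * max(sv[1L], 1)
}

#' Voronoi cells of a cone coordinate set within an ROI
#'
#' Computes the Euclidean Voronoi tessellation of the points and flags each
#' cell as *bound* when it is a closed polygon all of whose vertices lie
#' inside or on the ROI rectangle `[0, width] x [0, height]`. Cells are never
#' clipped to the ROI: a cell that crosses the boundary is excluded entirely
#' from density calculations. Areas are computed by the shoelace formula and
#' are `NA` for unbounded cells.
#'
#' @param points A [cone_points()] object (or a bare coordinate matrix if
#'   `roi` is given). At least 4 points, not all collinear.
#' @param roi A [roi_meta()] object; defaults to the ROI carried by `points`.
#' @return An object of class `voronoi_result`: list with `cell_areas_um2`
#'   (numeric, `NA` for unbounded cells), `is_bound` (logical), `cells`
#'   (list of vertex matrices, `NULL` for unbounded cells) and `n`.
#' @examples
#' roi <- roi_meta("s", "r", 100, 100, 0.5, 24, 0)
#' g <- as.matrix(expand.grid(x = seq(30, 70, 10), y = seq(30, 70, 10)))
#' v <- voronoi_cells(cone_points(g, roi, "truth"))
#' sum(v$is_bound)  # the 9 interior lattice points
#' @export
voronoi_cells <- function(points, roi = NULL) {
  if (inherits(points, "cone_points")) {
    if (is.null(roi)) roi <- points$roi
    coords <- points$coords
  } else {
    if (is.null(roi)) stop("'roi' is required when 'points' is a bare matrix",
                           call. = FALSE)
    coords <- .as_coords(points)
  }
  n <- nrow(coords)
  if (n < 4L)
    stop("Voronoi analysis needs at least 4 points", call. = FALSE)
  if (.is_collinear(coords))
    stop("degenerate geometry: points are (nearly) collinear", call. = FALSE)
  w <- roi$width_um; h <- roi$height_um
  span <- max(w, h, diff(range(coords[, 1L])), diff(range(coords[, 2L])))
  guard <- 8 * span + 1
  box <- rbind(c(-guard, -guard), c(w + guard, -guard),
               c(w + guard, h + guard), c(-guard, h + guard))
  box_tol <- 1e-7 * guard
  roi_tol <- 1e-9 * (1 + span)

  D <- as.matrix(dist(coords))
  areas <- rep(NA_real_, n)
  bound <- logical(n)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])
    nb <- nb[nb != i]
    poly <- box
    p <- coords[i, ]
    rmax <- sqrt(max((poly[, 1L] - p[1L])^2 + (poly[, 2L] - p[2L])^2))
    for (j in nb) {
      dij <- D[i, j]
      if (dij <= 1e-12) next  # coincident points never reach here after dedup
      if (dij / 2 > rmax) break
      u <- coords[j, ] - p
      m0 <- (coords[j, ] + p) / 2
      poly <- .clip_halfplane(poly, m0, u)
      rmax <- sqrt(max((poly[, 1L] - p[1L])^2 + (poly[, 2L] - p[2L])^2))
    }
    closed <- !any(poly[, 1L] <= -guard + box_tol | poly[, 1L] >= w + guard - box_tol |
                   poly[, 2L] <= -guard + box_tol | poly[, 2L] >= h + guard - box_tol)
    if (closed) {
      areas[i] <- .polygon_area(poly)
      cells[[i]] <- poly
      bound[i] <- all(poly[, 1L] >= -roi_tol & poly[, 1L] <= w + roi_tol &
                      poly[, 2L] >= -roi_tol & poly[, 2L] <= h + roi_tol)
    }
  }
  structure(list(cell_areas_um2 = areas, is_bound = bound, cells = cells,
                 n = n),
            class = "voronoi_result")
}

#' @export
print.voronoi_result <- function(x, ...) {
  cat(sprintf("<voronoi_result> %d points, %d bound cells, %d unbounded\n",
              x$n, sum(x$is_bound), sum(is.na(x$cell_areas_um2))))
  invisible(x)
}

#' Bound cone density of an ROI
#'
#' The number of cones with complete Voronoi cells inside the ROI divided by
#' the sum of those cells' areas, reported in cones per square millimetre.
#'
#' @inheritParams voronoi_cells
#' @return An object of class `bound_density`: list with `n_bound`,
#'   `total_bound_area_um2` and `density_cones_per_mm2`.
#' @examples
#' roi <- roi_meta("s", "r", 100, 100, 0.5, 24, 0)
#' g <- as.matrix(expand.grid(x = seq(5, 95, 10), y = seq(5, 95, 10)))
#' bound_density(cone_points(g, roi, "truth"))$density_cones_per_mm2  # 1e4
#' @export
bound_density <- function(points, roi = NULL) {
  v <- voronoi_cells(points, roi)
  nb <- sum(v$is_bound)
  if (nb == 0L)
    stop("no bound Voronoi cells inside the ROI", call. = FALSE)
  area <- sum(v$cell_areas_um2[v$is_bound])
  structure(list(n_bound = nb, total_bound_area_um2 = area,
                 density_cones_per_mm2 = nb / area * 1e6),
            class = "bound_density")
}

#' @export
print.bound_density <- function(x, ...) {
  cat(sprintf("<bound_density> %d bound cones / %.1f um2 = %.0f cones/mm2\n",
              x$n_bound, x$total_bound_area_um2, x$density_cones_per_mm2))
  invisible(x)
}

#' Per-ROI density table for several annotators
#'
#' @param sets A list of [cone_points()] objects (any ROIs/annotators).
#' @return A data frame with columns `subject_id`, `roi_id`, `annotator`,
#'   `n_bound`, `total_bound_area_um2`, `density_cones_per_mm2`.
#' @export
density_table <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "cone_points")))
  do.call(rbind, lapply(sets, function(s) {
    bd <- bound_density(s)
    data.frame(subject_id = s$roi$subject_id, roi_id = s$roi$roi_id,
               annotator = s$annotator, n_bound = bd$n_bound,
               total_bound_area_um2 = bd$total_bound_area_um2,
               density_cones_per_mm2 = bd$density_cones_per_mm2)
  }))
}
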