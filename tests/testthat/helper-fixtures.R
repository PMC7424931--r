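# Fixtures shared across test files. Everything is generated in code.

make_roi <- function(w = 100, h = w, scale = 0.5, al = 24, ecc = 500,
                     subject = "s01", roi_id = "r01") {
  roi_meta(subject, roi_id, w, h, scale, al, ecc)
}

# square grid of points, spacing s, lower-left corner at (x0, y0)
grid_points <- function(nx, ny = nx, s = 10, x0 = s / 2, y0 = s / 2) {
  as.matrix(expand.grid(x = x0 + (seq_len(nx) - 1) * s,
                        y = y0 + (seq_len(ny) - 1) * s))
}

# hexagonal lattice covering [0, w] x [0, h] with spacing s
hex_points <- function(s, w, h = w) {
  dy <- s * sqrt(3) / 2
  pts <- list()
  r <- 0L
  y <- 0
  while (y <= h) {
    off <- if (r %% 2L == 1L) s / 2 else 0
    x <- seq(off, w, by = s)
    pts[[r + 1L]] <- cbind(x, rep(y, length(x)))
    r <- r + 1L
    y <- r * dy
  }
  do.call(rbind, pts)
}

# random points in an ROI with a minimum pairwise separation (rejection)
separated_points <- function(n, w, h = w, min_sep = 5) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 20000L) {
    tries <- tries + 1L
    p <- c(runif(1, 0, w), runif(1, 0, h))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep)
      pts <- rbind(pts, p)
  }
  unname(pts)
}
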