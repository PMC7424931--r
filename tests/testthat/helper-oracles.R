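# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Maximum-cardinality bipartite matching under a distance threshold, via
# augmenting paths (Hungarian-style on the unweighted candidate graph).
max_matching_size <- function(gt, comp, threshold) {
  ng <- nrow(gt); nc <- nrow(comp)
  if (ng == 0 || nc == 0) return(0L)
  D <- sqrt(outer(gt[, 1], comp[, 1], "-")^2 +
            outer(gt[, 2], comp[, 2], "-")^2)
  adj <- lapply(seq_len(ng), function(i) which(D[i, ] <= threshold))
  match_comp <- rep(0L, nc)
  try_augment <- function(i, visited) {
    for (j in adj[[i]]) {
      if (visited[j]) next
      visited[j] <- TRUE
      if (match_comp[j] == 0L) {
        match_comp[j] <<- i
        return(TRUE)
      }
      prev <- match_comp[j]
      # temporarily free j and look for an alternative for its owner
      res <- try_augment(prev, visited)
      if (res) {
        match_comp[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(ng)) {
    visited <- rep(FALSE, nc)
    if (try_augment(i, visited)) size <- size + 1L
  }
  size
}

# ICC(2,1) closed form from sums of squares computed directly (no aov()).
icc_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Repeated-measures one-way ANOVA F from direct mean squares.
rm_anova_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  ss_subj <- k * sum((rowMeans(mat) - gm)^2)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_err <- sum((mat - gm)^2) - ss_subj - ss_cond
  msc <- ss_cond / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  f <- msc / mse
  list(f = f, p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# Voronoi bound cells and areas through deldir (independent tessellation
# route); returns per-point area (NA when the deldir cell touches or leaves
# the ROI rectangle) and a bound flag.
deldir_bound_oracle <- function(coords, w, h, eps = 1e-9) {
  dd <- deldir::deldir(coords[, 1], coords[, 2],
                       rw = c(-10 * w, 11 * w, -10 * h, 11 * h))
  tiles <- deldir::tile.list(dd)
  areas <- rep(NA_real_, nrow(coords))
  bound <- logical(nrow(coords))
  for (i in seq_along(tiles)) {
    t <- tiles[[i]]
    on_rw <- isTRUE(any(t$bp))  # touches the enclosing rectangle -> unbounded
    inside <- all(t$x >= -eps & t$x <= w + eps &
                  t$y >= -eps & t$y <= h + eps)
    if (!on_rw) {
      xs <- t$x; ys <- t$y
      areas[i] <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
      bound[i] <- inside
    }
  }
  list(areas = areas, bound = bound)
}
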