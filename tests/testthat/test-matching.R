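test_that("match_threshold reproduces hand-computed nearest-neighbour stats", {
  ts <- match_threshold(rbind(c(0, 0), c(10, 0), c(1, 0), c(15, 0)))
  # NN distances are 1, 5, 1, 5: mean 3, sample SD sqrt(16/3)
  expect_equal(ts$mean_nn_um, 3)
  expect_equal(ts$sd_nn_um, sqrt(16 / 3))
  expect_equal(ts$threshold_um, 3 + 2 * sqrt(16 / 3))
  # degenerate cases
  dup <- match_threshold(rbind(c(2, 2), c(2, 2)))
  expect_equal(dup$threshold_um, 0)
  line <- match_threshold(cbind(0:9, 0))
  expect_equal(line$mean_nn_um, 1)
  expect_equal(line$sd_nn_um, 0)
  expect_equal(line$threshold_um, 1)
  expect_error(match_threshold(rbind(c(0, 0))), "at least 2")
})

test_that("match_threshold pools cone_points sets into one master list", {
  roi <- make_roi(100)
  a <- cone_points(rbind(c(0, 0), c(10, 0)), roi, "a")
  b <- cone_points(rbind(c(1, 0), c(15, 0)), roi, "b")
  expect_equal(match_threshold(list(a, b))$threshold_um, 3 + 2 * sqrt(16 / 3))
})

test_that("pairwise matching is one-to-one, closest-first, inclusive at the threshold", {
  roi <- make_roi(100)
  gt <- cone_points(rbind(c(0, 0), c(10, 0)), roi, "a")
  comp <- cone_points(rbind(c(1, 0), c(15, 0)), roi, "b")
  pm <- match_pairwise(gt, comp, match_threshold(list(gt, comp)))
  expect_equal(nrow(pm$matched_pairs), 2L)
  expect_equal(sort(pm$matched_pairs$distance_um), c(1, 5))
  expect_length(pm$unmatched_gt, 0L)
  # identical sets match at distance zero under any threshold
  pm0 <- match_pairwise(gt, gt, 0)
  expect_equal(pm0$matched_pairs$distance_um, c(0, 0))
  # two candidates for one gt cone: the closer wins
  pm1 <- match_pairwise(rbind(c(0, 0)), rbind(c(5, 0), c(6, 0)), 7)
  expect_equal(pm1$matched_pairs$comp, 1L)
  expect_equal(pm1$matched_pairs$distance_um, 5)
  expect_equal(pm1$unmatched_comp, 2L)
  # boundary distance counts as within (<=)
  pm2 <- match_pairwise(rbind(c(0, 0)), rbind(c(7, 0)), 7)
  expect_equal(nrow(pm2$matched_pairs), 1L)
  # mismatched ROIs are refused
  other <- cone_points(rbind(c(1, 1)), make_roi(100, roi_id = "r99"), "b")
  expect_error(match_pairwise(gt, other, 5), "same ROI")
})

test_that("confusion counts satisfy the set-size identities", {
  roi <- make_roi(100)
  gt <- cone_points(rbind(c(0, 0), c(10, 0)), roi, "a")
  comp <- cone_points(rbind(c(1, 0), c(15, 0)), roi, "b")
  cc <- confusion_from_match(match_pairwise(gt, comp, 8))
  expect_equal(unlist(cc), c(n_tp = 2L, n_fp = 0L, n_fn = 0L, n_gt = 2L,
                             n_comp = 2L))
  # degenerate: empty comparison set
  cc0 <- confusion_from_match(
    match_pairwise(cbind(1:5, 0), matrix(numeric(0), ncol = 2), 5))
  expect_equal(unlist(cc0), c(n_tp = 0L, n_fp = 0L, n_fn = 5L, n_gt = 5L,
                              n_comp = 0L))
})

test_that("conservation identities hold over random matching problems", {
  set.seed(101)
  for (rep in 1:200) {
    ng <- sample(0:30, 1); nc <- sample(0:30, 1)
    gt <- cbind(runif(ng, 0, 50), runif(ng, 0, 50))
    comp <- cbind(runif(nc, 0, 50), runif(nc, 0, 50))
    pm <- match_pairwise(gt, comp, runif(1, 0, 15))
    cc <- confusion_from_match(pm)
    expect_identical(cc$n_comp, cc$n_tp + cc$n_fp)
    expect_identical(cc$n_gt, cc$n_tp + cc$n_fn)
    expect_false(anyDuplicated(pm$matched_pairs$gt) > 0)
    expect_false(anyDuplicated(pm$matched_pairs$comp) > 0)
    expect_true(all(pm$matched_pairs$distance_um <= pm$threshold$threshold_um))
  }
})

test_that("matching is direction-symmetric and monotone in the threshold", {
  set.seed(202)
  for (rep in 1:50) {
    a <- cbind(runif(15, 0, 40), runif(15, 0, 40))
    b <- cbind(runif(18, 0, 40), runif(18, 0, 40))
    thr <- runif(1, 1, 10)
    n_ab <- nrow(match_pairwise(a, b, thr)$matched_pairs)
    n_ba <- nrow(match_pairwise(b, a, thr)$matched_pairs)
    expect_identical(n_ab, n_ba)
    n_bigger <- nrow(match_pairwise(a, b, thr * 1.5)$matched_pairs)
    expect_gte(n_bigger, n_ab)
  }
})

test_that("greedy matching agrees with exhaustive maximum matching on separated mosaics", {
  set.seed(303)
  mismatches <- 0L
  for (rep in 1:100) {
    gt <- separated_points(sample(4:8, 1), 60, min_sep = 8)
    comp <- gt + matrix(rnorm(length(gt), sd = 1.5), ncol = 2)
    thr <- runif(1, 2, 6)
    greedy <- nrow(match_pairwise(gt, comp, thr)$matched_pairs)
    best <- max_matching_size(gt, comp, thr)
    if (greedy != best) mismatches <- mismatches + 1L
    expect_lte(greedy, best)
  }
  expect_lte(mismatches, 1L)
})

test_that("multigrader clustering keeps one selection per grader per cluster", {
  roi <- make_roi(200)
  base <- separated_points(5, 180, min_sep = 30)
  sets <- lapply(c("a", "b", "c"), function(l) cone_points(base, roi, l))
  cs <- cluster_multigrader(sets)
  expect_length(cs$clusters, 5L)
  expect_true(all(lengths(cs$clusters) == 3L))
  # every point of every annotator in exactly one cluster
  for (lab in c("a", "b", "c")) {
    idx <- unlist(lapply(cs$clusters, function(cl) cl[names(cl) == lab]))
    expect_setequal(idx, 1:5)
  }
  expect_error(cluster_multigrader(sets[1]), "at least 2")
})

test_that("clustering groups nearby cross-grader points and leaves far ones alone", {
  roi <- make_roi(200)
  a <- cone_points(rbind(c(0, 0)), roi, "a")
  b <- cone_points(rbind(c(1, 0)), roi, "b")
  c <- cone_points(rbind(c(100, 100)), roi, "c")
  cs <- cluster_multigrader(list(a, b, c), threshold = 50)
  sizes <- sort(lengths(cs$clusters))
  expect_equal(sizes, c(1L, 2L))
  pairc <- cs$clusters[[which(lengths(cs$clusters) == 2L)]]
  expect_setequal(names(pairc), c("a", "b"))
  # nearer partner wins when two same-grader points compete
  a2 <- cone_points(rbind(c(0, 0), c(2, 0)), roi, "a")
  b2 <- cone_points(rbind(c(1, 0)), roi, "b")
  cs2 <- cluster_multigrader(list(a2, b2), threshold = 1.5)
  pair <- cs2$clusters[[which(lengths(cs2$clusters) == 2L)]]
  expect_equal(unname(pair[["a"]]), 1L)  # d(a1,b1)=1 beats d(a2,b1)=1
})

test_that("two-annotator clustering reproduces pairwise matching counts", {
  set.seed(404)
  roi <- make_roi(150)
  for (rep in 1:30) {
    base <- separated_points(sample(8:15, 1), 140, min_sep = 12)
    a <- cone_points(base, roi, "a")
    bb <- base + matrix(rnorm(length(base), sd = 1), ncol = 2)
    bb <- bb[runif(nrow(bb)) > 0.15, , drop = FALSE]
    b <- suppressWarnings(cone_points(bb, roi, "b"))
    thr <- match_threshold(list(a, b))
    n_pair <- nrow(match_pairwise(a, b, thr)$matched_pairs)
    cs <- cluster_multigrader(list(a, b))
    cc <- confusion_from_clusters(cs, "a", "b")
    expect_identical(cc$n_tp, n_pair)
    expect_identical(cc$n_gt, n_cones(a))
    expect_identical(cc$n_comp, n_cones(b))
  }
})

test_that("cluster confusion counts rotate symmetrically between graders", {
  roi <- make_roi(100)
  # clusters {A,B}, {A}, {B}, {A,B} by construction
  a <- cone_points(rbind(c(10, 10), c(50, 50), c(90, 90)), roi, "A")
  b <- cone_points(rbind(c(10.5, 10), c(30, 70), c(90.5, 90)), roi, "B")
  cs <- cluster_multigrader(list(a, b), threshold = 2)
  ab <- confusion_from_clusters(cs, "A", "B")
  ba <- confusion_from_clusters(cs, "B", "A")
  expect_equal(ab$n_tp, 2L)
  expect_equal(ab$n_fn, 1L)
  expect_equal(ab$n_fp, 1L)
  expect_equal(ba$n_fp, ab$n_fn)
  expect_equal(ba$n_fn, ab$n_fp)
  expect_error(confusion_from_clusters(cs, "A", "Z"), "unknown annotator")
})
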