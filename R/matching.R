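# Point-set matching between annotators.
#
# The decision of whether two selections mark the same cone uses an adaptive
# per-ROI distance threshold: pool every selection from the annotators being
# compared into one master list, compute each point's nearest-neighbour
# distance within that list (self excluded), and set the threshold to
# mean + 2 * SD of those distances. Matching is strictly one-to-one; when
# several candidates fall inside the threshold the closest pair wins, which
# is realised as a single greedy pass over all candidate pairs in ascending
# distance order (deterministic, direction-symmetric).

# Nearest-neighbour distance of each point to any *other* point of the set.
.nn_distances <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points for nearest-neighbour distances",
                   call. = FALSE)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Adaptive matching threshold from a master coordinate list
#'
#' Pools cone selections into a single master list and derives the distance
#' threshold used to decide whether two selections mark the same cone: the
#' mean nearest-coordinate distance plus two times its standard deviation
#' (sample SD, n - 1 denominator). Each point's nearest neighbour is any
#' other point of the master list, itself excluded.
#'
#' @param master A two-column coordinate matrix, a [cone_points()] object, or
#'   a list of either (pooled row-wise). At least 2 points in total.
#' @return An object of class `threshold_stats`: list with `mean_nn_um`,
#'   `sd_nn_um` and `threshold_um = mean_nn_um + 2 * sd_nn_um`.
#' @examples
#' match_threshold(rbind(c(0, 0), c(10, 0), c(1, 0), c(15, 0)))
#' @export
match_threshold <- function(master) {
  if (is.list(master) && !inherits(master, "cone_points") && !is.data.frame(master))
    master <- do.call(rbind, lapply(master, .as_coords))
  coords <- .as_coords(master)
  if (nrow(coords) < 2L)
    stop("master list must contain at least 2 points", call. = FALSE)
  nn <- .nn_distances(coords)
  m <- mean(nn)
  s <- sd(nn)
  structure(list(mean_nn_um = m, sd_nn_um = s, threshold_um = m + 2 * s,
                 n = length(nn)),
            class = "threshold_stats")
}

#' @export
print.threshold_stats <- function(x, ...) {
  cat(sprintf("<threshold_stats> mean NN %.4f um, SD %.4f um, threshold %.4f um (n = %d)\n",
              x$mean_nn_um, x$sd_nn_um, x$threshold_um, x$n))
  invisible(x)
}

.threshold_value <- function(threshold) {
  if (inherits(threshold, "threshold_stats")) return(threshold$threshold_um)
  if (is.numeric(threshold) && length(threshold) == 1L && is.finite(threshold)
      && threshold >= 0)
    return(as.numeric(threshold))
  stop("'threshold' must be a threshold_stats object or a single non-negative number",
       call. = FALSE)
}

.same_roi <- function(a, b) {
  identical(a$roi$subject_id, b$roi$subject_id) &&
    identical(a$roi$roi_id, b$roi$roi_id)
}

#' One-to-one matching of two cone coordinate sets
#'
#' Finds the one-to-one correspondence between a ground-truth set and a
#' comparison set: every (ground-truth, comparison) pair closer than the
#' threshold (inclusive) is a candidate; candidates are accepted greedily in
#' ascending distance order, skipping pairs whose endpoint is already
#' matched. Exact distance ties break on (lower ground-truth index, lower
#' comparison index), so results are deterministic and symmetric in the two
#' directions.
#'
#' @param gt,comp [cone_points()] objects for the same ROI (bare coordinate
#'   matrices are also accepted).
#' @param threshold A [match_threshold()] result or a single non-negative
#'   distance in micrometres.
#' @return An object of class `pair_match`: list with `threshold`,
#'   `matched_pairs` (data frame with columns `gt`, `comp`, `distance_um`),
#'   `unmatched_gt`, `unmatched_comp` (integer index vectors), `n_gt`,
#'   `n_comp`.
#' @export
match_pairwise <- function(gt, comp, threshold) {
  if (inherits(gt, "cone_points") && inherits(comp, "cone_points") &&
      !.same_roi(gt, comp))
    stop("'gt' and 'comp' must belong to the same ROI", call. = FALSE)
  thr <- .threshold_value(threshold)
  G <- .as_coords(gt)
  C <- .as_coords(comp)
  ng <- nrow(G)
  nc <- nrow(C)
  pairs <- data.frame(gt = integer(0), comp = integer(0),
                      distance_um = numeric(0))
  if (ng > 0L && nc > 0L) {
    D <- sqrt(outer(G[, 1L], C[, 1L], "-")^2 + outer(G[, 2L], C[, 2L], "-")^2)
    cand <- which(D <= thr, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      dd <- D[cand]
      ord <- order(dd, cand[, 1L], cand[, 2L])
      cand <- cand[ord, , drop = FALSE]
      dd <- dd[ord]
      gt_free <- rep(TRUE, ng)
      comp_free <- rep(TRUE, nc)
      keep <- logical(length(dd))
      for (k in seq_along(dd)) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (gt_free[i] && comp_free[j]) {
          keep[k] <- TRUE
          gt_free[i] <- FALSE
          comp_free[j] <- FALSE
        }
      }
      pairs <- data.frame(gt = cand[keep, 1L], comp = cand[keep, 2L],
                          distance_um = dd[keep])
    }
  }
  structure(list(
    threshold = if (inherits(threshold, "threshold_stats")) threshold
                else structure(list(mean_nn_um = NA_real_, sd_nn_um = NA_real_,
                                    threshold_um = thr, n = NA_integer_),
                               class = "threshold_stats"),
    matched_pairs = pairs,
    unmatched_gt = setdiff(seq_len(ng), pairs$gt),
    unmatched_comp = setdiff(seq_len(nc), pairs$comp),
    n_gt = ng, n_comp = nc),
    class = "pair_match")
}

#' @export
print.pair_match <- function(x, ...) {
  cat(sprintf("<pair_match> %d pairs (threshold %.4f um), %d unmatched gt, %d unmatched comp\n",
              nrow(x$matched_pairs), x$threshold$threshold_um,
              length(x$unmatched_gt), length(x$unmatched_comp)))
  invisible(x)
}

#' Cluster cone selections from several annotators
#'
#' Pools the selections of all annotators into a master list, derives the
#' adaptive threshold from it with [match_threshold()], and groups selections
#' that lie within the threshold of each other by greedy agglomeration over
#' cross-annotator point pairs in ascending distance order. A merge is only
#' accepted when the resulting group still contains at most one selection per
#' annotator; every selection ends up in exactly one cluster (singletons
#' allowed).
#'
#' @param sets A list of [cone_points()] objects with distinct annotator
#'   labels, all for the same ROI; at least two. Empty sets are allowed and
#'   contribute no points.
#' @param threshold Optional: override the pooled-master-list threshold with
#'   a [match_threshold()] result or a single non-negative distance.
#' @return An object of class `cluster_set`: list with `graders` (annotator
#'   labels in input order), `clusters` (a list; each cluster is a named
#'   integer vector mapping annotator label to point index within that
#'   annotator's set) and `threshold`.
#' @export
cluster_multigrader <- function(sets, threshold = NULL) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("need at least 2 annotator sets", call. = FALSE)
  if (!all(vapply(sets, inherits, TRUE, "cone_points")))
    stop("every element of 'sets' must be a cone_points object", call. = FALSE)
  labels <- vapply(sets, function(s) s$annotator, "")
  if (anyDuplicated(labels))
    stop("annotator labels must be distinct", call. = FALSE)
  for (s in sets[-1L]) if (!.same_roi(sets[[1L]], s))
    stop("all annotator sets must belong to the same ROI", call. = FALSE)

  counts <- vapply(sets, n_cones, 0L)
  coords <- do.call(rbind, lapply(sets, .as_coords))
  owner <- rep.int(seq_along(sets), counts)
  within <- unlist(lapply(counts, seq_len), use.names = FALSE)
  n <- nrow(coords)

  if (is.null(threshold)) {
    if (n >= 2L) {
      threshold <- match_threshold(coords)
    } else {
      threshold <- structure(list(mean_nn_um = 0, sd_nn_um = 0,
                                  threshold_um = 0, n = n),
                             class = "threshold_stats")
    }
  } else if (!inherits(threshold, "threshold_stats")) {
    threshold <- structure(list(mean_nn_um = NA_real_, sd_nn_um = NA_real_,
                                threshold_um = .threshold_value(threshold),
                                n = n),
                           class = "threshold_stats")
  }
  thr <- threshold$threshold_um

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  members <- lapply(seq_len(n), function(i) i)  # indexed by root

  if (n >= 2L) {
    D <- as.matrix(dist(coords))
    cand <- which(upper.tri(D) & D <= thr & outer(owner, owner, "!="),
                  arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      dd <- D[cand]
      ord <- order(dd, cand[, 1L], cand[, 2L])
      cand <- cand[ord, , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        ri <- find(cand[k, 1L])
        rj <- find(cand[k, 2L])
        if (ri == rj) next
        if (any(owner[members[[ri]]] %in% owner[members[[rj]]])) next
        parent[rj] <- ri
        members[[ri]] <- c(members[[ri]], members[[rj]])
        members[[rj]] <- integer(0)
      }
    }
  }

  roots <- vapply(seq_len(n), find, 0L)
  cluster_ids <- if (n > 0L) split(seq_len(n), roots) else list()
  # deterministic cluster order: by smallest pooled index
  if (length(cluster_ids) > 0L)
    cluster_ids <- cluster_ids[order(vapply(cluster_ids, min, 0L))]
  clusters <- lapply(cluster_ids, function(idx) {
    idx <- idx[order(owner[idx])]
    setNames(within[idx], labels[owner[idx]])
  })
  names(clusters) <- NULL
  structure(list(graders = labels, clusters = clusters, threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<cluster_set> %d graders (%s), %d clusters (threshold %.4f um)\n",
              length(x$graders), paste(x$graders, collapse = ", "),
              length(x$clusters), x$threshold$threshold_um))
  if (length(sizes)) {
    tab <- table(sizes)
    cat("  cluster sizes:",
        paste(sprintf("%s grader(s): %d", names(tab), as.integer(tab)),
              collapse = "; "), "\n")
  }
  invisible(x)
}

.confusion_counts <- function(n_tp, n_fp, n_fn) {
  structure(list(n_tp = as.integer(n_tp), n_fp = as.integer(n_fp),
                 n_fn = as.integer(n_fn),
                 n_gt = as.integer(n_tp + n_fn),
                 n_comp = as.integer(n_tp + n_fp)),
            class = "confusion_counts")
}

#' Confusion counts from a pairwise match
#'
#' True positives are matched pairs; false negatives are ground-truth cones
#' left unmatched; false positives are comparison marks left unmatched. The
#' count identities `n_comp = n_tp + n_fp` and `n_gt = n_tp + n_fn` hold by
#' construction.
#'
#' @param match A [match_pairwise()] result.
#' @return An object of class `confusion_counts` with elements `n_tp`,
#'   `n_fp`, `n_fn`, `n_gt`, `n_comp`.
#' @export
confusion_from_match <- function(match) {
  stopifnot(inherits(match, "pair_match"))
  .confusion_counts(nrow(match$matched_pairs),
                    length(match$unmatched_comp),
                    length(match$unmatched_gt))
}

#' Confusion counts for an annotator pair from a multi-grader clustering
#'
#' With one annotator designated ground truth and another the comparison,
#' each cluster is scored by which of the two it contains: both (true
#' positive), ground truth only (false negative), comparison only (false
#' positive). Clusters containing neither are ignored.
#'
#' @param clusters A [cluster_multigrader()] result.
#' @param ground_truth,comparison Annotator labels present in
#'   `clusters$graders`.
#' @return A `confusion_counts` object.
#' @export
confusion_from_clusters <- function(clusters, ground_truth, comparison) {
  stopifnot(inherits(clusters, "cluster_set"))
  for (lab in c(ground_truth, comparison))
    if (!lab %in% clusters$graders)
      stop(sprintf("unknown annotator label '%s'", lab), call. = FALSE)
  if (identical(ground_truth, comparison))
    stop("ground truth and comparison annotators must differ", call. = FALSE)
  has_gt <- vapply(clusters$clusters, function(cl) ground_truth %in% names(cl), TRUE)
  has_cp <- vapply(clusters$clusters, function(cl) comparison %in% names(cl), TRUE)
  .confusion_counts(sum(has_gt & has_cp), sum(!has_gt & has_cp),
                    sum(has_gt & !has_cp))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, FN %d (n_gt %d, n_comp %d)\n",
              x$n_tp, x$n_fp, x$n_fn, x$n_gt, x$n_comp))
  invisible(x)
}

#' Export matched pairs as a data frame
#'
#' One row per matched pair with annotator labels, indices, coordinates and
#' pair distance, suitable for writing with [write.table()].
#'
#' @param match A [match_pairwise()] result.
#' @param gt,comp The [cone_points()] sets that were matched.
#' @return A data frame.
#' @export
match_table <- function(match, gt, comp) {
  stopifnot(inherits(match, "pair_match"),
            inherits(gt, "cone_points"), inherits(comp, "cone_points"))
  mp <- match$matched_pairs
  data.frame(
    gt_annotator = gt$annotator, comp_annotator = comp$annotator,
    gt_index = mp$gt, comp_index = mp$comp,
    gt_x = gt$coords[mp$gt, 1L], gt_y = gt$coords[mp$gt, 2L],
    comp_x = comp$coords[mp$comp, 1L], comp_y = comp$coords[mp$comp, 2L],
    distance_um = mp$distance_um)
}
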