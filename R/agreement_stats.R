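# Agreement statistics.
#
# Rates follow the standard detection-agreement definitions: the true
# positive rate is the fraction of ground-truth cones recovered, the false
# positive rate the fraction of comparison marks with no ground-truth
# partner, and Dice's coefficient 2*TP / (n_gt + n_comp). Density agreement
# uses Bland-Altman limits of agreement (log10-transformed when the raw
# differences fail normality), a two-way random-effects absolute-agreement
# single-measure ICC, and a repeated-measures one-way ANOVA with
# Bonferroni-corrected post hoc paired t-tests.

#' Agreement rates from confusion counts
#'
#' @param counts A [confusion_from_match()] / [confusion_from_clusters()]
#'   result, or any list with elements `n_tp`, `n_fp`, `n_fn`.
#' @return An object of class `agreement_rates`: list with `tpr`
#'   (`n_tp / n_gt`), `fpr` (`n_fp / n_comp`) and `dice`
#'   (`2 n_tp / (n_gt + n_comp)`).
#' @examples
#' agreement_rates(list(n_tp = 8, n_fp = 3, n_fn = 2))
#' @export
agreement_rates <- function(counts) {
  n_tp <- counts$n_tp; n_fp <- counts$n_fp; n_fn <- counts$n_fn
  stopifnot(is.numeric(n_tp), is.numeric(n_fp), is.numeric(n_fn),
            n_tp >= 0, n_fp >= 0, n_fn >= 0)
  n_gt <- n_tp + n_fn
  n_comp <- n_tp + n_fp
  if (n_gt == 0 || n_comp == 0)
    stop("agreement rates are undefined when either set is empty", call. = FALSE)
  structure(list(tpr = n_tp / n_gt, fpr = n_fp / n_comp,
                 dice = 2 * n_tp / (n_gt + n_comp)),
            class = "agreement_rates")
}

#' @export
print.agreement_rates <- function(x, ...) {
  cat(sprintf("<agreement_rates> TPR %.4f, FPR %.4f, Dice %.4f\n",
              x$tpr, x$fpr, x$dice))
  invisible(x)
}

#' Ground-truth rotation table for one ROI
#'
#' Clusters all annotators' selections with [cluster_multigrader()] and
#' computes confusion counts and agreement rates for every ordered
#' (ground truth, comparison) annotator pair — i.e. each annotator takes a
#' turn as ground truth, mirroring how multi-grader reliability is reported.
#'
#' @param sets A list of >= 2 [cone_points()] objects for the same ROI with
#'   distinct annotator labels.
#' @param threshold Optional threshold override passed to
#'   [cluster_multigrader()].
#' @return A data frame with `k (k - 1)` rows and columns `ground_truth`,
#'   `comparison`, `n_tp`, `n_fp`, `n_fn`, `tpr`, `fpr`, `dice`.
#' @export
rotate_ground_truth <- function(sets, threshold = NULL) {
  cs <- cluster_multigrader(sets, threshold = threshold)
  labs <- cs$graders
  rows <- list()
  for (g in labs) for (c in setdiff(labs, g)) {
    cc <- confusion_from_clusters(cs, g, c)
    r <- agreement_rates(cc)
    rows[[length(rows) + 1L]] <-
      data.frame(ground_truth = g, comparison = c, n_tp = cc$n_tp,
                 n_fp = cc$n_fp, n_fn = cc$n_fn,
                 tpr = r$tpr, fpr = r$fpr, dice = r$dice)
  }
  do.call(rbind, rows)
}

#' Bland-Altman analysis of paired densities
#'
#' Tests the raw paired differences for normality (Shapiro-Wilk at `alpha`);
#' when normality is rejected both series are log10-transformed before the
#' bias and limits of agreement are computed. Limits of agreement are
#' `bias +/- 1.96 SD` of the differences on the analysis scale. For more
#' than 5000 pairs the normality test uses a deterministic evenly spaced
#' subsample of 5000 differences (the test itself is defined for n <= 5000).
#'
#' @param values_a,values_b Numeric vectors of equal length >= 3 (e.g.
#'   per-ROI bound densities from two gradings). Differences are
#'   `values_b - values_a`.
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return An object of class `bland_altman`: list with `transform`
#'   (`"identity"` or `"log10"`), `normality_p`, `bias`, `loa_low`,
#'   `loa_high`, `sd_diff` and `n`.
#' @export
bland_altman <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) != length(values_b))
    stop("'values_a' and 'values_b' must have the same length", call. = FALSE)
  n <- length(values_a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  diffs <- values_b - values_a
  normality_p <- NA_real_
  transform <- "identity"
  if (sd(diffs) > 0) {
    test_d <- diffs
    if (n > 5000L)
      test_d <- diffs[unique(round(seq(1L, n, length.out = 5000L)))]
    normality_p <- shapiro.test(test_d)$p.value
    if (normality_p < alpha) {
      if (any(values_a <= 0) || any(values_b <= 0))
        stop("log10 transform requires strictly positive values", call. = FALSE)
      transform <- "log10"
      diffs <- log10(values_b) - log10(values_a)
    }
  }
  bias <- mean(diffs)
  s <- sd(diffs)
  structure(list(transform = transform, normality_p = normality_p,
                 bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s, n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n %d, scale %s, bias %.4g, LoA [%.4g, %.4g]\n",
              x$n, x$transform, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

# Two-way mean squares of a complete targets x raters matrix, via aov().
.two_way_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   target = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # perfect-fit warnings are expected for degenerate matrices; the callers
  # detect and handle that case themselves
  tab <- suppressWarnings(anova(aov(y ~ target + rater, data = df)))
  list(msr = tab["target", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"], n = n, k = k)
}

.CICCHETTI <- c(poor = 0.40, fair = 0.60, good = 0.75)

.icc_band <- function(icc) {
  if (icc < .CICCHETTI["poor"]) "poor"
  else if (icc < .CICCHETTI["fair"]) "fair"
  else if (icc < .CICCHETTI["good"]) "good"
  else "excellent"
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC for a
#' complete targets-by-raters matrix (each ROI's density measured by every
#' annotator), with the F-based confidence interval of McGraw & Wong. The
#' qualitative band follows Cicchetti's scale: < 0.40 poor, 0.40-0.59 fair,
#' 0.60-0.74 good, >= 0.75 excellent.
#'
#' @param density_matrix Numeric matrix, rows = targets (ROIs), columns =
#'   raters (annotators); >= 3 rows, >= 2 columns, no missing values.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `n_targets`, `n_raters` and `qualitative_band`.
#' @export
icc <- function(density_matrix, conf_level = 0.95) {
  mat <- as.matrix(density_matrix)
  if (nrow(mat) < 3L || ncol(mat) < 2L)
    stop("need at least 3 targets and 2 raters", call. = FALSE)
  if (any(!is.finite(mat)))
    stop("the rating matrix must be complete (no missing values)", call. = FALSE)
  ms <- .two_way_ms(mat)
  n <- ms$n; k <- ms$k
  denom <- ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n
  val <- if (denom <= 0) 0 else (ms$msr - ms$mse) / denom
  alpha <- 1 - conf_level
  if (1 - val < 1e-12 || ms$mse <= 0) {
    ci <- c(val, val)  # degenerate: no residual variance
  } else {
    a <- k * val / (n * (1 - val))
    b <- 1 + k * val * (n - 1) / (n * (1 - val))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - f_l * ms$mse) /
      (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (f_u * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
    ci <- c(max(-1, lower), min(1, upper))
  }
  structure(list(icc = val, ci_low = ci[1L], ci_high = ci[2L],
                 n_targets = n, n_raters = k,
                 qualitative_band = .icc_band(val)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f, CI [%.3f, %.3f], %s (%d targets, %d raters)\n",
              x$icc, x$ci_low, x$ci_high, x$qualitative_band,
              x$n_targets, x$n_raters))
  invisible(x)
}

#' Repeated-measures one-way ANOVA with Bonferroni post hoc tests
#'
#' Within-subject one-way ANOVA over a complete subjects-by-conditions
#' matrix (e.g. per-ROI densities under each annotator), followed by paired
#' t-tests for every condition pair with Bonferroni adjustment
#' (`p_adj = min(1, m * p_raw)`, m = number of pairs performed).
#'
#' @param matrix Numeric matrix, rows = subjects (ROIs), columns =
#'   conditions; >= 3 rows, >= 2 columns, complete.
#' @param alpha Significance level reported alongside (default 0.05).
#' @return An object of class `rm_anova`: list with `f`, `df1`, `df2`,
#'   `p` (omnibus), `degenerate` (logical; `TRUE` when there is no variance
#'   anywhere, in which case `p = 1`), `pairs` (data frame with
#'   `cond_a`, `cond_b`, `mean_diff`, `p_raw`, `p_bonferroni`),
#'   `m` (number of pairwise comparisons) and `alpha`.
#' @export
repeated_measures_anova <- function(matrix, alpha = 0.05) {
  mat <- as.matrix(matrix)
  if (nrow(mat) < 3L || ncol(mat) < 2L)
    stop("need at least 3 subjects and 2 conditions", call. = FALSE)
  if (any(!is.finite(mat)))
    stop("the matrix must be complete (no missing values)", call. = FALSE)
  conds <- colnames(mat)
  if (is.null(conds)) conds <- paste0("cond", seq_len(ncol(mat)))
  ms <- .two_way_ms(mat)
  eps <- 1e-12 * (mean(mat^2) + 1)  # guard against pure rounding noise
  degenerate <- ms$msc <= eps && ms$mse <= eps
  if (degenerate) {
    f <- 0; p <- 1
  } else if (ms$mse <= eps) {
    f <- Inf; p <- 0
  } else {
    f <- ms$msc / ms$mse
    p <- pf(f, ms$k - 1, (ms$n - 1) * (ms$k - 1), lower.tail = FALSE)
  }
  cmb <- utils::combn(ms$k, 2L)
  m <- ncol(cmb)
  pairs <- do.call(rbind, lapply(seq_len(m), function(idx) {
    i <- cmb[1L, idx]; j <- cmb[2L, idx]
    d <- mat[, j] - mat[, i]
    p_raw <- if (sd(d) <= 0) {
      if (mean(d) == 0) 1 else 0
    } else t.test(mat[, j], mat[, i], paired = TRUE)$p.value
    data.frame(cond_a = conds[i], cond_b = conds[j], mean_diff = mean(d),
               p_raw = p_raw, p_bonferroni = min(1, m * p_raw))
  }))
  structure(list(f = f, df1 = ms$k - 1, df2 = (ms$n - 1) * (ms$k - 1),
                 p = p, degenerate = degenerate, pairs = pairs, m = m,
                 alpha = alpha),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.3f, p = %.4g%s\n", x$df1, x$df2, x$f,
              x$p, if (x$degenerate) " [degenerate variance]" else ""))
  sig <- x$pairs$p_bonferroni < x$alpha
  cat(sprintf("  %d pairwise comparisons, %d significant at alpha = %g (Bonferroni)\n",
              x$m, sum(sig), x$alpha))
  invisible(x)
}

#' Coefficient of variation of per-annotator densities
#'
#' Sample SD divided by the mean; typically applied to one ROI's bound cone
#' density as measured by each annotator.
#'
#' @param densities Numeric vector of length >= 2 with positive mean.
#' @return The coefficient of variation (a fraction).
#' @examples
#' density_cov(c(90, 100, 110))
#' @export
density_cov <- function(densities) {
  stopifnot(is.numeric(densities))
  if (length(densities) < 2L)
    stop("need at least 2 values", call. = FALSE)
  m <- mean(densities)
  if (!is.finite(m) || m <= 0)
    stop("mean density must be positive", call. = FALSE)
  sd(densities) / m
}

#' Summarise agreement rates across ROIs
#'
#' Collapses a stack of per-ROI [rotate_ground_truth()] tables into the
#' mean and SD of TPR, FPR and Dice for every ordered annotator pair (the
#' usual multi-grader agreement report layout).
#'
#' @param rate_tables A data frame combining per-ROI rotation tables (rows
#'   bound together), with columns `ground_truth`, `comparison`, `tpr`,
#'   `fpr`, `dice`.
#' @return A data frame with one row per ordered pair and columns
#'   `ground_truth`, `comparison`, `n_roi`, `tpr_mean`, `tpr_sd`,
#'   `fpr_mean`, `fpr_sd`, `dice_mean`, `dice_sd`.
#' @export
agreement_summary <- function(rate_tables) {
  stopifnot(all(c("ground_truth", "comparison", "tpr", "fpr", "dice")
                %in% names(rate_tables)))
  key <- interaction(rate_tables$ground_truth, rate_tables$comparison,
                     drop = TRUE, lex.order = TRUE)
  out <- lapply(split(rate_tables, key), function(d)
    data.frame(ground_truth = d$ground_truth[1L],
               comparison = d$comparison[1L], n_roi = nrow(d),
               tpr_mean = mean(d$tpr), tpr_sd = sd(d$tpr),
               fpr_mean = mean(d$fpr), fpr_sd = sd(d$fpr),
               dice_mean = mean(d$dice), dice_sd = sd(d$dice)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise per-annotator densities across ROIs
#'
#' @param densities A [density_table()]-style data frame with columns
#'   `annotator` and `density_cones_per_mm2`.
#' @return A data frame with columns `annotator`, `n_roi`, `density_mean`,
#'   `density_sd`.
#' @export
density_summary <- function(densities) {
  stopifnot(all(c("annotator", "density_cones_per_mm2") %in% names(densities)))
  out <- lapply(split(densities, densities$annotator), function(d)
    data.frame(annotator = d$annotator[1L], n_roi = nrow(d),
               density_mean = mean(d$density_cones_per_mm2),
               density_sd = sd(d$density_cones_per_mm2)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
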