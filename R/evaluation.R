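# Per-subject evaluation: ROC and precision-recall curves built by a single
# sorted threshold sweep (anomaly = positive class; an observation is called
# positive when its similarity score is at or below the threshold), AUC by
# the trapezoidal rule, vertical curve averaging across subjects, five-fold
# cross-validated experiments, and the paired nonparametric comparisons.

.check_scored <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c("typical", "atypical"))) {
    stop("labels must be 'typical' or 'atypical'")
  }
  P <- sum(labels == "atypical")
  N <- sum(labels == "typical")
  if (P == 0L || N == 0L) {
    stop("curve construction needs both classes present (got ",
         P, " atypical, ", N, " typical)")
  }
  c(P = P, N = N)
}

# Cumulative true/false positive counts after each distinct score threshold,
# sweeping scores in ascending order (most anomalous first) and collapsing
# ties to a single operating point.
.sweep_counts <- function(scores, labels) {
  ord <- order(scores)
  s <- scores[ord]
  pos <- labels[ord] == "atypical"
  # index of the last element of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  list(tp = cumsum(pos)[last], fp = cumsum(!pos)[last],
       threshold = s[last])
}

#' ROC curve of a scored test set
#'
#' Anomalies (`"atypical"`) are the positive class; a query is called positive
#' when its similarity score is less than or equal to the threshold, since low
#' scores flag risk. The curve is generated in one sorted pass over all
#' distinct score thresholds, with tied scores collapsed to a single point; it
#' starts at (0,0) and ends at (1,1).
#'
#' @param scores Numeric similarity scores.
#' @param labels Character vector of `"typical"` / `"atypical"`.
#' @return Object of class `"roc_curve"`: a data frame with columns `fpr` and
#'   `tpr` and an `"auc"` attribute (trapezoidal area, in `[0, 1]`).
#' @export
roc_points <- function(scores, labels) {
  pn <- .check_scored(scores, labels)
  cnt <- .sweep_counts(scores, labels)
  fpr <- c(0, cnt$fp / pn["N"])
  tpr <- c(0, cnt$tp / pn["P"])
  curve <- data.frame(fpr = unname(fpr), tpr = unname(tpr))
  a <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(curve, class = c("roc_curve", "data.frame"), auc = a)
}

#' Area under a ROC curve
#'
#' Trapezoidal area of the (FPR, TPR) polyline, in `[0, 1]`. Equals the
#' normalized Mann-Whitney statistic of the underlying scores.
#'
#' @param curve A `"roc_curve"` object from [roc_points()].
#' @return Scalar in `[0, 1]`.
#' @export
auc <- function(curve) {
  if (!is.null(attr(curve, "auc"))) return(attr(curve, "auc"))
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

#' Precision-recall curve of a scored test set
#'
#' Same threshold sweep and positive-class convention as [roc_points()]:
#' one operating point per distinct score, recall = TP/P non-decreasing along
#' the curve, final point at recall 1 with precision equal to the anomaly
#' prevalence.
#'
#' @inheritParams roc_points
#' @return Object of class `"pr_curve"`: data frame with columns `recall` and
#'   `precision`.
#' @export
pr_points <- function(scores, labels) {
  pn <- .check_scored(scores, labels)
  cnt <- .sweep_counts(scores, labels)
  curve <- data.frame(recall = unname(cnt$tp / pn["P"]),
                      precision = unname(cnt$tp / (cnt$tp + cnt$fp)))
  structure(curve, class = c("pr_curve", "data.frame"))
}

#' Vertical averaging of per-subject curves
#'
#' Interpolates each curve's vertical coordinate (TPR or precision) on a fixed
#' horizontal grid (FPR or recall) of `grid_n` points in `[0, 1]` and returns
#' the per-grid-point mean and sample standard deviation across curves, the
#' population summary used to report one mean curve with deviation bands.
#'
#' @param curves List of `"roc_curve"` or `"pr_curve"` objects (all the same
#'   type).
#' @param grid_n Number of grid points (default 101).
#' @return Data frame with columns `x`, `mean`, `sd`.
#' @export
average_curves <- function(curves, grid_n = 101) {
  stopifnot(length(curves) >= 1L)
  is_roc <- inherits(curves[[1]], "roc_curve")
  grid <- seq(0, 1, length.out = grid_n)
  ys <- vapply(curves, function(cv) {
    x <- if (is_roc) cv$fpr else cv$recall
    y <- if (is_roc) cv$tpr else cv$precision
    approx(x, y, xout = grid, rule = 2, ties = max)$y
  }, numeric(grid_n))
  ys <- matrix(ys, nrow = grid_n)
  data.frame(x = grid,
             mean = rowMeans(ys),
             sd = apply(ys, 1L, function(v) if (length(v) > 1L) sd(v) else 0))
}

#' Paired Wilcoxon signed-rank comparison of two per-subject AUC columns
#'
#' Two-sided paired signed-rank test (exact distribution when 25 or fewer
#' nonzero differences and no tied magnitudes, normal approximation
#' otherwise); zero differences are dropped. Identical vectors give p = 1 by
#' convention.
#'
#' @param a,b Paired numeric vectors (e.g. per-subject AUCs of two methods).
#' @return List with `statistic`, `p.value`, `n` (nonzero pairs), `wins_a`
#'   and `wins_b` (counts of subjects where each method is strictly better).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  wins_a <- sum(d > 0)
  wins_b <- sum(d < 0)
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                wins_a = wins_a, wins_b = wins_b))
  }
  exact <- n <= 25L && !anyDuplicated(abs(dn))
  ht <- suppressWarnings(
    wilcox.test(dn, alternative = "two.sided", mu = 0,
                exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p.value = ht$p.value, n = n,
       wins_a = wins_a, wins_b = wins_b)
}

#' Kruskal-Wallis rank test across groups (e.g. across subjects)
#'
#' Wrapper around [stats::kruskal.test()] used to check whether subjects'
#' score or feature distributions are drawn from the same population.
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `statistic` (H), `df` and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  ht <- kruskal.test(groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Per-subject five-fold cross-validated comparison of one-class classifiers
#'
#' For every subject and method, the normal rows are split into five
#' contiguous temporal folds ([split_folds()]); each round trains on four
#' folds and scores the held-out fold joined with the full anomaly set. Scores
#' are pooled across the five rounds before one ROC and one P-R curve per
#' subject and method are built, and AUC is reported in percent.
#'
#' @param subjects Named list; each element a list with data frames `normal`
#'   and `anomalous` (feature columns, optional `t` column; labels ignored).
#' @param methods Character vector of method names accepted by [oc_train()].
#' @param n_members,k OCKRA / centroid-baseline parameters.
#' @param seed Master seed; all per-fold training seeds derive from it.
#' @param n_folds Number of folds (default 5).
#' @return List with `auc_table` (data frame: `subject` column plus one AUC-%
#'   column per method and a final `"Average"` row), `roc` and `pr` (lists of
#'   per-method, per-subject curves) and `scores` (pooled scored test sets).
#' @export
run_experiment <- function(subjects,
                           methods = c("ockra", "parzen", "kmeans1", "kmeans2"),
                           n_members = 100, k = 10, seed = 1, n_folds = 5) {
  stopifnot(length(subjects) >= 1L)
  if (is.null(names(subjects))) {
    names(subjects) <- paste0("TS", seq_along(subjects))
  }
  set.seed(seed)
  seed_tab <- array(sample.int(.Machine$integer.max,
                               length(subjects) * length(methods) * n_folds),
                    dim = c(length(subjects), length(methods), n_folds))

  auc_mat <- matrix(NA_real_, length(subjects), length(methods),
                    dimnames = list(names(subjects), methods))
  roc_list <- pr_list <- lapply(methods, function(m) list())
  names(roc_list) <- names(pr_list) <- methods
  score_sets <- list()

  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    normal <- sub$normal
    anomalous <- sub$anomalous
    npar <- .as_features(normal)
    apar <- .as_features(anomalous)
    folds <- split_folds(nrow(npar$X), nrow(apar$X), n_folds)
    for (mi in seq_along(methods)) {
      scores <- numeric(0)
      labels <- character(0)
      for (fi in seq_len(n_folds)) {
        fold <- folds[[fi]]
        fit <- oc_train(npar$X[fold$train, , drop = FALSE],
                        method = methods[mi], n_members = n_members, k = k,
                        seed = seed_tab[si, mi, fi],
                        timestamps = npar$timestamps[fold$train])
        test_x <- rbind(npar$X[fold$test, , drop = FALSE], apar$X)
        scores <- c(scores, predict(fit, test_x))
        labels <- c(labels, rep("typical", length(fold$test)),
                    rep("atypical", nrow(apar$X)))
      }
      rc <- roc_points(scores, labels)
      auc_mat[si, mi] <- 100 * auc(rc)
      roc_list[[mi]][[names(subjects)[si]]] <- rc
      pr_list[[mi]][[names(subjects)[si]]] <- pr_points(scores, labels)
      score_sets[[paste(names(subjects)[si], methods[mi], sep = ".")]] <-
        list(scores = scores, labels = labels,
             subject = names(subjects)[si], method = methods[mi])
    }
  }

  auc_table <- data.frame(subject = c(rownames(auc_mat), "Average"),
                          rbind(auc_mat, colMeans(auc_mat)),
                          check.names = FALSE, row.names = NULL)
  list(auc_table = auc_table, roc = roc_list, pr = pr_list,
       scores = score_sets)
}
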