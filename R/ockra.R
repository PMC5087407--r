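# OCKRA: an ensemble of one-class classifiers. Each member draws a random
# feature subset (n draws with replacement, deduplicated), projects the
# training data onto it, clusters the projection with k-means++ (k = 10 by
# default), and keeps a distance threshold delta equal to the mean pairwise
# Euclidean distance among training points subsampled at 60-second spacing.
# A query is scored per member by a Gaussian kernel of the distance to the
# nearest centroid, exp(-0.5 * (dmin/delta)^2), and the ensemble score is
# the member average: near 1 = normal behavior, near 0 = risk-prone.

#' Draw a random feature subset for one ensemble member
#'
#' Draws `n` feature indices uniformly with replacement from `1..n` and
#' removes duplicates, retaining about 63% of the features on average
#' (exactly `n * (1 - ((n-1)/n)^n)` in expectation). Uses the current R RNG
#' stream.
#'
#' @param n Number of available features (>= 1).
#' @return Sorted integer vector of distinct selected feature indices.
#' @export
select_random_features <- function(n) {
  if (n < 1L) stop("n must be >= 1")
  sort(unique(sample.int(n, n, replace = TRUE)))
}

#' Project a dataset onto a feature subset
#'
#' @param x Numeric matrix.
#' @param features Integer vector of column indices within `1..ncol(x)`.
#' @return The column subset of `x`, columns in ascending index order.
#' @export
project_features <- function(x, features) {
  x <- as.matrix(x)
  features <- as.integer(features)
  if (any(features < 1L | features > ncol(x))) {
    stop("feature index out of range 1..", ncol(x))
  }
  x[, sort(unique(features)), drop = FALSE]
}

# Indices of the 60-second subsample: the first row, then greedily every row
# at least `spacing` seconds after the previously kept one. Without
# timestamps, every `spacing`-th row.
.subsample_idx <- function(m, timestamps = NULL, spacing = 60) {
  if (is.null(timestamps)) return(seq(1L, m, by = spacing))
  keep <- 1L
  last <- timestamps[1L]
  for (i in seq_len(m)[-1L]) {
    if (timestamps[i] - last >= spacing) {
      keep <- c(keep, i)
      last <- timestamps[i]
    }
  }
  keep
}

#' Distance threshold: mean pairwise distance of the 60-second subsample
#'
#' Subsamples the training rows so that kept rows are at least `spacing`
#' seconds apart (or every `spacing`-th row when no timestamps are given),
#' reducing m rows to about m/`spacing`, then returns the mean Euclidean
#' distance over all unordered pairs of kept rows. If fewer than two rows
#' survive the subsampling, all rows are used. A degenerate threshold of 0
#' (constant data) is replaced by a floor of 1e-12.
#'
#' @param x Numeric matrix (typically a member's projected training data).
#' @param timestamps Optional numeric vector of row times in seconds.
#' @param spacing Subsampling spacing in seconds/rows (default 60).
#' @return Positive scalar threshold.
#' @export
distance_threshold <- function(x, timestamps = NULL, spacing = 60) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to compute a distance threshold")
  idx <- .subsample_idx(nrow(x), timestamps, spacing)
  if (length(idx) < 2L) idx <- seq_len(nrow(x))
  delta <- mean(dist(x[idx, , drop = FALSE]))
  if (delta <= 0) delta <- 1e-12
  delta
}

#' Gaussian similarity of a nearest-centroid distance
#'
#' `exp(-0.5 * (dmin/delta)^2)`: 1 at zero distance, above `exp(-0.5) = 0.607`
#' for any distance below the threshold, and below `exp(-4.5) = 0.011` beyond
#' three thresholds.
#'
#' @param dmin Non-negative distance(s) to the nearest centroid.
#' @param delta Positive distance threshold.
#' @return Similarity value(s) in (0, 1].
#' @export
member_similarity <- function(dmin, delta) {
  if (any(delta <= 0)) stop("delta must be > 0")
  if (any(dmin < 0)) stop("dmin must be >= 0")
  exp(-0.5 * (dmin / delta)^2)
}

#' Train an OCKRA one-class ensemble
#'
#' Fits `n_members` independent members. Member i draws a random feature
#' subset ([select_random_features()]), projects the training data onto it,
#' computes its distance threshold ([distance_threshold()]) on the projection,
#' and clusters the projection with k-means++ ([kmeanspp()], `k` clusters).
#' Any `label` column is stripped before training: the ensemble never sees
#' labels. Each member uses a child RNG seed derived from `seed`, so training
#' is reproducible end to end.
#'
#' @param x Training data: numeric matrix or data frame of feature columns
#'   (columns named `t`, `timestamp`, `label`, `subject` are treated as
#'   metadata and dropped; a `t`/`timestamp` column supplies `timestamps`).
#' @param n_members Ensemble size (default 100).
#' @param k Clusters per member (default 10).
#' @param seed Master RNG seed (default 1).
#' @param timestamps Optional row times in seconds for the 60-second
#'   threshold subsampling; taken from `x` when it has a `t` column.
#' @return Object of class `"ockra"`: a list with `members` (each a list of
#'   `features`, `delta`, `centroids`), `k`, `n_members`, `seed`, `n` (trained
#'   feature count) and `feature_names`.
#' @seealso [predict.ockra()], [write_model_json()]
#' @examples
#' x <- matrix(rnorm(200 * 5), 200)
#' fit <- ockra(x, n_members = 10, k = 3, seed = 42)
#' summary(predict(fit, x))
#' @export
ockra <- function(x, n_members = 100, k = 10, seed = 1, timestamps = NULL) {
  parts <- .as_features(x)
  X <- parts$X
  if (is.null(timestamps)) timestamps <- parts$timestamps
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  n <- ncol(X)
  n_members <- as.integer(n_members)
  k <- as.integer(k)

  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max, n_members)
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    set.seed(member_seeds[i])
    feats <- select_random_features(n)
    Xp <- X[, feats, drop = FALSE]
    delta <- distance_threshold(Xp, timestamps)
    centroids <- kmeanspp(Xp, k)
    members[[i]] <- list(features = feats, delta = delta, centroids = centroids)
  }
  structure(list(members = members, k = k, n_members = n_members,
                 seed = seed, n = n, feature_names = colnames(X)),
            class = "ockra")
}

# Ensemble similarity scores for a feature matrix against a member list.
.ensemble_scores <- function(members, X) {
  s <- numeric(nrow(X))
  for (mem in members) {
    d2 <- .sqdist(X[, mem$features, drop = FALSE], mem$centroids)
    dmin <- sqrt(apply(d2, 1L, min))
    s <- s + member_similarity(dmin, mem$delta)
  }
  s / length(members)
}

#' Score new observations with a trained OCKRA ensemble
#'
#' Each member projects the query onto its feature subset, finds the Euclidean
#' distance to its nearest centroid (ties to the lowest centroid index), and
#' converts it to a similarity via [member_similarity()]; the ensemble score
#' is the average over members. Scores lie in `[0, 1]`: values near 0 flag a
#' potentially risky (anomalous) observation, values near 1 normal behavior.
#'
#' @param object Fitted `"ockra"` model.
#' @param newdata Matrix or data frame with the trained feature columns.
#' @param ... Unused.
#' @return Numeric vector of similarity scores, one per row of `newdata`.
#' @export
predict.ockra <- function(object, newdata, ...) {
  X <- .as_features(newdata)$X
  if (ncol(X) != object$n) {
    stop("newdata has ", ncol(X), " features; model was trained on ", object$n)
  }
  .ensemble_scores(object$members, X)
}

#' @export
print.ockra <- function(x, ...) {
  cat("OCKRA one-class ensemble\n")
  cat("  members:", x$n_members, "  clusters per member (k):", x$k, "\n")
  cat("  trained features:", x$n,
      "  stored centroids:", sum(vapply(x$members, function(m) nrow(m$centroids), 0L)),
      "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.ockra <- function(object, ...) {
  nf <- vapply(object$members, function(m) length(m$features), 0L)
  deltas <- vapply(object$members, function(m) m$delta, 0)
  out <- list(n_members = object$n_members, k = object$k, n = object$n,
              centroids = sum(vapply(object$members,
                                     function(m) nrow(m$centroids), 0L)),
              features_per_member = summary(nf), delta = summary(deltas))
  class(out) <- "summary.ockra"
  out
}

#' @export
print.summary.ockra <- function(x, ...) {
  cat("OCKRA ensemble:", x$n_members, "members, k =", x$k, ",",
      x$centroids, "centroids over", x$n, "features\n")
  cat("selected features per member:\n")
  print(x$features_per_member)
  cat("member distance thresholds (delta):\n")
  print(x$delta)
  invisible(x)
}
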