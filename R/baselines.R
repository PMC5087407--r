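# Baseline one-class classifiers: the Parzen window classifier on Euclidean
# distance, two centroid-based variants of it (nearest center only / all
# centers), and an adapter around libsvm's one-class SVM. All distance-based
# baselines share OCKRA's Gaussian kernel and its 60-second width rule so the
# methods differ only in their set of reference points.

#' Parzen window one-class classifier
#'
#' Stores the training rows verbatim and sets the window width to the mean
#' pairwise Euclidean distance among rows subsampled at 60-second spacing
#' (the same rule as OCKRA's member threshold, [distance_threshold()]).
#'
#' @inheritParams ockra
#' @return Object of class `"parzen_oc"` with elements `training_points`,
#'   `width` and `n`.
#' @export
parzen_oc <- function(x, timestamps = NULL) {
  parts <- .as_features(x)
  X <- parts$X
  if (is.null(timestamps)) timestamps <- parts$timestamps
  width <- distance_threshold(X, timestamps)
  structure(list(training_points = X, width = width, n = ncol(X)),
            class = "parzen_oc")
}

#' @rdname parzen_oc
#' @param object Fitted model.
#' @param newdata Matrix or data frame of query rows.
#' @param ... Unused.
#' @return `predict` returns the mean over training points of
#'   `exp(-0.5 * (d/width)^2)`, in `(0, 1]` per query row.
#' @export
predict.parzen_oc <- function(object, newdata, ...) {
  X <- .as_features(newdata)$X
  if (ncol(X) != object$n) stop("feature count mismatch")
  d <- sqrt(.sqdist(X, object$training_points))
  rowMeans(member_similarity(d, object$width))
}

#' Centroid-based one-class classifier (k-means variants of Parzen)
#'
#' Replaces the Parzen reference set by `k` k-means++ cluster centers of the
#' training data, with the same 60-second width rule. `mode = "closest"`
#' scores a query by the kernel of the distance to its nearest center only;
#' `mode = "all"` averages the kernel over all centers.
#'
#' @inheritParams ockra
#' @param mode `"closest"` (nearest center) or `"all"` (all centers).
#' @return Object of class `"kmeans_oc"` with elements `centroids`, `width`,
#'   `mode`, `k` and `n`.
#' @export
kmeans_oc <- function(x, k = 10, mode = c("closest", "all"), seed = 1,
                      timestamps = NULL) {
  mode <- match.arg(mode)
  parts <- .as_features(x)
  X <- parts$X
  if (is.null(timestamps)) timestamps <- parts$timestamps
  width <- distance_threshold(X, timestamps)
  set.seed(seed)
  centroids <- kmeanspp(X, k)
  structure(list(centroids = centroids, width = width, mode = mode,
                 k = nrow(centroids), n = ncol(X)),
            class = "kmeans_oc")
}

#' @rdname kmeans_oc
#' @param object Fitted model.
#' @param newdata Matrix or data frame of query rows.
#' @param ... Unused.
#' @export
predict.kmeans_oc <- function(object, newdata, ...) {
  X <- .as_features(newdata)$X
  if (ncol(X) != object$n) stop("feature count mismatch")
  d <- sqrt(.sqdist(X, object$centroids))
  if (object$mode == "closest") {
    member_similarity(apply(d, 1L, min), object$width)
  } else {
    rowMeans(member_similarity(d, object$width))
  }
}

#' One-class SVM adapter (libsvm via e1071)
#'
#' Thin adapter around `e1071::svm(type = "one-classification")` with the RBF
#' kernel and the study defaults `gamma = 0.038`, `nu = 0.5`, without feature
#' scaling. The fitted support vectors, dual coefficients and offset are
#' extracted so that scoring and JSON round-tripping do not depend on the
#' backend object; scoring evaluates the libsvm decision function
#' `sum_j coef_j * exp(-gamma * ||x - SV_j||^2) - rho` (higher = more normal).
#'
#' @inheritParams ockra
#' @param gamma RBF kernel width parameter.
#' @param nu Upper bound on the training outlier fraction.
#' @return Object of class `"ocsvm_oc"` with elements `sv`, `coefs`, `rho`,
#'   `gamma`, `nu` and `n`.
#' @export
ocsvm_oc <- function(x, gamma = 0.038, nu = 0.5) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("the one-class SVM baseline requires the 'e1071' package; ",
         "install it or choose another method")
  }
  X <- .as_features(x)$X
  fit <- e1071::svm(X, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = gamma, nu = nu, scale = FALSE)
  structure(list(sv = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs),
                 rho = as.numeric(fit$rho),
                 gamma = gamma, nu = nu, n = ncol(X)),
            class = "ocsvm_oc")
}

#' @rdname ocsvm_oc
#' @param object Fitted model.
#' @param newdata Matrix or data frame of query rows.
#' @param ... Unused.
#' @return `predict` returns the decision value per query row (not bounded to
#'   `[0, 1]`; larger means more normal).
#' @export
predict.ocsvm_oc <- function(object, newdata, ...) {
  X <- .as_features(newdata)$X
  if (ncol(X) != object$n) stop("feature count mismatch")
  K <- exp(-object$gamma * .sqdist(X, object$sv))
  as.numeric(K %*% object$coefs) - object$rho
}

#' Train any of the package's one-class classifiers by name
#'
#' Dispatcher used by [run_experiment()] and the command-line interface.
#'
#' @inheritParams ockra
#' @param method One of `"ockra"`, `"parzen"`, `"kmeans1"` (closest center),
#'   `"kmeans2"` (all centers), `"ocsvm"`.
#' @param ... Passed to [ocsvm_oc()] for the SVM adapter.
#' @return A fitted model with a `predict` method returning one score per row.
#' @export
oc_train <- function(x, method = c("ockra", "parzen", "kmeans1", "kmeans2", "ocsvm"),
                     n_members = 100, k = 10, seed = 1, timestamps = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    ockra = ockra(x, n_members = n_members, k = k, seed = seed,
                  timestamps = timestamps),
    parzen = parzen_oc(x, timestamps = timestamps),
    kmeans1 = kmeans_oc(x, k = k, mode = "closest", seed = seed,
                        timestamps = timestamps),
    kmeans2 = kmeans_oc(x, k = k, mode = "all", seed = seed,
                        timestamps = timestamps),
    ocsvm = ocsvm_oc(x, ...)
  )
}
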