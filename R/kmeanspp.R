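# k-means++ seeding followed by Lloyd iterations, on Euclidean distance.
# Hand-rolled because the seeding rule is part of the ensemble's definition
# and must be reproducible member-by-member from the R RNG stream.

# Squared Euclidean distances between the rows of A (m x d) and B (k x d).
.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Fit cluster centroids with k-means++ seeding and Lloyd iterations
#'
#' The first center is drawn uniformly among the rows; each subsequent center
#' is drawn with probability proportional to the squared Euclidean distance to
#' the nearest center already chosen. Lloyd iterations then alternate
#' assignment (ties to the lowest centroid index) and centroid recomputation
#' until the largest centroid shift falls below `tol` or `max_iter` is
#' reached. An emptied cluster is repaired by moving its centroid to the point
#' farthest from its current centroid. When the data contain fewer than `k`
#' distinct rows, that many centroids are returned instead.
#'
#' Uses the current R RNG stream; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param x Numeric matrix (rows = observations).
#' @param k Requested number of clusters (>= 1).
#' @param max_iter Maximum Lloyd iterations (default 100).
#' @param tol Convergence threshold on the maximum centroid displacement.
#' @return Numeric matrix of `min(k, #distinct rows)` centroids.
#' @export
kmeanspp <- function(x, k, max_iter = 100, tol = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stop("cannot cluster an empty matrix")
  if (k < 1L) stop("k must be >= 1")
  k <- min(k, nrow(unique(x)))

  m <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i0 <- sample.int(m, 1L)
  centers[1L, ] <- x[i0, ]
  if (k > 1L) {
    d2 <- .sqdist(x, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2:k) {
      tot <- sum(d2)
      if (tot <= 0) {
        # all points coincide with chosen centers; fall back to uniform
        pick <- sample.int(m, 1L)
      } else {
        u <- runif(1L) * tot
        pick <- which(cumsum(d2) >= u)[1L]
      }
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, .sqdist(x, centers[j, , drop = FALSE])[, 1L])
    }
  }

  for (iter in seq_len(max_iter)) {
    d2 <- .sqdist(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # empty cluster: seize the point farthest from its own centroid
        far <- which.max(d2[cbind(seq_len(m), assign)])
        new_centers[j, ] <- x[far, ]
        assign[far] <- j
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  dimnames(centers) <- list(NULL, colnames(x))
  centers
}

# Within-cluster sum of squared distances to the nearest centroid.
.inertia <- function(x, centers) {
  sum(apply(.sqdist(as.matrix(x), as.matrix(centers)), 1L, min))
}
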