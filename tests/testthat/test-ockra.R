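test_that("random feature selection draws with replacement and deduplicates", {
  expect_identical(select_random_features(1), 1L)
  set.seed(42); a <- select_random_features(26)
  set.seed(42); b <- select_random_features(26)
  expect_identical(a, b)
  expect_true(all(a >= 1 & a <= 26))
  expect_false(anyDuplicated(a) > 0)
  expect_error(select_random_features(0), ">= 1")

  # expected retained fraction: 1 - (25/26)^26 = 0.6393 (closed form)
  set.seed(1)
  frac <- mean(vapply(1:2000, function(i) length(select_random_features(26)), 0)) / 26
  expect_equal(frac, 1 - (25 / 26)^26, tolerance = 0.01)
})

test_that("projection selects columns in canonical order and validates indices", {
  x <- matrix(1:12, 4, 3)
  expect_identical(project_features(x, 1:3), x)
  expect_identical(project_features(x, 2), x[, 2, drop = FALSE])
  expect_identical(project_features(x, c(3, 1, 3)), x[, c(1, 3)])
  expect_identical(project_features(project_features(x, c(2, 3)), 1:2),
                   project_features(x, c(2, 3)))
  expect_error(project_features(x, 4), "out of range")
})

test_that("distance threshold is the mean pairwise distance of the 60-s subsample", {
  expect_equal(distance_threshold(matrix(c(0, 2), 2, 1)), 2)
  # brute-force pairwise mean for {0,1,2}: distances {1,1,2} -> 4/3
  pts <- matrix(c(0, 1, 2), 3, 1)
  expect_equal(distance_threshold(pts), mean(dist(pts)))
  expect_equal(distance_threshold(pts), 4 / 3)

  # 1 Hz timestamps: m rows reduce to ~m/60 kept points
  set.seed(3)
  x <- matrix(rnorm(600), 600, 1)
  ts <- 0:599
  kept <- ockra:::.subsample_idx(600, ts, 60)
  expect_equal(length(kept), 10L)
  expect_true(all(diff(ts[kept]) >= 60))
  expect_equal(distance_threshold(x, ts), mean(dist(x[kept, , drop = FALSE])))

  # degenerate constant data hits the positive floor
  expect_equal(distance_threshold(matrix(1, 5, 2)), 1e-12)
  expect_error(distance_threshold(matrix(1, 1, 2)), "at least 2 rows")
})

test_that("k-means++ recovers degenerate and well-separated structure", {
  x <- matrix(rnorm(40), 20, 2)
  set.seed(1)
  expect_equal(kmeanspp(x, 1), matrix(colMeans(x), 1), ignore_attr = TRUE)

  # k = number of distinct rows: centroids are the rows themselves
  xd <- matrix(c(0, 0, 5, 5, 9, 0), 3, 2, byrow = TRUE)
  set.seed(2)
  ctr <- kmeanspp(rbind(xd, xd), 3)
  expect_equal(ctr[order(ctr[, 1]), ], xd[order(xd[, 1]), ],
               tolerance = 1e-9, ignore_attr = TRUE)
  # more clusters than distinct rows: k' = distinct-row count
  set.seed(2)
  expect_equal(nrow(kmeanspp(rbind(xd, xd), 10)), 3L)

  blobs <- two_blobs(n = 50, sd = 0.1, seed = 5)
  set.seed(6)
  ctr <- kmeanspp(blobs, 2)
  ctr <- ctr[order(ctr[, 1]), ]
  expect_lt(sqrt(sum((ctr[1, ] - colMeans(blobs[1:50, ]))^2)), 0.2)
  expect_lt(sqrt(sum((ctr[2, ] - colMeans(blobs[51:100, ]))^2)), 0.2)
  expect_error(kmeanspp(matrix(0, 0, 2), 2), "empty")
})

test_that("k-means++ inertia matches the exhaustive brute-force optimum on tiny instances", {
  cases <- list(
    list(seed = 11, m = 10, d = 2, k = 2),
    list(seed = 12, m = 8, d = 3, k = 2),
    list(seed = 13, m = 7, d = 1, k = 3)
  )
  for (cs in cases) {
    set.seed(cs$seed)
    # separated structure so the global optimum is well-defined
    x <- matrix(rnorm(cs$m * cs$d), cs$m, cs$d) +
      5 * (seq_len(cs$m) %% cs$k)
    best <- brute_force_inertia(x, cs$k)
    set.seed(cs$seed + 100)
    fit <- kmeanspp(x, cs$k)
    expect_equal(ockra:::.inertia(x, fit), best, tolerance = 1e-6)
    # independent reference implementation agrees
    ref <- kmeans(x, cs$k, nstart = 25)
    expect_equal(ref$tot.withinss, best, tolerance = 1e-6)
  }
})

test_that("member similarity kernel matches its printed bounds and monotonicity", {
  expect_equal(member_similarity(0, 1), 1)
  expect_equal(member_similarity(1, 1), exp(-0.5))
  expect_gt(member_similarity(1, 1), 0.6)
  expect_equal(member_similarity(3, 1), exp(-4.5))
  expect_lt(member_similarity(3, 1), 0.02)
  d <- seq(0, 5, by = 0.1)
  expect_true(all(diff(member_similarity(d, 1.3)) < 0))
  expect_error(member_similarity(1, 0), "delta")
  expect_error(member_similarity(-1, 1), "dmin")
})

test_that("ensemble scoring averages per-member kernel similarities", {
  # two members with dmin/delta of 1 and 3: s = (e^-0.5 + e^-4.5)/2
  model <- structure(list(
    members = list(
      list(features = 1L, delta = 1, centroids = matrix(0, 1, 1)),
      list(features = 2L, delta = 1, centroids = matrix(0, 1, 1))
    ), n = 2L, n_members = 2L, k = 1L, seed = 0L, feature_names = NULL),
    class = "ockra")
  s <- predict(model, matrix(c(1, 3), 1, 2))
  expect_equal(s, (exp(-0.5) + exp(-4.5)) / 2, tolerance = 1e-12)
  expect_equal(round(s, 4), 0.3088)
  expect_error(predict(model, matrix(0, 1, 3)), "features")
})

test_that("training is reproducible and stores n_members x k centroids", {
  set.seed(99)
  x <- matrix(rnorm(200 * 4), 200, 4)
  fit1 <- ockra(x, n_members = 20, k = 5, seed = 7)
  fit2 <- ockra(x, n_members = 20, k = 5, seed = 7)
  expect_identical(fit1, fit2)
  expect_identical(predict(fit1, x), predict(fit2, x))
  expect_equal(sum(vapply(fit1$members, function(m) nrow(m$centroids), 0L)),
               20L * 5L)
  fit3 <- ockra(x, n_members = 20, k = 5, seed = 8)
  expect_false(identical(fit1$members[[1]]$features, fit3$members[[1]]$features) &&
               identical(fit1$members[[2]]$features, fit3$members[[2]]$features))

  # a single-member ensemble scores exactly as its member
  fit1m <- ockra(x, n_members = 1, k = 3, seed = 3)
  mem <- fit1m$members[[1]]
  q <- matrix(rnorm(4), 1, 4)
  dmin <- min(sqrt(ockra:::.sqdist(q[, mem$features, drop = FALSE],
                                   mem$centroids)))
  expect_equal(predict(fit1m, q), member_similarity(dmin, mem$delta))
  expect_error(ockra(x[1, , drop = FALSE]), "at least 2")
})

test_that("scores stay in [0,1], hit 1 only at zero distance, and decay radially", {
  x <- matrix(rnorm(100 * 3), 100, 3)
  fit <- ockra(x, n_members = 15, k = 4, seed = 2)
  q <- matrix(rnorm(50 * 3, sd = 4), 50, 3)
  s <- predict(fit, q)
  expect_true(all(s >= 0 & s <= 1))

  # constant training data: the sole centroid in every member is that point,
  # so the point itself scores exactly 1 and anything else (almost) 0
  xc <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  fitc <- ockra(xc, n_members = 10, k = 10, seed = 5)
  expect_equal(predict(fitc, xc[1, , drop = FALSE]), 1)
  expect_lt(predict(fitc, xc[1, , drop = FALSE] + 1), 1e-6)

  # single-member monotonicity: moving radially away from the nearest
  # centroid never increases the score
  fit1 <- ockra(x, n_members = 1, k = 3, seed = 4)
  ctr <- fit1$members[[1]]$centroids[1, ]
  dir <- rnorm(length(ctr)); dir <- dir / sqrt(sum(dir^2))
  q_full <- matrix(0, 8, 3)
  q_full[, fit1$members[[1]]$features] <-
    matrix(ctr, 8, length(ctr), byrow = TRUE) + outer(seq(0, 7), dir)
  expect_true(all(diff(predict(fit1, q_full)) <= 1e-12))
})

test_that("model JSON round trip reproduces structure and scores exactly", {
  x <- matrix(rnorm(80 * 5), 80, 5)
  fit <- ockra(x, n_members = 5, k = 3, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_identical(back$n, fit$n)
  expect_identical(back$n_members, fit$n_members)
  expect_identical(lapply(back$members, `[[`, "features"),
                   lapply(fit$members, `[[`, "features"))
  expect_equal(lapply(back$members, `[[`, "centroids"),
               lapply(fit$members, function(m) unname(m$centroids)))
  q <- matrix(rnorm(10 * 5), 10, 5)
  expect_equal(predict(back, q), predict(fit, q), tolerance = 1e-12)
})

test_that("ensemble separates anomalies shifted 5 pooled sd in 3 features", {
  set.seed(31)
  normal <- matrix(rnorm(400 * 6), 400, 6)
  pooled_sd <- apply(normal, 2, sd)
  anom <- matrix(rnorm(80 * 6), 80, 6)
  anom[, 1:3] <- anom[, 1:3] + 5 * rep(pooled_sd[1:3], each = 80)
  fit <- ockra(normal, n_members = 30, k = 10, seed = 32)
  s <- c(predict(fit, normal), predict(fit, anom))
  lb <- c(rep("typical", 400), rep("atypical", 80))
  expect_gt(auc(roc_points(s, lb)), 0.95)
})

test_that("labels present in a training table are stripped, never learned from", {
  set.seed(41)
  df <- as.data.frame(matrix(rnorm(50 * 3), 50))
  df$label <- rep(c("typical", "atypical"), 25)
  fit_lab <- ockra(df, n_members = 5, k = 2, seed = 1)
  fit_unlab <- ockra(df[, 1:3], n_members = 5, k = 2, seed = 1)
  expect_identical(fit_lab$members, fit_unlab$members)
  expect_equal(fit_lab$n, 3L)
})
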