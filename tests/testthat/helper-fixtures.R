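# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# One raw-log reading block: a channel sampled at `hz` over [t0, t0 + secs).
reading_block <- function(channel, values, t0 = 0, hz = length(values)) {
  data.frame(timestamp = t0 + (seq_along(values) - 1) / hz,
             channel = channel, value = values)
}

# Minimal complete one-window log covering all 17 channels, with accel_x
# overridable (used for the window-rule arithmetic checks).
one_window_log <- function(accel_x = rep(0.5, 8), t0 = 0) {
  hr_chans <- c("gyro_accel_x", "gyro_accel_y", "gyro_accel_z",
                "gyro_x", "gyro_y", "gyro_z", "accel_y", "accel_z")
  blocks <- lapply(hr_chans, function(ch) reading_block(ch, rep(0, 8), t0))
  blocks <- c(blocks, list(reading_block("accel_x", accel_x, t0)))
  one_hz <- data.frame(
    timestamp = t0,
    channel = c("heart_rate", "skin_temp", "pace", "speed", "uv",
                "steps_total", "distance_total", "calories_total"),
    value = c(70, 33, 0, 0, 0, 100, 5000, 40))
  rbind(do.call(rbind, blocks), one_hz)
}

# A multi-window log: `n_sec` windows of the one-window pattern with
# cumulative counters advancing by fixed increments.
multi_window_log <- function(n_sec = 3, step_inc = 3, dist_inc = 50,
                             cal_inc = 0.1) {
  logs <- lapply(seq_len(n_sec) - 1, function(s) {
    lg <- one_window_log(t0 = s)
    lg$value[lg$channel == "steps_total"] <- 100 + step_inc * s
    lg$value[lg$channel == "distance_total"] <- 5000 + dist_inc * s
    lg$value[lg$channel == "calories_total"] <- 40 + cal_inc * s
    lg
  })
  do.call(rbind, logs)
}

# Two well-separated Gaussian blobs in 2-D.
two_blobs <- function(n = 50, sd = 0.1, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n, 0, sd), ncol = 2),
        matrix(rnorm(2 * n, 10, sd), ncol = 2))
}

# Brute-force k-means optimum: enumerate every assignment of m points to k
# clusters and return the minimum within-cluster sum of squared distances.
brute_force_inertia <- function(x, k) {
  x <- as.matrix(x)
  m <- nrow(x)
  stopifnot(k^m <= 3e6)
  best <- Inf
  assign <- rep(1L, m)
  repeat {
    inertia <- 0
    for (j in unique(assign)) {
      pts <- x[assign == j, , drop = FALSE]
      ctr <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, inertia)
    i <- 1L
    while (i <= m && assign[i] == k) {
      assign[i] <- 1L
      i <- i + 1L
    }
    if (i > m) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Rank-based AUC oracle: P(score_anomaly < score_normal) + 0.5 P(tie),
# independent of the threshold-sweep implementation.
mann_whitney_auc <- function(scores, labels) {
  a <- scores[labels == "atypical"]
  t <- scores[labels == "typical"]
  cmp <- outer(a, t, function(x, y) (x < y) + 0.5 * (x == y))
  mean(cmp)
}

# Exhaustive threshold-enumeration PR oracle: precision/recall at every
# distinct score threshold (call positive when score <= thr).
enumerate_pr <- function(scores, labels) {
  P <- sum(labels == "atypical")
  do.call(rbind, lapply(sort(unique(scores)), function(thr) {
    called <- scores <= thr
    tp <- sum(called & labels == "atypical")
    data.frame(recall = tp / P, precision = tp / sum(called))
  }))
}
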