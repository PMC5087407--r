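# Preprocessing of raw multi-rate wearable sensor logs into per-second
# 26-dimensional feature vectors, plus fold splitting and CSV I/O for
# labeled feature tables.

# Channel taxonomy. High-rate channels (nominally 8 Hz) form the three
# tri-axial blocks of the feature vector; value channels are read at 1 Hz
# or slower and enter the vector as raw (carried-forward) values;
# cumulative channels enter as per-second increments.
.hr_channels <- c("gyro_accel_x", "gyro_accel_y", "gyro_accel_z",
                  "gyro_x", "gyro_y", "gyro_z",
                  "accel_x", "accel_y", "accel_z")
.value_channels <- c("heart_rate", "skin_temp", "pace", "speed", "uv")
.cum_channels <- c("steps_total", "distance_total", "calories_total")

#' Canonical feature names of the 26-dimensional per-second vector
#'
#' Fields 1-18 are the mean and sample standard deviation of the three
#' tri-axial high-rate blocks (accelerometer readings delivered with the
#' gyroscope event, gyroscope angular velocity, accelerometer), fields 19-23
#' the carried-forward heart rate, skin temperature, pace, speed and UV
#' values, and fields 24-26 the per-second increments of the cumulative
#' pedometer, distance and calorie counters.
#'
#' @return Character vector of length 26.
#' @export
feature_names <- function() {
  hr <- as.vector(t(outer(.hr_channels, c("mean", "sd"), paste, sep = "_")))
  c(hr, "heart_rate", "skin_temp", "pace", "speed", "uv",
    "steps_delta", "distance_delta", "calories_delta")
}

#' Encode the band's ordinal UV exposure category as a number
#'
#' @param category Character vector with values among
#'   `"none"`, `"low"`, `"medium"`, `"high"`, `"very_high"`.
#' @return Numeric vector (0 = none ... 4 = very_high).
#' @examples
#' encode_uv(c("none", "medium", "very_high"))
#' @export
encode_uv <- function(category) {
  codes <- c(none = 0, low = 1, medium = 2, high = 3, very_high = 4)
  bad <- !(category %in% names(codes))
  if (any(bad)) {
    stop("unknown UV category: ", paste(unique(category[bad]), collapse = ", "))
  }
  unname(codes[category])
}

# Carry-forward lookup: value of the last reading at or before each output
# second; seconds before the first reading are backfilled with it.
.carry_forward <- function(read_secs, read_vals, out_secs) {
  if (length(read_secs) == 0L) return(rep(0, length(out_secs)))
  idx <- findInterval(out_secs, read_secs)
  idx[idx == 0L] <- 1L
  read_vals[idx]
}

#' Build per-second 26-dimensional feature vectors from a raw sensor log
#'
#' Applies the window rules for a one-second window: channels sampled faster
#' than 1 s contribute their window mean and sample standard deviation (sd 0
#' for a single sample); channels at 1 s contribute the raw value; slower
#' channels contribute the last observed value, carried forward; cumulative
#' channels (pedometer, distance, calories) contribute the difference between
#' the current and previous absolute value. A second with no high-rate sample
#' (a log gap, e.g. battery recharging) emits no vector. The increment of a
#' cumulative channel is 0 at the first emitted second and is reset to 0 after
#' a gap longer than `gap_reset` seconds.
#'
#' @param log Data frame with columns `timestamp` (seconds, non-decreasing per
#'   channel), `channel` (see [feature_names()] for the tri-axial blocks;
#'   value channels are `heart_rate`, `skin_temp`, `pace`, `speed`, `uv`;
#'   cumulative channels are `steps_total`, `distance_total`,
#'   `calories_total`) and `value` (numeric; UV already numerically encoded,
#'   see [encode_uv()]).
#' @param gap_reset Gap length in seconds after which the previous reference
#'   value of cumulative channels is discarded (default 120).
#' @return Data frame with a window-start column `t` and the 26 feature
#'   columns of [feature_names()], one row per emitted second.
#' @export
build_feature_vectors <- function(log, gap_reset = 120) {
  if (is.null(log) || nrow(log) == 0L) stop("empty sensor log")
  need <- c("timestamp", "channel", "value")
  if (!all(need %in% names(log))) {
    stop("log must have columns: ", paste(need, collapse = ", "))
  }
  known <- c(.hr_channels, .value_channels, .cum_channels)
  bad <- setdiff(unique(log$channel), known)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  log <- log[order(log$timestamp), , drop = FALSE]
  sec <- floor(log$timestamp)

  is_hr <- log$channel %in% .hr_channels
  out_secs <- sort(unique(sec[is_hr]))
  if (length(out_secs) == 0L) stop("log contains no high-rate samples")

  m <- length(out_secs)
  out <- matrix(0, nrow = m, ncol = 26,
                dimnames = list(NULL, feature_names()))

  # high-rate blocks: window mean and sample sd, carried forward across
  # windows where a channel happens to be missing (sd 0 there)
  for (ch in .hr_channels) {
    rows <- log$channel == ch
    s <- sec[rows]
    v <- log$value[rows]
    if (length(v) == 0L) next
    grp <- factor(s, levels = sort(unique(s)))
    mu <- tapply(v, grp, mean)
    n_w <- tapply(v, grp, length)
    ssq <- tapply(v, grp, function(z) sum((z - mean(z))^2))
    sdv <- ifelse(n_w > 1L, sqrt(ssq / (n_w - 1L)), 0)
    ch_secs <- as.numeric(names(mu))
    hit <- match(out_secs, ch_secs)
    mean_col <- .carry_forward(ch_secs, as.numeric(mu), out_secs)
    sd_col <- ifelse(is.na(hit), 0, as.numeric(sdv)[hit])
    out[, paste0(ch, "_mean")] <- mean_col
    out[, paste0(ch, "_sd")] <- sd_col
  }

  # value channels: last reading at or before the window (rules 2 and 3)
  val_cols <- c(heart_rate = "heart_rate", skin_temp = "skin_temp",
                pace = "pace", speed = "speed", uv = "uv")
  for (ch in names(val_cols)) {
    rows <- log$channel == ch
    out[, val_cols[[ch]]] <- .carry_forward(sec[rows], log$value[rows], out_secs)
  }

  # cumulative channels: per-second increment, 0 at a segment start
  seg_break <- c(TRUE, diff(out_secs) > gap_reset)
  cum_cols <- c(steps_total = "steps_delta", distance_total = "distance_delta",
                calories_total = "calories_delta")
  for (ch in names(cum_cols)) {
    rows <- log$channel == ch
    abs_val <- .carry_forward(sec[rows], log$value[rows], out_secs)
    d <- c(0, diff(abs_val))
    d[seg_break] <- 0
    out[, cum_cols[[ch]]] <- d
  }

  data.frame(t = out_secs, out, check.names = FALSE)
}

#' Split a subject's data into five-fold train/test index sets
#'
#' The normal-behavior rows are partitioned into `n_folds` contiguous temporal
#' blocks of (approximately) equal size. Each repetition trains on four blocks
#' and tests on the remaining block joined with the full anomaly set; anomaly
#' rows never enter training.
#'
#' @param normal Normal-behavior dataset (data frame/matrix) or its row count.
#' @param anomalous Anomaly dataset or its row count.
#' @param n_folds Number of folds (default 5).
#' @return List of `n_folds` splits, each a list with integer index vectors
#'   `train` and `test` (over normal rows) and `anomaly` (over anomaly rows).
#' @export
split_folds <- function(normal, anomalous, n_folds = 5) {
  n <- if (is.numeric(normal) && length(normal) == 1L) normal else nrow(normal)
  n_a <- if (is.numeric(anomalous) && length(anomalous) == 1L) anomalous else nrow(anomalous)
  if (n < n_folds) stop("fewer normal rows (", n, ") than folds (", n_folds, ")")
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  lapply(seq_len(n_folds), function(i) {
    test <- (bounds[i] + 1L):bounds[i + 1L]
    list(train = setdiff(seq_len(n), test),
         test = test,
         anomaly = seq_len(n_a))
  })
}

#' Read / write a labeled feature table as CSV
#'
#' The on-disk format is one observation per row: named numeric feature
#' columns (26 for band-schema data, any width accepted), optionally preceded
#' by a window-time column `t`, with an optional final column `label` taking
#' the values `"typical"` (normal behavior) or `"atypical"` (anomaly). Labels
#' are ground truth for evaluation only and are never used in training.
#'
#' @param path File path.
#' @return `read_labeled_csv` returns a data frame of numeric features with
#'   the optional `t` and `label` columns preserved.
#' @export
read_labeled_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ds <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ds) < 1L) stop("no columns in ", path)
  last <- names(ds)[ncol(ds)]
  has_label <- last == "label" || (is.character(ds[[ncol(ds)]]) &&
    all(ds[[ncol(ds)]] %in% c("typical", "atypical")))
  if (has_label) {
    lab <- ds[[ncol(ds)]]
    bad <- which(!lab %in% c("typical", "atypical"))
    if (length(bad)) {
      stop("unknown label '", lab[bad[1]], "' at row ", bad[1], " of ", path)
    }
  }
  feat_cols <- setdiff(seq_len(ncol(ds)), if (has_label) ncol(ds) else integer(0))
  feat_cols <- setdiff(feat_cols, which(names(ds) == "t"))
  for (j in feat_cols) {
    if (!is.numeric(ds[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(ds[[j]]))))
      stop("non-numeric value in column '", names(ds)[j], "' at row ",
           if (length(bad)) bad[1] else 1L, " of ", path)
    }
  }
  if (has_label) names(ds)[ncol(ds)] <- "label"
  ds
}

#' @rdname read_labeled_csv
#' @param ds Data frame as returned by [read_labeled_csv()] or
#'   [build_feature_vectors()] (optionally with a `label` column).
#' @export
write_labeled_csv <- function(ds, path) {
  stopifnot(is.data.frame(ds))
  if ("label" %in% names(ds)) {
    ds <- ds[, c(setdiff(names(ds), "label"), "label"), drop = FALSE]
  }
  write.csv(ds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a dataset into feature matrix, timestamps and labels. Columns named
# t/timestamp/label/subject are metadata, everything else is a feature.
.as_features <- function(x) {
  if (is.matrix(x)) {
    return(list(X = x, timestamps = NULL, labels = NULL))
  }
  stopifnot(is.data.frame(x))
  ts <- if ("t" %in% names(x)) x$t else if ("timestamp" %in% names(x)) x$timestamp
  labels <- if ("label" %in% names(x)) x$label
  drop <- intersect(names(x), c("t", "timestamp", "label", "subject"))
  X <- as.matrix(x[, setdiff(names(x), drop), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, timestamps = ts, labels = labels)
}
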