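#' Reference per-subject AUC table of the PRIDE benchmark
#'
#' The published per-subject AUC percentages (ROC, TPR vs FPR) of the five
#' one-class classifiers on the 23-subject PRIDE wearable-band benchmark,
#' shipped as a plain-CSV fixture. The final `"Average"` row holds the
#' per-method column means rounded to two decimals. The PRIDE data themselves
#' are restricted, so this table serves as the arithmetic fixture for the
#' evaluation-report schema and the paired method comparisons.
#'
#' @return Data frame with columns `subject`, `ocSVM`, `Parzen`, `kMeans1`,
#'   `kMeans2`, `OCKRA`.
#' @export
pride_auc_table <- function() {
  path <- system.file("extdata", "pride_benchmark_auc.csv", package = "ockra",
                      mustWork = TRUE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
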