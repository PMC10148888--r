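#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computed via mid-ranks, which is exactly the pair statistic
#' (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos n_neg).
#'
#' @param scores numeric predictions.
#' @param labels binary 0/1 truth; both classes must be present.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("AUC undefined: only one class present",
          class = "pwmmrm_undefined_auc_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# empirical ROC curve over score thresholds; starts (0,0), ends (1,1)
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1); fp <- cumsum(labels[o] == 0)
  # collapse ties so the curve is a function of the threshold
  keep <- c(diff(scores[o]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(labels == 0)),
             tpr = c(0, tp[keep] / sum(labels == 1)))
}

#' Bootstrap validation of a classifier's ROC AUC
#'
#' Case-resampling percentile confidence interval for the AUC; resamples
#' that lose a class are redrawn. Reproducible given the seed.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param level confidence level in (0,1).
#' @param seed integer seed.
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `curve`,
#'   `n_bootstrap`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000L, level = 0.95,
                             seed = 1L) {
  if (level <= 0 || level >= 1) stopf("level must be in (0,1)")
  if (n_boot < 100) stopf("n_boot must be >= 100")
  auc <- roc_auc(scores, labels)  # also validates both classes present
  n <- length(scores)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      roc_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 curve = roc_curve(scores, labels),
                 n_bootstrap = as.integer(n_boot), level = level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC %.3f (%.0f%% bootstrap CI %.3f-%.3f, %d replicates)\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, x$n_bootstrap))
  invisible(x)
}
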