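#' Wilcoxon signed-rank test for paired passing rates
#'
#' Two-sided test of the paired difference `x - y`. Zero differences are
#' dropped (standard signed-rank convention); absolute differences are
#' midranked. For `n <= exact_max` non-zero pairs the null distribution is
#' enumerated exactly over all `2^n` sign assignments (valid under ties);
#' beyond that a normal approximation with tie-corrected variance and
#' continuity correction is used. If every difference is zero the test is
#' degenerate and `p = 1` is returned with a flag.
#'
#' @param x,y Equal-length paired numeric samples, `n >= 5`.
#' @param exact_max Largest `n` for exact enumeration (default 12).
#' @return List with `p_value`, `statistic` (W+, the positive-rank sum),
#'   `n_used`, `method`, and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  if (length(x) != length(y))
    stop_named("vmatqa_invalid_samples", "paired samples must have equal length")
  if (length(x) < 5)
    stop_named("vmatqa_invalid_samples", "need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p_value = 1, statistic = NA_real_, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    # exact enumeration over all sign assignments, tie-safe via midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wall <- as.vector(signs %*% r)
    p <- mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w, n_used = n, method = method,
       degenerate = FALSE)
}

#' ROC-based error detection from gamma passing rates
#'
#' Builds the ROC of "error present" (positive class) against "error free"
#' using the gamma passing rate as the score (errors are expected to lower
#' the rate, so a map is classified as an error when its rate falls at or
#' below the threshold). The AUC is the rank statistic
#' `P(rate_error < rate_error_free) + 0.5 P(tie)`; the operating threshold
#' maximizes Youden's J (ties resolved toward the lower threshold) and the
#' reported accuracy is evaluated at that threshold on the pooled sample.
#' A Wilcoxon signed-rank p-value is included when a pairing of each error
#' rate with its error-free partner is supplied (or when the two samples
#' have equal length and are paired by position).
#'
#' @param rates_error_free,rates_error Passing-rate samples in percent.
#' @param ef_index Optional integer index pairing `rates_error[k]` with
#'   `rates_error_free[ef_index[k]]` for the Wilcoxon test.
#' @return An object of class `detection_outcome`: `p_value` (NA when no
#'   pairing is available), `auc`, `threshold`, `accuracy` (percent),
#'   `n_error_free`, `n_error`.
#' @export
roc_detect <- function(rates_error_free, rates_error, ef_index = NULL) {
  if (!length(rates_error_free) || !length(rates_error))
    stop_named("vmatqa_invalid_samples", "both samples must be non-empty")
  labels <- factor(c(rep("error_free", length(rates_error_free)),
                     rep("error", length(rates_error))),
                   levels = c("error_free", "error"))
  scores <- c(rates_error_free, rates_error)
  # direction ">": error-free (controls) expected to have the higher rates
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("error_free", "error"), direction = ">",
                   quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))

  cand <- sort(unique(scores))
  best <- list(j = -Inf, thr = NA_real_, acc = NA_real_)
  for (thr in cand) {
    sens <- mean(rates_error <= thr)
    spec <- mean(rates_error_free > thr)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) {
      acc <- (sum(rates_error <= thr) + sum(rates_error_free > thr)) /
        length(scores)
      best <- list(j = j, thr = thr, acc = acc)
    }
  }

  p <- NA_real_
  if (is.null(ef_index) &&
      length(rates_error) == length(rates_error_free))
    ef_index <- seq_along(rates_error_free)
  if (!is.null(ef_index) && length(rates_error) >= 5)
    p <- wilcoxon_signed_rank(rates_error_free[ef_index], rates_error)$p_value

  structure(list(p_value = p, auc = auc, threshold = best$thr,
                 accuracy = 100 * best$acc,
                 n_error_free = length(rates_error_free),
                 n_error = length(rates_error)),
            class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("<detection_outcome> AUC %.3f, threshold %.2f%%, accuracy %.1f%%, p %s\n",
              x$auc, x$threshold, x$accuracy,
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3))))
  invisible(x)
}
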