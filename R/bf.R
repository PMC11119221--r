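#' Difference of two models' evidence on the 2·log(BF) scale
#'
#' Given the log Bayes factors of models A and B against a *common* baseline
#' (usually a null model), returns `2 (log BF_A0 - log BF_B0)`, which equals
#' `2 log BF_AB`. Positive values favour A.
#'
#' @param log_bf_a0,log_bf_b0 Log Bayes factors of A and B versus the common
#'   baseline, on the natural-log scale.
#' @return `2 * (log_bf_a0 - log_bf_b0)`.
#' @examples
#' twoLogBFDiff(10123.59, 10121.52)  # 4.14
#' @export
twoLogBFDiff <- function(log_bf_a0, log_bf_b0) {
  if (!all(is.finite(log_bf_a0)) || !all(is.finite(log_bf_b0)))
    stop("log Bayes factors must be finite", call. = FALSE)
  2 * (log_bf_a0 - log_bf_b0)
}

#' Kass-Raftery evidence category for a 2·log(BF) value
#'
#' Conventional bands on the magnitude: below 2, evidence "not worth more
#' than a bare mention" (weak); 2 to 6, positive; 6 to 10, strong; 10 and
#' above, very strong. The category depends only on `|value|`; the sign says
#' which model is favoured and is reported separately by callers.
#'
#' @param value A 2·log(BF) value (finite; vectorized).
#' @return Character vector with levels `"weak"`, `"positive"`, `"strong"`,
#'   `"very strong"`.
#' @examples
#' interpret2LogBF(c(1.34, 4.14, 95.26))
#' @export
interpret2LogBF <- function(value) {
  if (!all(is.finite(value))) stop("value must be finite", call. = FALSE)
  v <- abs(value)
  cut(v, breaks = c(0, 2, 6, 10, Inf),
      labels = c("weak", "positive", "strong", "very strong"),
      right = FALSE, include.lowest = TRUE) |> as.character()
}

#' Schwarz (BIC) approximation to a log Bayes factor
#'
#' Under unit-information priors, `ln BF(model vs baseline) ~
#' (BIC_baseline - BIC_model) / 2`. Both BICs must come from fits on
#' identical observations; when the observation counts are supplied they are
#' checked.
#'
#' This is the fast desk-scale proxy for a fully Bayesian bridge-sampling
#' Bayes factor: BIC is a large-sample approximation that assumes a unit
#' prior, so treat the result as a screening quantity, not a substitute for
#' BFs computed under priors chosen for the problem.
#'
#' @param bic_model,bic_baseline BIC values of the model of interest and the
#'   baseline model.
#' @param n_model,n_baseline Optional observation counts used for the two
#'   fits; if both are given they must match.
#' @return Approximate `ln BF(model vs baseline)` (nats).
#' @examples
#' approxLogBFfromBIC(100, 100 + 2 * log(10))  # log(10): BF = 10
#' @export
approxLogBFfromBIC <- function(bic_model, bic_baseline,
                               n_model = NULL, n_baseline = NULL) {
  if (!all(is.finite(bic_model)) || !all(is.finite(bic_baseline)))
    stop("BIC values must be finite", call. = FALSE)
  if (!is.null(n_model) && !is.null(n_baseline) &&
      !isTRUE(all(n_model == n_baseline)))
    stop("BICs computed on different observation counts are not comparable",
         call. = FALSE)
  (bic_baseline - bic_model) / 2
}

#' Pairwise Bayes-factor comparison table
#'
#' Given labelled log Bayes factors of several models against a common
#' baseline, builds the table of all pairwise 2·log(BF) differences with
#' their Kass-Raftery categories and the direction of support.
#'
#' @param labels Character vector of model labels.
#' @param log_bf0 Numeric vector of log BFs versus the common baseline
#'   (nats), parallel to `labels`.
#' @return A `mlm_bf_comparison` data.frame with columns `model_a`,
#'   `model_b`, `log_bf_a0`, `log_bf_b0`, `two_log_bf_diff`, `category`,
#'   `favoured`.
#' @examples
#' bfCompare(c("best BIC", "best AIC", "full"),
#'           c(4296.58, 4297.25, 4248.95))
#' @export
bfCompare <- function(labels, log_bf0) {
  stopifnot(length(labels) == length(log_bf0), length(labels) >= 2L)
  if (anyDuplicated(labels)) stop("duplicate model labels", call. = FALSE)
  pairs <- utils::combn(length(labels), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- twoLogBFDiff(log_bf0[a], log_bf0[b])
    data.frame(model_a = labels[a], model_b = labels[b],
               log_bf_a0 = log_bf0[a], log_bf_b0 = log_bf0[b],
               two_log_bf_diff = d,
               category = interpret2LogBF(d),
               favoured = if (d > 0) labels[a] else if (d < 0) labels[b]
                          else "neither",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mlm_bf_comparison", "data.frame")
  out
}

#' @export
print.mlm_bf_comparison <- function(x, ...) {
  cat("<bf comparison> 2*log(BF) differences vs a common baseline\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s vs %s: 2logBF = %.2f (%s; favours %s)\n",
                x$model_a[i], x$model_b[i], x$two_log_bf_diff[i],
                x$category[i], x$favoured[i]))
  }
  invisible(x)
}
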