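#' Receiver operating characteristic curve and AUC
#'
#' Thin wrapper around \pkg{pROC} producing a curve ordered by increasing
#' false-positive rate and the trapezoidal AUC, which equals the probability
#' that a random positive outscores a random negative (ties counted 1/2).
#'
#' @param scores numeric prediction scores (higher = more likely positive).
#' @param targets 0/1 vector; both classes must be present.
#' @return object of class `roc_result` with fields `thresholds`, `fpr`,
#'   `tpr` (monotone non-decreasing along the curve) and `auc`.
#' @export
roc_curve <- function(scores, targets) {
  if (length(scores) != length(targets)) {
    stop("scores and targets differ in length", call. = FALSE)
  }
  if (length(unique(targets)) < 2L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- pROC::roc(response = targets, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  structure(list(thresholds = r$thresholds[ord],
                 fpr = (1 - r$specificities)[ord],
                 tpr = r$sensitivities[ord],
                 auc = as.numeric(r$auc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}
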