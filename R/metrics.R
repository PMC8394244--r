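# Confusion-matrix performance metrics; AD is the positive class.

#' Build a confusion matrix from truth and prediction labels
#'
#' @param truth,pred factors or character vectors of `"AD"`/`"NOLD"`.
#' @param positive the positive class (default `"AD"`).
#' @return List with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, pred, positive = "AD") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == positive & pred == positive),
       fp = sum(truth != positive & pred == positive),
       tn = sum(truth != positive & pred != positive),
       fn = sum(truth == positive & pred != positive))
}

#' Performance metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, F-measure, Matthews correlation
#' coefficient, positive and negative predictive value. Percentages are on
#' the 0-100 scale (MCC on `[-1, 1]`), unrounded; reports round to two
#' decimals. A metric whose denominator is zero is `NA` (absent), not 0.
#'
#' @param cm list with `tp`, `fp`, `tn`, `fn` (see [confusion_matrix()]).
#' @return List of `sen`, `spec`, `acc`, `f`, `mcc`, `ppv`, `npv`.
#' @export
#' @examples
#' metrics_from_confusion(list(tp = 5, fn = 1, tn = 9, fp = 2))
metrics_from_confusion <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total < 1) stop("empty confusion matrix")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sen <- div(tp, tp + fn); spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp); npv <- div(tn, tn + fn)
  f <- if (is.na(sen) || is.na(ppv) || (ppv + sen) == 0) NA_real_ else
    2 * ppv * sen / (ppv + sen)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  list(sen = 100 * sen, spec = 100 * spec, acc = 100 * div(tp + tn, total),
       f = 100 * f, mcc = mcc, ppv = 100 * ppv, npv = 100 * npv)
}

format_metrics <- function(m) {
  vapply(c("sen", "spec", "acc", "f", "mcc", "ppv", "npv"), function(k) {
    v <- m[[k]]
    if (is.na(v)) "-" else formatC(round(v, 2), format = "f", digits = 2)
  }, "")
}
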