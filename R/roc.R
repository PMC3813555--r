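# ROC calibration of the fat-fraction classification band.
#
# The 20%/60% fat-fraction band used to classify brown adipose tissue was
# calibrated on ex vivo samples: the upper threshold is the largest cut
# keeping the white-adipose false-positive rate under 10%, the lower
# threshold the largest cut keeping brown-adipose classification at or above
# 99.9%.

#' Calibrate fat-fraction classification thresholds by ROC sweep
#'
#' Sweeps candidate thresholds over [0, 1] and, at each threshold t, records
#' the fraction of brown-adipose samples below t (true classification rate
#' for an upper cut), the fraction of white-adipose samples below t (false
#' positive rate of the upper cut), and the fraction of brown-adipose
#' samples above t (true classification rate for a lower cut). The operating
#' thresholds are chosen per the stated rules and the rates at the reference
#' cuts (0.20, 0.60) are reported for comparison. The area under the
#' ROC curve (upper-cut classification of brown vs white adipose) is
#' computed by the trapezoid rule.
#'
#' @param bat_ff,wat_ff numeric vectors of fat fractions for the two
#'   tissues (nonempty).
#' @param step sweep granularity (default 0.001).
#' @param wat_fpr_max upper-threshold false-positive ceiling (default 0.10).
#' @param bat_lower_rate lower-threshold classification floor (default
#'   0.999).
#' @return list with `thresholds` (data frame of the sweep), `upper`,
#'   `lower`, `operating` (rates at 0.20/0.60 and at the chosen thresholds)
#'   and `auc`.
#' @export
roc_calibrate <- function(bat_ff, wat_ff, step = 0.001, wat_fpr_max = 0.10,
                          bat_lower_rate = 0.999) {
  stopifnot(length(bat_ff) > 0, length(wat_ff) > 0)
  if (stats::sd(bat_ff) == 0 && stats::sd(wat_ff) == 0 &&
      bat_ff[1] == wat_ff[1]) {
    stop("no-threshold error: both samples are the same constant",
         call. = FALSE)
  }
  t <- seq(0, 1, by = step)
  fb <- stats::ecdf(bat_ff)
  fw <- stats::ecdf(wat_ff)
  bat_below <- fb(t)
  wat_below <- fw(t)
  bat_above <- 1 - fb(t)
  sweep_tab <- data.frame(threshold = t, bat_below = bat_below,
                          wat_below = wat_below, bat_above = bat_above)
  ok_up <- which(wat_below < wat_fpr_max)
  upper <- if (length(ok_up)) t[max(ok_up)] else NA_real_
  ok_lo <- which(bat_above >= bat_lower_rate)
  lower <- if (length(ok_lo)) t[max(ok_lo)] else NA_real_
  # trapezoid AUC of TPR (bat below t) against FPR (wat below t)
  auc <- sum(diff(wat_below) * (utils::head(bat_below, -1) +
                                  utils::tail(bat_below, -1)) / 2)
  operating <- list(
    bat_below_060 = fb(0.60), wat_below_060 = fw(0.60),
    bat_above_020 = 1 - fb(0.20),
    upper = upper, lower = lower,
    bat_below_upper = if (is.na(upper)) NA_real_ else fb(upper),
    wat_below_upper = if (is.na(upper)) NA_real_ else fw(upper),
    bat_above_lower = if (is.na(lower)) NA_real_ else 1 - fb(lower))
  list(thresholds = sweep_tab, upper = upper, lower = lower,
       operating = operating, auc = auc)
}
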