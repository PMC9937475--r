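# ROC construction and operating-point summaries. The empirical AUC is
# the trapezoidal area of the tie-collapsed ROC, which equals the
# Mann-Whitney statistic P(score_D > score_N) + 0.5 P(tie); the
# binormal closed form gives the detectability index Az for two
# Gaussian classes.

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the unique score values (larger
#' score = more diseased; log-likelihood-ratio scores satisfy this),
#' collapsing tied scores into single vertices, and integrates the area
#' by the trapezoidal rule. The resulting AUC is exactly the
#' Mann-Whitney probability of correct pairwise ranking, counting ties
#' as half.
#'
#' @param scores Numeric decision scores.
#' @param labels Truth labels, coded `"diseased"`/`"normal"` (or
#'   `"AD"`/`"NC"`, or a logical vector where `TRUE` = diseased).
#' @return An object of class `roc_curve`: list with `points` (data
#'   frame `fpr`, `tpr`, starting at (0,0) and ending at (1,1)), `auc`,
#'   `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels) {
  pos <- as_diseased_indicator(labels)
  if (length(scores) != length(pos))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need at least one diseased and one normal subject",
         call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # threshold at each distinct score (call diseased when score >= t)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  pts <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

as_diseased_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- toupper(as.character(labels))
  if (!all(l %in% c("DISEASED", "NORMAL", "AD", "NC")))
    stop("labels must be diseased/normal (or AD/NC)", call. = FALSE)
  l %in% c("DISEASED", "AD")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d diseased vs %d normal, %d vertices, AUC = %.3f\n",
              x$n_pos, x$n_neg, nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "false positive rate (1 - specificity)",
                 ylab = "true positive rate (sensitivity)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Binormal detectability index Az
#'
#' Closed-form area under the ROC curve for two Gaussian classes:
#' Az = Phi(|mu_n - mu_d| / sqrt(sigma_n^2 + sigma_d^2)), the
#' probability that a diseased draw falls on the diseased side of an
#' independent normal draw.
#'
#' @param normal,diseased `gaussian_density` objects, or an
#'   `lr_observer` passed as `normal` (Gaussian backend).
#' @return Az in \[0.5, 1\].
#' @examples
#' binormal_az(gaussian_density(7238.4, 870.0),
#'             gaussian_density(5962.1, 1025.3))
#' @export
binormal_az <- function(normal, diseased = NULL) {
  if (inherits(normal, "lr_observer")) {
    if (normal$backend != "gaussian")
      stop("binormal Az requires the Gaussian backend", call. = FALSE)
    diseased <- normal$diseased
    normal <- normal$normal
  }
  stopifnot(inherits(normal, "gaussian_density"),
            inherits(diseased, "gaussian_density"))
  stats::pnorm(abs(normal$mu - diseased$mu) /
               sqrt(normal$sigma^2 + diseased$sigma^2))
}

#' Hanley-McNeil confidence interval for an empirical AUC
#'
#' Normal-approximation interval using the Hanley-McNeil standard
#' error with the exponential approximation Q1 = A/(2-A),
#' Q2 = 2A^2/(1+A); bounds are clipped to \[0, 1\].
#'
#' @param curve A [empirical_roc()] result.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lower, upper)`; attribute `se` carries the
#'   standard error.
#' @export
auc_confidence_interval <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "roc_curve"))
  if (curve$n_pos < 2L || curve$n_neg < 2L)
    stop("confidence interval undefined for fewer than 2 subjects per class",
         call. = FALSE)
  a <- curve$auc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (curve$n_pos - 1) * (q1 - a^2) +
              (curve$n_neg - 1) * (q2 - a^2)) /
             (curve$n_pos * curve$n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(lower = max(0, a - z * se), upper = min(1, a + z * se))
  attr(out, "se") <- se
  out
}

#' Confusion-matrix report at the y = 0 operating point
#'
#' Classifies every subject of a labeled test cohort with
#' [predict.lr_observer()] and tabulates the result against truth.
#' AD is the positive class throughout.
#'
#' @param model An `lr_observer`.
#' @param test A [cohort_table()] where every subject is labeled AD
#'   or NC.
#' @return A `classification_report`: list with integer counts `tp`,
#'   `fp`, `tn`, `fn` and rates `sensitivity`, `specificity`,
#'   `balanced_accuracy`.
#' @export
evaluate_at_zero_threshold <- function(model, test) {
  stopifnot(inherits(test, "cohort_table"))
  if (nrow(test) == 0L)
    stop("empty test cohort", call. = FALSE)
  pred <- predict(model, test)
  if (any(pred$group == "UNKNOWN"))
    stop("every test subject must be labeled AD or NC", call. = FALSE)
  classification_report(
    tp = sum(pred$group == "AD" & pred$decision == "diseased"),
    fn = sum(pred$group == "AD" & pred$decision == "normal"),
    tn = sum(pred$group == "NC" & pred$decision == "normal"),
    fp = sum(pred$group == "NC" & pred$decision == "diseased"))
}

#' @rdname evaluate_at_zero_threshold
#' @param tp,fp,tn,fn Non-negative integer confusion counts (AD
#'   positive), for building a report directly from counts.
#' @export
classification_report <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (tp + fn == 0L || tn + fp == 0L)
    stop("report undefined without both diseased and normal subjects",
         call. = FALSE)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification at the y = 0 criterion (AD positive)\n")
  cat(sprintf("  TP %d  FN %d | TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  balanced accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity,
              100 * x$balanced_accuracy))
  invisible(x)
}
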