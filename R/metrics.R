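# Classification metrics and operating points for scored blood/non-blood
# predictions. Scores are probabilities in [0, 1]; labels are 1 = blood
# (positive), 0 = non-blood. A score >= threshold counts as a positive
# prediction (ties go to positive).

checkScored <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must be aligned and of equal length")
  if (length(scores) == 0L) stop("empty score set")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  if (min(scores) < 0 || max(scores) > 1)
    stop("scores must be in [0, 1]")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 (non-blood) or 1 (blood)")
  invisible(TRUE)
}

#' Confusion counts at a classification threshold
#'
#' @param scores numeric vector of probabilities in \code{[0, 1]}.
#' @param labels 0/1 vector aligned with \code{scores} (1 = blood).
#' @param threshold classification threshold; a score >= threshold is
#'   predicted blood. Default 0.5.
#' @return Named numeric vector \code{c(TP, FP, TN, FN)}.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  checkScored(scores, labels)
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1),
    FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0),
    FN = sum(!pred & labels == 1))
}

#' F-beta score from precision and recall
#'
#' \code{(1 + beta^2) * P * R / (beta^2 * P + R)}; F1 weighs precision and
#' recall equally, F2 weighs recall higher. Returns 0 when both precision and
#' recall are 0.
#'
#' @param precision,recall reals in \code{[0, 1]}.
#' @param beta 1 or 2.
#' @return Real in \code{[0, 1]}.
#' @examples
#' fBeta(0.5, 1, beta = 2)  # 5 * 0.5 / 3
#' @export
fBeta <- function(precision, recall, beta = 1) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) curve swept over all distinct score
#' thresholds. Computed through the rank (Mann-Whitney) identity, which
#' handles ties by the probabilistic interpretation:
#' \code{AUC = P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)}.
#'
#' @inheritParams confusionCounts
#' @return Real in \code{[0, 1]}.
#' @export
rocAuc <- function(scores, labels) {
  checkScored(scores, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("ROC AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# All achievable operating points: one row per candidate threshold (each
# distinct score, plus a threshold above all scores), with the sensitivity,
# FPR and specificity attained when scores >= threshold are positive.
operatingPoints <- function(scores, labels) {
  thr <- c(sort(unique(scores)), max(scores) + 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  data.frame(threshold = thr, sensitivity = sens, fpr = fpr,
             specificity = 1 - fpr)
}

#' Sensitivity at a fixed false-positive rate
#'
#' Sensitivity at the smallest threshold whose achieved FPR does not exceed
#' the requested rate (conservative attainment, no interpolation between
#' thresholds). With fewer negatives than \code{1/fpr} the requested rate
#' cannot be resolved and the result carries a
#' \code{attr(, "degenerateResolution") = TRUE} flag.
#'
#' @inheritParams confusionCounts
#' @param fpr requested false-positive rate, in \code{(0, 1)}.
#' @return Real in \code{[0, 1]}; non-decreasing in \code{fpr}.
#' @export
sensAtFpr <- function(scores, labels, fpr) {
  checkScored(scores, labels)
  if (!(fpr > 0 && fpr < 1)) stop("fpr must be in (0, 1)")
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L)
    stop("both classes must be present")
  op <- operatingPoints(scores, labels)
  ok <- op$fpr <= fpr
  out <- max(op$sensitivity[ok])           # always attainable: top threshold
  if (sum(labels == 0) < 1 / fpr) attr(out, "degenerateResolution") <- TRUE
  out
}

#' Specificity at a fixed sensitivity
#'
#' Specificity at the largest threshold whose achieved sensitivity is at
#' least the requested value (conservative attainment).
#'
#' @inheritParams confusionCounts
#' @param sens requested sensitivity, in \code{(0, 1]}.
#' @return Real in \code{[0, 1]}; non-increasing in \code{sens}.
#' @export
specAtSens <- function(scores, labels, sens) {
  checkScored(scores, labels)
  if (!(sens > 0 && sens <= 1)) stop("sens must be in (0, 1]")
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L)
    stop("both classes must be present")
  op <- operatingPoints(scores, labels)
  ok <- op$sensitivity >= sens
  if (!any(ok)) return(0)
  max(op$specificity[ok])
}

#' Full classification metric report
#'
#' Computes every evaluation metric: ROC AUC; F1 and F2 scores, sensitivity,
#' specificity, precision and accuracy at the 0.5 threshold; the
#' high-specificity operating points sens@0.01, sens@0.001 and sens@0.0001
#' (sensitivity at the threshold attaining the given false-positive rate);
#' and the high-sensitivity operating points spec@0.95, spec@0.99 and
#' spec@0.999 (specificity when sensitivity is forced to the given level).
#'
#' @inheritParams confusionCounts
#' @return Named list of 13 metric values, all in \code{[0, 1]}.
#' @export
fullReport <- function(scores, labels, threshold = 0.5) {
  cc <- confusionCounts(scores, labels, threshold)
  tp <- unname(cc["TP"]); fp <- unname(cc["FP"])
  tn <- unname(cc["TN"]); fn <- unname(cc["FN"])
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(
    ROCAUC = rocAuc(scores, labels),
    F1 = fBeta(precision, recall, 1),
    F2 = fBeta(precision, recall, 2),
    sensitivity = recall,
    specificity = specificity,
    precision = precision,
    accuracy = (tp + tn) / sum(cc),
    `sens@0.01` = as.numeric(sensAtFpr(scores, labels, 0.01)),
    `sens@0.001` = as.numeric(sensAtFpr(scores, labels, 0.001)),
    `sens@0.0001` = as.numeric(sensAtFpr(scores, labels, 0.0001)),
    `spec@0.95` = specAtSens(scores, labels, 0.95),
    `spec@0.99` = specAtSens(scores, labels, 0.99),
    `spec@0.999` = specAtSens(scores, labels, 0.999)
  )
}

#' Read a scored-prediction table
#'
#' @param path CSV with columns \code{image_id}, \code{score}, \code{label}.
#' @return data.frame with those columns.
#' @export
readScores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "score", "label")
  if (!all(need %in% names(df)))
    stop("scores CSV must have columns image_id, score, label")
  df
}
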