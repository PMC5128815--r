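# Coerce labels to 0/1 with 1 = positive. Accepts logical, 0/1 numeric,
# "+"/"-", or a factor/character with a stated positive level.
as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  if (is.null(positive)) {
    lv <- sort(unique(labels))
    positive <- if (all(lv %in% c("+", "-"))) "+"
      else if (all(lv %in% c("high", "low"))) "high"
      else if (all(lv %in% c("positive", "negative"))) "positive"
      else stop("cannot infer the positive label from: ",
                paste(lv, collapse = ", "))
  }
  as.integer(labels == positive)
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' ROC curve points
#'
#' Builds the ROC curve of a score against binary labels. Thresholds sit at
#' the distinct score values (a sample is called positive when its score is
#' greater than or equal to the threshold); tied scores collapse into a
#' single step. The curve always contains the endpoints (0,0) and (1,1).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (logical, 0/1, "+"/"-", "high"/"low", ...).
#' @param positive positive label when it cannot be inferred.
#' @return A data.frame of class `roc_curve` with columns `threshold`,
#'   `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  check_two_classes(y)
  stopifnot(length(scores) == length(y), !anyNA(scores))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; ys <- y[ord]
  runs <- rle(s)
  thr <- runs$values
  last <- cumsum(runs$lengths)
  cum_tp <- cumsum(ys)
  cum_fp <- cumsum(1 - ys)
  tpr <- cum_tp[last] / n_pos
  fpr <- cum_fp[last] / n_neg
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (out$fpr[nrow(out)] != 1 || out$tpr[nrow(out)] != 1) {
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x),
              trapezoid_auc(x$fpr, x$tpr)))
  invisible(x)
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; identical to the fraction of
#' (positive, negative) pairs ranked correctly, with 0.5 credit for ties.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  curve <- roc_points(scores, labels, positive)
  trapezoid_auc(curve$fpr, curve$tpr)
}

#' Optimal probability/score boundary from a ROC curve
#'
#' Selects the threshold of the curve point with minimal Euclidean distance
#' to the top-left corner, `sqrt(fpr^2 + (1 - tpr)^2)`; ties are broken in
#' favour of the lower false-positive rate.
#'
#' @param curve a `roc_curve` from [roc_points()].
#' @return The selected threshold (a sample scoring at or above it is called
#'   positive).
#' @export
optimal_boundary <- function(curve) {
  if (!inherits(curve, "roc_curve")) stop("not a roc_curve")
  if (nrow(curve) < 2L) stop("degenerate ROC curve")
  d <- sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(curve$fpr[best])]
  curve$threshold[best]
}

# DeLong placement-value AUC and variance for one cohort.
delong_components <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  check_two_classes(y)
  x_pos <- scores[y == 1L]
  x_neg <- scores[y == 0L]
  m <- length(x_pos); n <- length(x_neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(x_pos, function(x) mean(psi(x, x_neg)), numeric(1))
  v01 <- vapply(x_neg, function(y) mean(psi(x_pos, y)), numeric(1))
  auc <- mean(v10)
  var <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var)
}

#' Compare two AUCs from independent cohorts (DeLong)
#'
#' Estimates each cohort's AUC and its variance from DeLong placement
#' values, then performs an unpaired two-sided z-test on the difference.
#'
#' @param scores_a,labels_a scores and labels of the first cohort.
#' @param scores_b,labels_b scores and labels of the second cohort.
#' @param positive positive label when it cannot be inferred.
#' @return An `auc_comparison` list with `auc_a`, `auc_b`, `var_a`, `var_b`,
#'   `z` and `p_two_sided`.
#' @export
delong_compare <- function(scores_a, labels_a, scores_b, labels_b,
                           positive = NULL) {
  a <- delong_components(scores_a, labels_a, positive)
  b <- delong_components(scores_b, labels_b, positive)
  diff <- a$auc - b$auc
  v <- a$var + b$var
  if (v <= 0) {
    if (abs(diff) > 0) {
      stop("degenerate separation: zero combined variance with unequal AUCs")
    }
    z <- 0
  } else {
    z <- diff / sqrt(v)
  }
  structure(list(auc_a = a$auc, auc_b = b$auc, var_a = a$var, var_b = b$var,
                 z = z, p_two_sided = 2 * stats::pnorm(-abs(z))),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.4f vs %.4f; z = %.3f, two-sided p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_two_sided))
  invisible(x)
}

#' DeLong confidence interval for a single AUC
#'
#' @param scores,labels one cohort's scores and labels.
#' @param level confidence level.
#' @param positive positive label when it cannot be inferred.
#' @return Named vector `auc`, `lower`, `upper` (clamped to \[0, 1\]).
#' @export
auc_ci <- function(scores, labels, level = 0.95, positive = NULL) {
  comp <- delong_components(scores, labels, positive)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  half <- zq * sqrt(comp$var)
  c(auc = comp$auc, lower = max(0, comp$auc - half),
    upper = min(1, comp$auc + half))
}
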