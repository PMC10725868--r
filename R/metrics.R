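# Regression and classification metrics plus per-fold aggregation with a
# Student-t confidence interval.

#' Regression metrics for synergy scores
#'
#' @param y,yhat equal-length numeric vectors of observed and predicted
#'   scores.
#' @return list with \code{mse}, \code{rmse}, \code{pearson} and
#'   \code{pearson_defined} (FALSE when either vector is constant, in which
#'   case \code{pearson} is NA).
#' @export
regressionMetrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  mse <- mean((y - yhat)^2)
  defined <- stats::sd(y) > 0 && stats::sd(yhat) > 0
  list(mse = mse, rmse = sqrt(mse),
       pearson = if (defined) stats::cor(y, yhat) else NA_real_,
       pearson_defined = defined)
}

#' Student-t confidence interval from a summary
#'
#' \code{mean +/- t((1 + level)/2, n - 1) * sd / sqrt(n)} with sample
#' standard deviation; reproduces intervals printed alongside per-fold
#' mean +/- sd summaries.
#'
#' @param mean,sd,n fold mean, sample standard deviation, fold count.
#' @param level confidence level (default 0.95).
#' @return numeric \code{c(lo, hi)}.
#' @examples
#' ciFromSummary(219.14, 39.59, 5)
#' @export
ciFromSummary <- function(mean, sd, n, level = 0.95) {
  stopifnot(n >= 2, sd >= 0, level > 0, level < 1)
  half <- stats::qt((1 + level) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

#' Aggregate per-fold metric values
#'
#' @param values numeric vector of per-fold values (>= 2).
#' @param level confidence level.
#' @param metric metric name carried in the report.
#' @return a \linkS4class{MetricReport}.
#' @export
foldAggregateCI <- function(values, level = 0.95, metric = "metric") {
  stopifnot(length(values) >= 2, all(is.finite(values)))
  m <- mean(values)
  s <- stats::sd(values)
  new("MetricReport", metric = metric, values = values, mean = m, sd = s,
      ci = ciFromSummary(m, s, length(values), level), level = level)
}

# trapezoidal area under an ROC curve built from score thresholds
.roc_auc <- function(labels, scores) {
  pos <- sum(labels)
  neg <- sum(!labels)
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  keep <- c(diff(sc) != 0, TRUE)   # one point per distinct threshold
  tpr <- c(0, tp[keep] / pos)
  fpr <- c(0, fp[keep] / neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# average precision (step interpolation of the precision-recall curve)
.pr_auc <- function(labels, scores) {
  pos <- sum(labels)
  if (pos == 0 || pos == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / pos
  keep <- c(diff(sc) != 0, TRUE)
  prec <- prec[keep]
  rec <- rec[keep]
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for synergy labels
#'
#' Accuracy and Cohen's kappa are computed on hard argmax labels over all
#' three classes; precision is TP/(TP+FP) for the synergistic class. The
#' threshold-free metrics (ROC-AUC by the trapezoidal rule, PR-AUC by the
#' average-precision convention) are computed on the binary subset of
#' samples whose true class is synergistic or antagonistic, scoring with
#' P(synergistic); additive samples are excluded there, mirroring how
#' synergy screens report the two decisive classes.
#'
#' @param y_true character/factor of true classes
#'   (see \code{\link{synergyClasses}}).
#' @param probs numeric matrix, one row per sample, columns named by class,
#'   rows summing to 1.
#' @return list with \code{accuracy}, \code{precision}, \code{kappa},
#'   \code{roc_auc}, \code{pr_auc}, \code{binary_accuracy} (synergistic
#'   vs antagonistic call on the binary subset), \code{n_binary} and
#'   \code{auc_defined}.
#' @export
classificationMetrics <- function(y_true, probs) {
  classes <- synergyClasses()
  y_true <- as.character(y_true)
  stopifnot(all(y_true %in% classes), nrow(probs) == length(y_true),
            all(classes %in% colnames(probs)))
  probs <- probs[, classes, drop = FALSE]
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    stop("probability rows must sum to 1")
  pred <- classes[max.col(probs, ties.method = "first")]

  accuracy <- mean(pred == y_true)
  tp <- sum(pred == "synergistic" & y_true == "synergistic")
  fp <- sum(pred == "synergistic" & y_true != "synergistic")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_

  # Cohen's kappa on the 3-class confusion
  po <- accuracy
  pe <- sum(vapply(classes, function(cl) mean(pred == cl) * mean(y_true == cl),
                   numeric(1)))
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1

  bin <- y_true %in% c("synergistic", "antagonistic")
  lab <- y_true[bin] == "synergistic"
  sc <- probs[bin, "synergistic"]
  roc <- .roc_auc(lab, sc)
  pr <- .pr_auc(lab, sc)
  bin_acc <- if (sum(bin)) mean((sc > probs[bin, "antagonistic"]) == lab)
             else NA_real_
  list(accuracy = accuracy, precision = precision, kappa = kappa,
       roc_auc = roc, pr_auc = pr, binary_accuracy = bin_acc,
       n_binary = sum(bin), auc_defined = !is.na(roc))
}
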