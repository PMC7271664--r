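# Differential diagnosis from per-subject Array-of-Importance CCR values:
# leave-one-subject-out SVM with the full metric panel, and the
# between-group t-test.

#' Leave-one-subject-out group discrimination from scalar CCR features
#'
#' Pools the two groups' per-subject features (typically the top CCR from
#' the Array of Importance), holds out one subject at a time, trains a
#' polynomial-kernel SVM on the rest (standardized with training-fold
#' statistics) and aggregates the held-out predictions into the usual
#' metric panel. The first group is the positive class; swapping the
#' arguments swaps sensitivity and specificity. ROC/AUC are computed from
#' the per-fold SVM decision values, oriented so larger means "more like
#' the positive class".
#'
#' @param a,b Numeric feature vectors, one value per subject (>= 3 each).
#' @param labels Length-2 character vector naming the groups (defaults to
#'   the argument names).
#' @param kernel_degree Polynomial kernel degree (default 3).
#' @param cost SVM regularization constant (default 1).
#' @param coef0 Polynomial kernel offset (default 1).
#' @param seed Integer seed fixed before each fold's fit.
#' @return An object of class `"classifier_metrics"`: list with
#'   `sensitivity`, `specificity`, `precision`, `recall`, `f_score`,
#'   `accuracy_percent`, `auc`, `confusion`, `predictions`,
#'   `decision_values`, `labels`.
#' @export
group_classify <- function(a, b, labels = NULL, kernel_degree = 3L,
                           cost = 1, coef0 = 1, seed = 1L) {
  if (is.null(labels))
    labels <- c(deparse(substitute(a)), deparse(substitute(b)))
  stopifnot(length(labels) == 2L, labels[1L] != labels[2L])
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs >= 3 subjects")
  x <- c(a, b)
  y <- factor(rep(labels, c(length(a), length(b))), levels = labels)
  n <- length(x)
  pred <- character(n)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i]; ytr <- y[-i]
    if (stats::sd(xtr) == 0)
      stop("degenerate training fold: single-valued feature")
    mu <- mean(xtr); s <- stats::sd(xtr)
    if (!is.null(seed)) set.seed(seed)
    fit <- e1071::svm(x = matrix((xtr - mu) / s, ncol = 1L), y = ytr,
                      kernel = "polynomial", degree = kernel_degree,
                      cost = cost, coef0 = coef0, gamma = 1,
                      scale = FALSE)
    p <- stats::predict(fit, matrix((x[i] - mu) / s, ncol = 1L),
                        decision.values = TRUE)
    pred[i] <- as.character(p)
    dv <- as.numeric(attr(p, "decision.values"))
    # libsvm orients decision values toward the first training label;
    # normalize so positive = first group
    dvname <- colnames(attr(p, "decision.values"))
    if (!is.null(dvname) &&
        !startsWith(dvname, paste0(labels[1L], "/"))) dv <- -dv
    dec[i] <- dv
  }
  pos <- labels[1L]; neg <- labels[2L]
  tp <- sum(pred == pos & y == pos)
  fn <- sum(pred == neg & y == pos)
  tn <- sum(pred == neg & y == neg)
  fp <- sum(pred == pos & y == neg)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  fsc <- if (!is.na(prec) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  roc <- pROC::roc(response = y, predictor = dec,
                   levels = c(neg, pos), direction = "<", quiet = TRUE)
  structure(
    list(sensitivity = sens, specificity = spec, precision = prec,
         recall = sens, f_score = fsc,
         accuracy_percent = 100 * (tp + tn) / n,
         auc = as.numeric(pROC::auc(roc)),
         confusion = table(truth = y, predicted = factor(pred, labels)),
         predictions = pred, decision_values = dec, labels = labels),
    class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("%s vs %s  sens %.2f  spec %.2f  prec %.2f  recall %.2f  ",
           "F %.2f  acc %.1f%%  AUC %.3f\n"),
    x$labels[1L], x$labels[2L], x$sensitivity, x$specificity,
    x$precision, x$recall, x$f_score, x$accuracy_percent, x$auc))
  invisible(x)
}

#' Between-group t-test on per-subject CCR values
#'
#' Standard t statistic and two-sided p-value. `"two_sample_pooled"`
#' (default) assumes equal variances, `"welch"` does not, `"paired"`
#' pairs the observations (requires equal lengths). Degenerate inputs
#' are resolved explicitly: identical paired vectors give statistic 0
#' and p 1; zero-variance samples with different means give an infinite
#' statistic and p 0; zero variance with equal means is an error.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param variant `"two_sample_pooled"`, `"paired"` or `"welch"`.
#' @return An object of class `"ttest_result"`: list with `statistic`,
#'   `p_value`, `df`, `variant`.
#' @export
group_ttest <- function(a, b,
                        variant = c("two_sample_pooled", "paired",
                                    "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  wrap <- function(statistic, p_value, df) {
    structure(list(statistic = statistic, p_value = p_value, df = df,
                   variant = variant), class = "ttest_result")
  }
  if (variant == "paired") {
    if (length(a) != length(b))
      stop("paired variant requires equal lengths")
    d <- a - b
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(wrap(0, 1, length(d) - 1L))
      return(wrap(sign(mean(d)) * Inf, 0, length(d) - 1L))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b))
        stop("zero variance in both samples and no mean difference")
      return(wrap(sign(mean(a) - mean(b)) * Inf, 0,
                  length(a) + length(b) - 2L))
    }
    tt <- stats::t.test(a, b, var.equal = (variant == "two_sample_pooled"))
  }
  wrap(unname(tt$statistic), tt$p.value, unname(tt$parameter))
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.2f, p = %.3g (%s)\n",
              x$statistic, x$df, x$p_value, x$variant))
  invisible(x)
}
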