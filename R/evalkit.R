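#' One-vs-rest counts for a class
#'
#' TP is the diagonal cell; FN the rest of the class row; FP the rest of the
#' class column; TN the remainder.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param class class label.
#' @return named vector c(TP, TN, FP, FN).
#' @export
perClassCounts <- function(cm, class) {
  m <- cm@counts
  if (!class %in% rownames(m)) stop("unknown class: ", class)
  tp <- m[class, class]
  fn <- sum(m[class, ]) - tp
  fp <- sum(m[, class]) - tp
  tn <- sum(m) - tp - fp - fn
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Confusion-matrix metric report
#'
#' Per-class one-vs-rest recall (sensitivity), specificity, precision, F1,
#' FPR, FNR and FDR, their macro (unweighted) means, and the overall
#' accuracy trace/total. Undefined ratios (0/0) are reported as NaN and
#' excluded from the macro mean with a warning.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with `perClass` (data.frame), `macro` (named vector),
#'   `accuracy`.
#' @examples
#' cm <- confusionMatrix(matrix(c(50, 10, 5, 35), 2,
#'                              dimnames = list(c("a", "b"), c("a", "b"))))
#' cmMetrics(cm)$perClass["a", c("precision", "recall", "f1")]
#' @export
cmMetrics <- function(cm) {
  m <- cm@counts
  if (sum(m) == 0) stop("empty confusion matrix")
  classes <- rownames(m)
  rows <- lapply(classes, function(cl) {
    ct <- perClassCounts(cm, cl)
    rat <- function(a, b) if (a + b == 0) NaN else a / (a + b)
    recall <- rat(ct["TP"], ct["FN"])
    spec <- rat(ct["TN"], ct["FP"])
    prec <- rat(ct["TP"], ct["FP"])
    f1 <- if (is.nan(prec) || is.nan(recall) || prec + recall == 0) NaN
          else 2 * prec * recall / (prec + recall)
    c(recall = unname(recall), specificity = unname(spec),
      precision = unname(prec), f1 = unname(f1),
      fpr = unname(rat(ct["FP"], ct["TN"])), fnr = unname(rat(ct["FN"], ct["TP"])),
      fdr = unname(rat(ct["FP"], ct["TP"])))
  })
  perClass <- as.data.frame(do.call(rbind, rows), row.names = classes)
  if (any(is.nan(as.matrix(perClass))))
    warning("undefined (0/0) per-class metrics excluded from macro averages")
  macro <- colMeans(perClass, na.rm = TRUE)
  list(perClass = perClass, macro = macro,
       accuracy = sum(diag(m)) / sum(m))
}

#' MAE and RMSE between one-hot labels and class scores
#'
#' Elementwise over the n x K score matrix against the one-hot encoding of
#' the actual labels, averaged over all n * K entries.
#'
#' @param actual label vector (length n).
#' @param scores n x K matrix of class scores; columns named by class.
#' @return named vector c(mae, rmse).
#' @export
maeRmse <- function(actual, scores) {
  if (is.null(dim(scores))) stop("scores matrix required")
  lev <- colnames(scores)
  if (is.null(lev)) stop("scores needs class column names")
  onehot <- outer(as.character(actual), lev, "==") * 1
  d <- onehot - scores
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Multiclass Matthews correlation coefficient
#'
#' Generalised correlation over the K x K matrix:
#' (c*s - sum(p*t)) / sqrt((s^2 - sum(p^2)) (s^2 - sum(t^2))) with c the
#' trace, s the total, t the row (actual) and p the column (predicted)
#' marginals.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return MCC in [-1, 1], or NaN for degenerate marginals.
#' @export
mccScore <- function(cm) {
  m <- cm@counts
  s <- sum(m); c0 <- sum(diag(m))
  t <- rowSums(m); p <- colSums(m)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(NaN)
  (c0 * s - sum(p * t)) / den
}

#' Cohen's kappa
#'
#' (p_o - p_e) / (1 - p_e) with p_e from the row/column marginals.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return kappa, or NaN when 1 - p_e = 0.
#' @export
kappaScore <- function(cm) {
  m <- cm@counts
  s <- sum(m)
  po <- sum(diag(m)) / s
  pe <- sum(rowSums(m) * colSums(m)) / s^2
  if (1 - pe == 0) return(NaN)
  (po - pe) / (1 - pe)
}

# exact null distribution of W+ = sum of ranks with positive sign, over all
# 2^n sign assignments; ranks are midranks doubled to stay integral
wilcoxExactP <- function(ranks2, W2) {
  maxs <- sum(ranks2)
  f <- numeric(maxs + 1); f[1] <- 1  # f[w+1] = #assignments with W2 = w
  for (r in ranks2) {
    g <- f
    g[(r + 1):(maxs + 1)] <- g[(r + 1):(maxs + 1)] + f[1:(maxs + 1 - r)]
    f <- g
  }
  tot <- sum(f)
  lo <- sum(f[seq_len(W2 + 1)]) / tot        # P(W2 <= w)
  hi <- sum(f[(W2 + 1):(maxs + 1)]) / tot    # P(W2 >= w)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test (exact for small n)
#'
#' Zero differences are dropped and ties midranked. For n <= `exactMax` the
#' two-sided p-value is exact over all 2^n sign assignments (computed by
#' convolution of the signed-rank distribution, identical to full
#' enumeration); beyond that a normal approximation with continuity and tie
#' correction is used.
#'
#' @param x,y paired samples of equal length.
#' @param exactMax largest n for the exact distribution (default 25).
#' @return list with `W` (positive-rank sum), `p` (two-sided), `n` (pairs
#'   used), `exact`.
#' @examples
#' wilcoxonSignedRank(2:10, 1:9)$p  # 9 positive differences: 2/2^9
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 25L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; test undefined")
    return(list(W = NA_real_, p = NA_real_, n = 0L, exact = NA))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    p <- wilcoxExactP(as.integer(round(2 * r)), as.integer(round(2 * W)))
    list(W = W, p = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))), n = n, exact = FALSE)
  }
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps the thresholds over the observed scores for that
#' class and integrates the (FPR, TPR) curve by the trapezoid rule; the
#' macro AUC is the unweighted mean over classes with both positives and
#' negatives present.
#'
#' @param actual label vector (length n).
#' @param scores n x K score matrix with class column names.
#' @return list with `perClass` (each: data.frame of ROC points, auc) and
#'   `macroAuc`.
#' @export
rocAuc <- function(actual, scores) {
  lev <- colnames(scores)
  if (is.null(lev)) stop("scores needs class column names")
  perClass <- lapply(lev, function(cl) {
    pos <- as.character(actual) == cl
    if (all(pos) || !any(pos))
      return(list(points = NULL, auc = NA_real_))
    sc <- scores[, cl]
    th <- c(Inf, sort(unique(sc), decreasing = TRUE))
    tpr <- vapply(th, function(t) mean(sc[pos] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(sc[!pos] >= t), numeric(1))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(threshold = th, fpr = fpr, tpr = tpr), auc = auc)
  })
  names(perClass) <- lev
  aucs <- vapply(perClass, `[[`, numeric(1), "auc")
  list(perClass = perClass, macroAuc = mean(aucs, na.rm = TRUE))
}

#' Population summary of per-fold accuracies
#'
#' @param accs per-fold accuracy vector.
#' @return named vector with mean and population SD.
#' @export
cvSummary <- function(accs) {
  m <- mean(accs)
  c(mean = m, sd = sqrt(mean((accs - m)^2)))
}

#' k-fold cross-validation driver
#'
#' Partitions the manifest with [kfoldPartition()], then calls
#' `trainer(trainManifest, evalManifest)` once per fold (k = 1: a single
#' 70:20:10 holdout, training on train+val and evaluating on test). The
#' trainer returns an accuracy in [0, 1].
#'
#' @param manifest data.frame with a `class` column.
#' @param k number of folds (>= 1).
#' @param trainer function(train, eval) -> accuracy.
#' @param seed integer seed for the partition.
#' @return list with `foldAccuracy`, `mean`, `sd` (population SD).
#' @export
kfoldCV <- function(manifest, k, trainer, seed = 1L) {
  part <- kfoldPartition(manifest, k, seed)
  folds <- if (k == 1L) 1L else seq_len(k)
  accs <- vapply(folds, function(f) {
    ev <- part[!is.na(part$fold) & part$fold == f, , drop = FALSE]
    tr <- part[is.na(part$fold) | part$fold != f, , drop = FALSE]
    if (length(setdiff(unique(part$class), unique(ev$class))))
      warning("fold ", f, " is missing at least one class")
    as.numeric(trainer(tr, ev))
  }, numeric(1))
  s <- cvSummary(accs)
  list(foldAccuracy = accs, mean = unname(s["mean"]), sd = unname(s["sd"]))
}
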