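# ---- evaluation metrics and model comparison ---------------------------------

f1_from_counts <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 0, 2 * tp / den)
}

#' Multilabel F1 metrics report
#'
#' Binarizes probabilities at `threshold` and reports per-target precision,
#' recall and F1 (`F1 = 2TP / (2TP + FP + FN)`, defined as 0 when the
#' denominator is 0), plus the macro F1 (unweighted mean of per-target F1)
#' and micro F1 (F1 of the pooled confusion counts). Targets with no test
#' samples (all labels `NA`) get `NA` and are excluded from the macro mean.
#'
#' @param probabilities Samples x targets probability (or 0/1) matrix.
#' @param labels Binary matrix of the same shape.
#' @param threshold Decision threshold.
#' @return A `metrics_report`: `per_target` data frame, `macro_f1`,
#'   `micro_f1`, `counts`.
#' @export
metrics_report <- function(probabilities, labels, threshold = 0.5) {
  y <- as.matrix(labels)
  pred <- (as.matrix(probabilities) >= threshold) * 1L
  Tn <- ncol(y)
  nm <- colnames(y) %||% paste0("target_", seq_len(Tn))
  tab <- data.frame(target = nm, tp = 0L, fp = 0L, fn = 0L, tn = 0L,
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  for (t in seq_len(Tn)) {
    use <- !is.na(y[, t])
    if (!any(use)) next
    yt <- y[use, t]; pt <- pred[use, t]
    tp <- sum(pt == 1 & yt == 1); fp <- sum(pt == 1 & yt == 0)
    fn <- sum(pt == 0 & yt == 1); tn <- sum(pt == 0 & yt == 0)
    tab[t, c("tp", "fp", "fn", "tn")] <- c(tp, fp, fn, tn)
    tab$precision[t] <- if (tp + fp > 0) tp / (tp + fp) else 0
    tab$recall[t] <- if (tp + fn > 0) tp / (tp + fn) else 0
    tab$f1[t] <- f1_from_counts(tp, fp, fn)
  }
  macro <- mean(tab$f1, na.rm = TRUE)
  micro <- f1_from_counts(sum(tab$tp), sum(tab$fp), sum(tab$fn))
  structure(list(per_target = tab, macro_f1 = macro, micro_f1 = micro,
                 n_samples = nrow(y), threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report on", x$n_samples, "samples (threshold",
      x$threshold, ")\n")
  print(x$per_target, row.names = FALSE, digits = 4)
  cat(sprintf("macro F1 = %.4f   micro F1 = %.4f\n", x$macro_f1, x$micro_f1))
  invisible(x)
}

macro_f1 <- function(pred01, labels) {
  metrics_report(pred01, labels, threshold = 0.5)$macro_f1
}

#' Split records into training and test sets
#'
#' Uniformly random seeded split at the given ratio; the training set takes
#' `ceiling(ratio[1] / sum(ratio) * N)` records and the test set the rest.
#' The two parts are disjoint and cover the input.
#'
#' @param records A data frame (split by rows), list, or integer count `N`
#'   (in which case index vectors are returned).
#' @param ratio Length-2 positive numeric, train:test (default 5:1).
#' @param seed Integer seed; the same seed always yields the same membership.
#' @return `list(train=, test=)` of the same kind as the input.
#' @export
split_dataset <- function(records, ratio = c(5, 1), seed = 1L) {
  if (length(ratio) != 2 || any(ratio <= 0)) stop("ratio must be two positive numbers")
  n <- if (is.numeric(records) && length(records) == 1) as.integer(records)
       else if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 2) stop("need at least 2 records to split")
  n_train <- ceiling(ratio[1] / sum(ratio) * n)
  idx <- withr_seed(seed, sample.int(n, n_train))
  train_idx <- sort(idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  pick <- function(i) {
    if (is.numeric(records) && length(records) == 1) i
    else if (is.data.frame(records)) records[i, , drop = FALSE]
    else records[i]
  }
  list(train = pick(train_idx), test = pick(test_idx))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Approximate randomization test for paired model comparison
#'
#' Tests whether two models' predictions on the same test samples differ in a
#' chosen metric. The observed statistic is `|metric(A) - metric(B)|`; each
#' iteration swaps the two models' prediction rows per sample with
#' probability 1/2 and recomputes it. The reported p-value uses the add-one
#' estimator `p = (1 + #{permuted >= observed}) / (1 + n_iter)`, so it lies
#' in (0, 1] and equals 1 when the predictions are identical.
#'
#' @param pred_a,pred_b Binary (or probability, binarized at 0.5) prediction
#'   matrices, samples x targets.
#' @param labels Binary label matrix of the same shape.
#' @param metric `"macro_f1"` or `"micro_f1"`.
#' @param n_iter Number of random swap iterations.
#' @param seed Integer seed.
#' @return `list(p_value=, observed=, n_iter=)`.
#' @export
approx_randomization_test <- function(pred_a, pred_b, labels,
                                      metric = c("macro_f1", "micro_f1"),
                                      n_iter = 9999L, seed = 1L) {
  metric <- match.arg(metric)
  A <- (as.matrix(pred_a) >= 0.5) * 1L
  B <- (as.matrix(pred_b) >= 0.5) * 1L
  y <- as.matrix(labels)
  if (!all(dim(A) == dim(B)) || !all(dim(A) == dim(y)))
    stop("pred_a, pred_b and labels must have identical dimensions")
  mfun <- function(pred) {
    r <- metrics_report(pred, y, threshold = 0.5)
    if (metric == "macro_f1") r$macro_f1 else r$micro_f1
  }
  obs <- abs(mfun(A) - mfun(B))
  n <- nrow(A)
  hits <- withr_seed(seed, {
    h <- 0L
    for (it in seq_len(n_iter)) {
      swap <- runif(n) < 0.5
      Ai <- A; Bi <- B
      Ai[swap, ] <- B[swap, , drop = FALSE]
      Bi[swap, ] <- A[swap, , drop = FALSE]
      if (abs(mfun(Ai) - mfun(Bi)) >= obs - 1e-12) h <- h + 1L
    }
    h
  })
  list(p_value = (1 + hits) / (1 + n_iter), observed = obs,
       n_iter = as.integer(n_iter))
}
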