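#' Per-label precision, recall and F1
#'
#' Zero-denominator cases (a label never predicted, or with no true
#' positives in the truth) are defined as 0, so labels a model has
#' effectively abandoned show up as precision 0 rather than NA.
#'
#' @param decisions Binary matrix, documents by codes.
#' @param truth Binary matrix of the same shape.
#' @return A tibble with one row per label: `code`, `precision`, `recall`,
#'   `f1`, `support` (number of true documents), `tp`, `fp`, `fn`.
#' @export
per_label_prf <- function(decisions, truth) {
  stopifnot(all(dim(decisions) == dim(truth)))
  tp <- colSums(decisions == 1 & truth == 1)
  fp <- colSums(decisions == 1 & truth == 0)
  fn <- colSums(decisions == 0 & truth == 1)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  codes <- colnames(truth)
  if (is.null(codes)) codes <- paste0("label_", seq_len(ncol(truth)))
  tibble(code = codes, precision = unname(p), recall = unname(r),
         f1 = unname(f), support = unname(tp + fn),
         tp = unname(tp), fp = unname(fp), fn = unname(fn))
}

#' Macro- and micro-averaged F1
#'
#' Macro-F1 is the unweighted mean of per-label F1; micro-F1 treats every
#' (document, code) pair as one prediction and computes F1 over the
#' flattened pairs.
#'
#' @inheritParams per_label_prf
#' @return A named list `f1_macro`, `f1_micro`.
#' @export
macro_micro_f1 <- function(decisions, truth) {
  per <- per_label_prf(decisions, truth)
  d <- as.vector(decisions)
  y <- as.vector(truth)
  tp <- sum(d == 1 & y == 1); fp <- sum(d == 1 & y == 0)
  fn <- sum(d == 0 & y == 1)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  micro <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(f1_macro = mean(per$f1), f1_micro = micro)
}

# ROC-AUC of one score vector; ties give 0.5 via pROC's trapezoidal rule.
auc_one <- function(scores, truth) {
  if (length(unique(truth)) < 2) return(NA_real_)
  if (length(unique(scores)) < 2) return(0.5)
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Macro- and micro-averaged ROC-AUC
#'
#' Macro-AUC averages per-label AUC over labels having both classes present
#' (degenerate labels are skipped and reported via a message and the
#' `skipped` attribute); micro-AUC is computed over the flattened
#' (document, code) pairs.
#'
#' @param scores Numeric matrix of probabilities, documents by codes.
#' @param truth Binary matrix of the same shape.
#' @return A named list `auc_macro`, `auc_micro` (attribute `skipped`: codes
#'   skipped in the macro average).
#' @export
auc_macro_micro <- function(scores, truth) {
  stopifnot(all(dim(scores) == dim(truth)))
  per <- vapply(seq_len(ncol(truth)),
                function(j) auc_one(scores[, j], truth[, j]), numeric(1))
  skipped <- which(is.na(per))
  if (length(skipped) > 0) {
    inform(sprintf("macro-AUC: skipped %d label(s) with a single class",
                   length(skipped)))
  }
  macro <- mean(per[!is.na(per)])
  micro <- auc_one(as.vector(scores), as.vector(truth))
  out <- list(auc_macro = macro, auc_micro = micro)
  attr(out, "skipped") <- if (!is.null(colnames(truth)))
    colnames(truth)[skipped] else skipped
  out
}

#' Precision at n
#'
#' For each document, the fraction of its n highest-scored labels present in
#' the ground truth, averaged over documents.  Ties are broken by ascending
#' label index so the metric is deterministic.
#'
#' @param scores Numeric matrix, documents by codes.
#' @param truth Binary matrix of the same shape.
#' @param n Number of top labels to inspect (default 5).
#' @return A scalar in \[0,1\].
#' @export
precision_at_n <- function(scores, truth, n = 5) {
  stopifnot(all(dim(scores) == dim(truth)), n >= 1, n <= ncol(scores))
  per_doc <- vapply(seq_len(nrow(scores)), function(i) {
    top <- order(-scores[i, ], seq_len(ncol(scores)))[seq_len(n)]
    mean(truth[i, top])
  }, numeric(1))
  mean(per_doc)
}

#' Full metrics report
#'
#' Computes the whole evaluation suite on a score matrix: macro/micro AUC,
#' macro/micro F1 (decisions at `threshold`), precision-at-n, and the
#' per-label precision/recall/F1 table.
#'
#' @param scores Numeric matrix of probabilities, documents by codes.
#' @param truth Binary matrix of the same shape.
#' @param threshold Decision threshold (default 0.5).
#' @param n Top-n for precision-at-n (default 5, capped at the label count).
#' @return A `swam_metrics` object; `glance()` gives the scalar metrics as a
#'   one-row tibble, `tidy()` the per-label table.
#' @export
metrics_report <- function(scores, truth, threshold = 0.5, n = 5) {
  n <- min(n, ncol(scores))
  decisions <- (scores >= threshold) * 1L
  f1 <- macro_micro_f1(decisions, truth)
  auc <- suppressMessages(auc_macro_micro(scores, truth))
  structure(
    list(auc_macro = auc$auc_macro, auc_micro = auc$auc_micro,
         f1_macro = f1$f1_macro, f1_micro = f1$f1_micro,
         p_at_n = precision_at_n(scores, truth, n = n), n = n,
         threshold = threshold,
         per_label = per_label_prf(decisions, truth)),
    class = "swam_metrics"
  )
}

#' @export
print.swam_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<swam_metrics>  AUC macro %.3f / micro %.3f | ",
           "F1 macro %.3f / micro %.3f | P@%d %.3f\n"),
    x$auc_macro, x$auc_micro, x$f1_macro, x$f1_micro, x$n, x$p_at_n))
  zp <- x$per_label$code[x$per_label$precision == 0 & x$per_label$support > 0]
  if (length(zp) > 0) {
    cat("  zero-precision labels:", paste(zp, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.swam_metrics <- function(x, ...) {
  tibble(auc_macro = x$auc_macro, auc_micro = x$auc_micro,
         f1_macro = x$f1_macro, f1_micro = x$f1_micro,
         p_at_n = x$p_at_n, n = x$n, threshold = x$threshold)
}

#' @export
tidy.swam_metrics <- function(x, ...) x$per_label

#' Write a metrics report
#'
#' Scalar metrics go to `<path>` as JSON; the per-label table to
#' `<path>.per_label.tsv`.
#'
#' @param report A `swam_metrics` object.
#' @param path Output path for the JSON summary.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(
    list(auc_macro = report$auc_macro, auc_micro = report$auc_micro,
         f1_macro = report$f1_macro, f1_micro = report$f1_micro,
         p_at_n = report$p_at_n, n = report$n, threshold = report$threshold),
    path, auto_unbox = TRUE, digits = NA)
  readr::write_tsv(report$per_label, paste0(path, ".per_label.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' Unigram bag-of-words logistic-regression baseline
#'
#' Fits one independent binary one-vs-rest logistic regression per code on
#' unigram count features (ridge-regularized with a small fixed penalty for
#' stability on high-dimensional counts; fits are deterministic).  Labels
#' without a positive training document are skipped with a warning and score
#' 0 everywhere.
#'
#' @param dataset A `swam_dataset`.
#' @param lambda Ridge penalty (default 1e-3).
#' @param split Evaluation split (default `"test"`).
#' @return A list: `report` (a `swam_metrics` on the evaluation split),
#'   `scores` (document x code probability matrix), `decisions`.
#' @export
bow_logreg_baseline <- function(dataset, lambda = 1e-3, split = "test") {
  tr <- dataset_split_ids(dataset, "train")
  ev <- dataset_split_ids(dataset, split)
  v <- vocab_size(dataset$vocab)
  dtm <- function(ids_list) {
    i <- rep(seq_along(ids_list), lengths(ids_list))
    j <- unlist(ids_list)
    keep <- j != PAD_ID
    Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                         dims = c(length(ids_list), v))
  }
  Xtr <- dtm(tr$ids)
  Xev <- dtm(ev$ids)
  L <- ncol(tr$labels)
  scores <- matrix(0, nrow = length(ev$ids), ncol = L,
                   dimnames = list(ev$doc_id, colnames(tr$labels)))
  for (l in seq_len(L)) {
    y <- tr$labels[, l]
    if (sum(y) == 0 || sum(y) == length(y)) {
      warn(sprintf("baseline: label %s has a single class in training; skipped",
                   colnames(tr$labels)[l]))
      next
    }
    fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    scores[, l] <- as.vector(predict(fit, Xev, type = "response"))
  }
  list(report = metrics_report(scores, ev$labels),
       scores = scores,
       decisions = (scores >= 0.5) * 1L)
}

#' Paired bootstrap comparison of two models
#'
#' Resamples documents with replacement `B` times and recomputes the chosen
#' metric for both models on each resample; the reported p-value is the
#' fraction of resamples on which model A does not beat model B (a one-sided
#' test of A's superiority), with exact ties split half-and-half so two
#' identical models give p = 0.5.  Deterministic under `seed`.
#'
#' @param scores_a,scores_b Score matrices (documents x codes) from two
#'   models over the same documents.
#' @param truth Binary truth matrix of the same shape.
#' @param metric One of `"f1_macro"`, `"f1_micro"`, `"auc_macro"`,
#'   `"auc_micro"`, `"p_at_n"`.
#' @param B Number of bootstrap resamples (default 10000; below 100 a
#'   warning is issued).
#' @param seed Integer seed.
#' @param threshold Decision threshold for the F1 metrics.
#' @param n Top-n for `"p_at_n"`.
#' @return The p-value, with attributes `observed_a`, `observed_b`, `B`.
#' @export
paired_bootstrap <- function(scores_a, scores_b, truth,
                             metric = c("f1_macro", "f1_micro", "auc_macro",
                                        "auc_micro", "p_at_n"),
                             B = 10000, seed = 1L, threshold = 0.5, n = 5) {
  metric <- match.arg(metric)
  stopifnot(all(dim(scores_a) == dim(truth)),
            all(dim(scores_b) == dim(truth)))
  if (B < 100) warn("fewer than 100 bootstrap resamples")
  mfun <- function(sc, y) {
    switch(metric,
      f1_macro = macro_micro_f1((sc >= threshold) * 1L, y)$f1_macro,
      f1_micro = macro_micro_f1((sc >= threshold) * 1L, y)$f1_micro,
      auc_macro = suppressMessages(auc_macro_micro(sc, y)$auc_macro),
      auc_micro = suppressMessages(auc_macro_micro(sc, y)$auc_micro),
      p_at_n = precision_at_n(sc, y, n = min(n, ncol(y))))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nd <- nrow(truth)
  wins_b <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(nd, nd, replace = TRUE)
    ma <- mfun(scores_a[idx, , drop = FALSE], truth[idx, , drop = FALSE])
    mb <- mfun(scores_b[idx, , drop = FALSE], truth[idx, , drop = FALSE])
    if (ma < mb) wins_b <- wins_b + 1
    else if (ma == mb) wins_b <- wins_b + 0.5
  }
  p <- wins_b / B
  attr(p, "observed_a") <- mfun(scores_a, truth)
  attr(p, "observed_b") <- mfun(scores_b, truth)
  attr(p, "B") <- B
  p
}
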