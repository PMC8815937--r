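# Linear-SVM discrimination of solenoid vs globular domains from codeword
# histograms, with two-fold cross-validation and benchmark-style metrics.

l1_normalize <- function(H) {
  H <- as.matrix(H)
  s <- rowSums(H)
  if (any(s == 0)) stopf("cannot L1-normalize zero histogram row(s)")
  H / s
}

as_binary_labels <- function(labels) {
  f <- factor(as.character(labels), levels = c("globular", "solenoid"))
  if (anyNA(f)) stopf("labels must be 'solenoid' or 'globular'")
  f
}

#' Train a linear SVM on codeword histograms
#'
#' Histograms are L1-normalized (removing the domain-size confound) and a
#' linear-kernel soft-margin SVM is fit with solenoid as the positive
#' class. Deterministic for fixed input.
#'
#' @param H n_images x k histogram matrix.
#' @param labels Vector of `"solenoid"` / `"globular"`, one per row.
#' @param c_param Soft-margin cost C.
#' @param seed RNG seed (recorded; libsvm training itself is deterministic
#'   here).
#' @return An object of class `histogram_svm`.
#' @export
train_linear_svm <- function(H, labels, c_param = 1, seed = 1) {
  y <- as_binary_labels(labels)
  if (nlevels(droplevels(y)) < 2L) stopf("both classes must be present")
  X <- l1_normalize(H)
  if (length(y) != nrow(X)) stopf("one label per histogram row required")
  fit <- with_local_seed(seed,
    e1071::svm(X, y, kernel = "linear", cost = c_param, scale = FALSE))
  structure(list(fit = fit, k = ncol(X), c_param = c_param,
                 seed = as.integer(seed)),
            class = "histogram_svm")
}

#' Confusion counts of a trained SVM on labeled histograms
#'
#' Solenoid is the positive class: `tp` solenoid predicted solenoid, `fp`
#' globular predicted solenoid, `tn` globular predicted globular, `fn`
#' solenoid predicted globular.
#'
#' @param model A [train_linear_svm()] model.
#' @param H Histogram matrix with the model's codebook dimension.
#' @param labels True labels.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_svm <- function(model, H, labels) {
  if (!inherits(model, "histogram_svm")) stopf("model must be a histogram_svm")
  H <- as.matrix(H)
  if (ncol(H) != model$k)
    stopf("histogram dimension %d does not match the model's codebook (%d)",
          ncol(H), model$k)
  y <- as_binary_labels(labels)
  pred <- stats::predict(model$fit, l1_normalize(H))
  confusion_counts(
    tp = sum(pred == "solenoid" & y == "solenoid"),
    fp = sum(pred == "solenoid" & y == "globular"),
    tn = sum(pred == "globular" & y == "globular"),
    fn = sum(pred == "globular" & y == "solenoid"))
}

#' @rdname evaluate_svm
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0)) stopf("counts must be nonnegative")
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Per-class and overall accuracy from confusion counts
#'
#' `solenoid_acc = 100 tp / (tp + fn)`, `globular_acc = 100 tn / (tn + fp)`,
#' `overall_acc = 100 (tp + tn) / (tp + fp + tn + fn)`, each reported to
#' one decimal (exact rational arithmetic before rounding).
#'
#' @param cc A [confusion_counts()] object.
#' @return List of class `benchmark_metrics` with `solenoid_acc`,
#'   `globular_acc`, `overall_acc` in percent.
#' @export
benchmark_metrics <- function(cc) {
  if (cc$tp + cc$fn == 0L) stopf("no solenoid items")
  if (cc$tn + cc$fp == 0L) stopf("no globular items")
  structure(list(
    solenoid_acc = round(100 * cc$tp / (cc$tp + cc$fn), 1),
    globular_acc = round(100 * cc$tn / (cc$tn + cc$fp), 1),
    overall_acc = round(100 * (cc$tp + cc$tn) / (cc$tp + cc$fp + cc$tn + cc$fn), 1)),
    class = "benchmark_metrics")
}

#' @export
print.benchmark_metrics <- function(x, ...) {
  cat(sprintf("<benchmark_metrics> solenoid %.1f%%  globular %.1f%%  overall %.1f%%\n",
              x$solenoid_acc, x$globular_acc, x$overall_acc))
  invisible(x)
}

#' Two-fold cross-validated solenoid/globular classification
#'
#' The corpus is split into two stratified random halves. Per fold, a
#' fresh codebook is built from the training images only, both halves are
#' encoded against it, the SVM is trained on the training half and
#' evaluated on the held-out half; confusion counts are summed over both
#' folds, so every item is tested exactly once. Bit-stable for a fixed
#' seed.
#'
#' @param features_list List of [image_features], one per domain.
#' @param labels `"solenoid"` / `"globular"` per domain.
#' @param vocab_size Codebook size per fold.
#' @param seed Seed controlling the split and the fold codebooks.
#' @param c_param SVM cost.
#' @return List with `confusion` (summed [confusion_counts()]), `metrics`
#'   ([benchmark_metrics()]) and per-fold details.
#' @export
twofold_cv <- function(features_list, labels, vocab_size = 200, seed = 1,
                       c_param = 1) {
  y <- as_binary_labels(labels)
  if (any(table(y) < 2L)) stopf("each class needs at least 2 members")
  n <- length(features_list)
  if (length(y) != n) stopf("one label per feature set required")
  fold <- integer(n)
  fold_assign <- with_local_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx[seq_len(floor(length(idx) / 2))]] <- 1L
      fold[idx[(floor(length(idx) / 2) + 1L):length(idx)]] <- 2L
    }
    fold
  })
  folds <- list()
  total <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (f in 1:2) {
    train <- which(fold_assign != f)
    test <- which(fold_assign == f)
    dict <- build_dictionary(features_list[train])
    if (vocab_size > dict$M)
      stopf("vocab_size %d exceeds the %d training features of fold %d",
            vocab_size, dict$M, f)
    cb <- build_codebook(dict, k = vocab_size, seed = seed + f)
    H_train <- encode_corpus(features_list[train], cb)$histograms
    H_test <- encode_corpus(features_list[test], cb)$histograms
    model <- train_linear_svm(H_train, y[train], c_param = c_param,
                              seed = seed + f)
    cc <- evaluate_svm(model, H_test, y[test])
    folds[[f]] <- list(test_idx = test, confusion = cc,
                       codebook_meta = cb$train_meta)
    total <- total + c(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn)
  }
  cc <- confusion_counts(total["tp"], total["fp"], total["tn"], total["fn"])
  list(confusion = cc, metrics = benchmark_metrics(cc), folds = folds,
       fold_assignment = fold_assign)
}
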