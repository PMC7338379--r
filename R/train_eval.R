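#' Stratified 80/20 split plus five-fold cross-validation plan
#'
#' Reproduces the evaluation protocol of the screening readout: the labelled
#' manifest is first split into an 80% training pool and a 20% held-out test
#' set, then the training pool is partitioned into `n_folds` disjoint
#' validation folds of near-equal size (difference at most one). Both stages
#' are stratified by class by default.
#'
#' @param manifest data frame with at least a `true_class` column; rows are
#'   indexed 1..n
#' @param test_fraction held-out fraction (default 0.20)
#' @param n_folds number of cross-validation folds (>= 2)
#' @param stratified stratify both stages by `true_class`
#' @param seed integer seed; the plan is deterministic under it
#' @return list of class `"split_plan"`: `test_idx`, `folds` (each with
#'   `train_idx`, `val_idx`), and the resolved parameters
#' @export
make_splits <- function(manifest, test_fraction = 0.2, n_folds = 5L,
                        stratified = TRUE, seed = 1L) {
  stopifnot(is.data.frame(manifest), "true_class" %in% names(manifest))
  n <- nrow(manifest)
  if (n_folds < 2L)
    stop("cross-validation requires n_folds >= 2")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  if (any(manifest$true_class == "unlabeled"))
    stop("manifest contains unlabeled items; exclude them before splitting")
  groups <- if (stratified) split(seq_len(n), manifest$true_class)
            else list(all = seq_len(n))
  test_idx <- integer(0)
  fold_of <- integer(n)
  offset <- 0L  # rotates remainder folds across strata to keep sizes within 1
  with_seed(seed, {
    for (g in groups) {
      if (stratified && length(g) < n_folds)
        stop("too few labelled items per class for ", n_folds, " folds")
      g <- sample(g)
      n_test <- round(length(g) * test_fraction)
      test_idx <- c(test_idx, g[seq_len(n_test)])
      pool <- g[-seq_len(n_test)]
      if (length(pool) < n_folds)
        stop("too few items left for ", n_folds, " folds after the test split")
      fold_of[pool] <- ((offset + seq_along(pool) - 1L) %% n_folds) + 1L
      offset <- (offset + length(pool)) %% n_folds
    }
  })
  test_idx <- sort(test_idx)
  pool_idx <- setdiff(seq_len(n), test_idx)
  folds <- lapply(seq_len(n_folds), function(k) {
    val <- pool_idx[fold_of[pool_idx] == k]
    list(train_idx = setdiff(pool_idx, val), val_idx = val)
  })
  structure(list(test_idx = test_idx, folds = folds,
                 test_fraction = test_fraction, n_folds = as.integer(n_folds),
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_plan")
}

#' Confusion matrix over the three viability classes
#'
#' @param true,pred character/factor vectors over [spheroid_classes()]
#' @param classes class order for rows (true) and columns (predicted)
#' @return integer matrix, rows = true classes, columns = predictions
#' @export
confusion_matrix <- function(true, pred, classes = spheroid_classes()) {
  true <- factor(as.character(true), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  if (any(is.na(true))) stop("test set contains unlabeled items")
  m <- table(true = true, pred = pred)
  matrix(as.integer(m), length(classes), length(classes),
         dimnames = list(true = classes, pred = classes))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)`, and
#' `F1 = 2 * (precision * recall) / (precision + recall)`; any metric with a
#' zero denominator is reported as 0.
#'
#' @param cm square counts matrix (rows = true, columns = predicted)
#' @return list with `per_class` (data frame: class, precision, recall, f1,
#'   support), `accuracy`, and the `confusion_matrix`
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  list(per_class = data.frame(class = classes, precision = precision,
                              recall = recall, f1 = f1,
                              support = rowSums(cm), row.names = NULL),
       accuracy = sum(tp) / max(sum(cm), 1),
       confusion_matrix = cm)
}

#' Evaluate a trained model on a labelled test set
#'
#' Predictions are taken at the arg-max of the softmax output; metrics follow
#' [metrics_from_confusion()].
#'
#' @param model a trained `"spheroid_cnn"`
#' @param images list of test images
#' @param labels their true classes (must not contain `"unlabeled"`)
#' @return a `"metrics_report"`: per-class precision/recall/F1, accuracy,
#'   confusion matrix and the raw probability matrix
#' @export
evaluate <- function(model, images, labels) {
  labels <- as.character(labels)
  if (any(!labels %in% spheroid_classes()))
    stop("test set contains unlabeled items")
  probs <- predict_proba(model, images)
  pred <- spheroid_classes()[max.col(probs)]
  rep_ <- metrics_from_confusion(confusion_matrix(labels, pred))
  structure(c(rep_, list(probabilities = probs, predicted = pred)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Test accuracy:", sprintf("%.3f", x$accuracy), "\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Five-fold cross-validated training
#'
#' Trains one fresh model per fold for exactly `epochs` epochs, with
#' augmentation re-drawn each epoch on the training fold only; validation
#' accuracy is computed per epoch on the clean fold images. Accuracy curves
#' are averaged across folds; the best model is the one with the highest
#' final-epoch validation accuracy (ties broken by lowest fold index),
#' mirroring the protocol of picking the best-performing fold model for the
#' held-out test set.
#'
#' @param images full image list the split plan indexes into
#' @param labels class labels aligned with `images`
#' @param plan a [make_splits()] plan
#' @param spec a [model_spec()]
#' @param augmentation an [augmentation_config()] or `NULL` to disable
#' @param epochs training epochs per fold (default 50)
#' @param batch_size,lr optimizer settings
#' @param dropout_rate optional override of the spec's dropout
#' @param seed integer seed; fold models get distinct derived seeds
#' @param verbose print progress
#' @return list of class `"cv_result"`: `curves` (data frame `epoch`,
#'   `acc_avg`, `val_acc_avg`), `fold_curves`, `fold_final_val_acc`,
#'   `best_fold`, `best_model`
#' @export
train_cv <- function(images, labels, plan, spec,
                     augmentation = augmentation_config(), epochs = 50L,
                     batch_size = 32L, lr = 1e-3, dropout_rate = NULL,
                     seed = 1L, verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  if (epochs < 1L) stop("epochs must be >= 1")
  labels <- as.character(labels)
  fold_curves <- list()
  models <- list()
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    if (length(f$train_idx) == 0 || length(f$val_idx) == 0)
      stop("empty fold ", k)
    model <- build_model(spec, dropout_rate = dropout_rate,
                         seed = as.integer(seed) + 131L * k)
    model <- train_model(model,
                         images[f$train_idx], labels[f$train_idx],
                         images[f$val_idx], labels[f$val_idx],
                         epochs = epochs, batch_size = batch_size, lr = lr,
                         augmentation = augmentation,
                         seed = as.integer(seed) + 977L * k,
                         verbose = verbose)
    fold_curves[[k]] <- model$history
    models[[k]] <- model
    if (verbose)
      message(sprintf("fold %d/%d: final val_acc %.3f", k,
                      length(plan$folds),
                      model$history$val_acc[epochs]))
  }
  acc_avg <- rowMeans(sapply(fold_curves, `[[`, "acc"))
  val_avg <- rowMeans(sapply(fold_curves, `[[`, "val_acc"))
  finals <- vapply(fold_curves, function(h) h$val_acc[nrow(h)], numeric(1))
  best <- which.max(finals)  # which.max takes the first maximum: lowest fold
  structure(list(
    curves = data.frame(epoch = seq_len(epochs), acc_avg = acc_avg,
                        val_acc_avg = val_avg),
    fold_curves = fold_curves,
    fold_final_val_acc = finals,
    best_fold = best,
    best_model = models[[best]]
  ), class = "cv_result")
}

#' Serialize a metrics report / accuracy curves
#'
#' @param report a `"metrics_report"`
#' @param path JSON output path
#' @export
write_metrics_json <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              per_class = report$per_class,
              confusion_matrix = unclass(report$confusion_matrix))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_json
#' @param cv a `"cv_result"`
#' @export
write_curves_csv <- function(cv, path) {
  utils::write.csv(cv$curves, path, row.names = FALSE)
  invisible(path)
}
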